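emptySsrFrame <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             motif = character(), unit_length = integer(),
             repeat_number = integer(), ssr_type = character(),
             ssr = character(), n_members = integer(),
             stringsAsFactors = FALSE)
}

#' Find perfect microsatellites (SSRs)
#'
#' MISA-dialect detection of maximal perfect tandem repeats of 1-6 bp
#' units. The default minimum repeat numbers are 10 (mono), 6 (di) and 5
#' (tri to hexa). Runs whose unit is a power of a shorter unit are
#' reported at the shorter unit; trailing partial units are truncated; N
#' breaks any run. Coordinates are 1-based inclusive.
#'
#' @param sequences FASTA path, named character vector or
#'   [Biostrings::DNAStringSet].
#' @param minRepeats integer(6), minimum repeat number per unit length.
#' @return data.frame with columns `sequence_id`, `start`, `end`, `motif`,
#'   `unit_length`, `repeat_number`, `ssr_type` ("p1".."p6"), `ssr`
#'   (rendered, e.g. `"(AC)6"`), `n_members` (1 for perfect loci), sorted
#'   by sequence and start.
#' @examples
#' findSsrs(c(x = "ACACACACACAC"))
#' @export
findSsrs <- function(sequences, minRepeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  if (length(minRepeats) != 6)
    stop("minRepeats must give one threshold per unit length 1..6")
  if (is.character(sequences) &&
      !(length(sequences) > 0 && all(file.exists(sequences)))) {
    badChr <- grepl("[^ACGTN]", sequences)
    if (any(badChr))
      stop("non-DNA characters in sequence(s): ",
           paste(if (is.null(names(sequences))) which(badChr)
                 else names(sequences)[badChr], collapse = ", "))
  }
  sequences <- loadAssembly(sequences)
  bad <- grepl("[^ACGTN]", as.character(sequences))
  if (any(bad))
    stop("non-DNA characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  res <- lapply(seq_along(sequences), function(i) {
    hits <- cpp_find_ssrs(as.character(sequences[[i]]),
                          as.integer(minRepeats))
    n <- length(hits$start)
    if (n == 0) return(NULL)
    data.frame(sequence_id = names(sequences)[i],
               start = hits$start, end = hits$end, motif = hits$motif,
               unit_length = hits$unit_length,
               repeat_number = hits$repeat_number,
               ssr_type = paste0("p", hits$unit_length),
               ssr = sprintf("(%s)%d", hits$motif, hits$repeat_number),
               n_members = 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(emptySsrFrame())
  out <- out[order(match(out$sequence_id, names(sequences)), out$start,
                   out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge (or remove) SSRs that lie too close together
#'
#' Consecutive loci on one sequence separated by at most `maxGap`
#' intervening bases are combined into one compound ("c") locus spanning
#' the run; its `ssr` field concatenates the members and `n_members`
#' records how many perfect loci it absorbed. With `action = "remove"`
#' such loci are dropped instead.
#'
#' @param loci data.frame from [findSsrs()], sorted by sequence and start.
#' @param maxGap Maximum distance in bases between consecutive loci
#'   (default 100).
#' @param action "merge" (default) or "remove".
#' @return data.frame in the same format.
#' @export
mergeCompound <- function(loci, maxGap = 100, action = c("merge", "remove")) {
  action <- match.arg(action)
  if (nrow(loci) == 0) return(loci)
  if (is.unsorted(order(match(loci$sequence_id, unique(loci$sequence_id)),
                        loci$start)))
    stop("loci must be sorted by sequence and start")
  bySeq <- split(seq_len(nrow(loci)), loci$sequence_id)
  keepRows <- list()
  for (rows in bySeq) {
    sub <- loci[rows, , drop = FALSE]
    if (any(diff(sub$start) < 0)) stop("loci must be sorted by start")
    gap <- sub$start[-1] - sub$end[-nrow(sub)] - 1L
    grp <- cumsum(c(1L, as.integer(gap > maxGap)))
    merged <- lapply(split(seq_len(nrow(sub)), grp), function(g) {
      part <- sub[g, , drop = FALSE]
      if (nrow(part) == 1) return(part)
      if (action == "remove") return(NULL)
      data.frame(sequence_id = part$sequence_id[1],
                 start = part$start[1], end = part$end[nrow(part)],
                 motif = NA_character_, unit_length = NA_integer_,
                 repeat_number = NA_integer_, ssr_type = "c",
                 ssr = paste(part$ssr, collapse = ""),
                 n_members = sum(part$n_members),
                 stringsAsFactors = FALSE)
    })
    keepRows[[length(keepRows) + 1L]] <- do.call(rbind, merged)
  }
  out <- do.call(rbind, keepRows)
  if (is.null(out)) return(emptySsrFrame())
  out <- out[order(match(out$sequence_id, unique(loci$sequence_id)),
                   out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop SSRs too close to contig ends
#'
#' Removes loci with fewer than `minFlank` bases between the locus and
#' either end of its sequence (loci that could not be flanked by a primer).
#'
#' @param loci data.frame of SSR loci.
#' @param sequenceLengths Named vector of sequence lengths, or the
#'   assembly itself.
#' @param minFlank Required flank on each side in bases (default 100; 0
#'   disables the filter).
#' @return Filtered data.frame.
#' @export
filterFlanks <- function(loci, sequenceLengths, minFlank = 100) {
  if (nrow(loci) == 0) return(loci)
  if (!is.numeric(sequenceLengths)) {
    assembly <- loadAssembly(sequenceLengths)
    sequenceLengths <- setNames(width(assembly), names(assembly))
  }
  len <- sequenceLengths[loci$sequence_id]
  if (any(is.na(len)))
    stop("unknown sequence id(s): ",
         paste(unique(loci$sequence_id[is.na(len)]), collapse = ", "))
  if (any(loci$end > len | loci$start < 1))
    stop("locus outside sequence bounds")
  keep <- (loci$start - 1) >= minFlank & (len - loci$end) >= minFlank
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

REV_BASE <- c(A = "T", C = "G", G = "C", T = "A")

revcompMotif <- function(m) {
  vapply(strsplit(m, ""), function(ch)
    paste(rev(unname(REV_BASE[ch])), collapse = ""), character(1))
}

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n) - 1L, function(i)
    paste0(substring(m, i + 1L, n), substring(m, 1L, i)), character(1))
}

#' Canonical motif class of an SSR unit
#'
#' Groups motifs equivalent under rotation and reverse complement (reads
#' come from either strand and a tandem array has no defined phase). The
#' class representative is the lexicographically smallest rotation of the
#' motif or its reverse complement, rendered as "X/revcomp(X)".
#'
#' @param motif character vector of 1-6 bp units (ACGT only).
#' @return character vector of class labels, e.g. `"AC/GT"`.
#' @examples
#' canonicalMotif(c("GT", "CCT", "A"))
#' @export
canonicalMotif <- function(motif) {
  vapply(motif, function(m) {
    if (is.na(m) || !nzchar(m) || nchar(m) > 6 || grepl("[^ACGT]", m))
      stop("motif must be a 1-6 bp ACGT string: ", m)
    cands <- c(rotations(m), rotations(revcompMotif(m)))
    rep0 <- min(cands)
    paste0(rep0, "/", revcompMotif(rep0))
  }, character(1), USE.NAMES = FALSE)
}

#' Summarize an SSR catalogue
#'
#' Produces the standard MISA-style summary: sequences examined, total
#' SSRs, sequences containing SSRs / more than one SSR, compound loci and
#' member counts, plus per-unit-length counts and shares and per
#' canonical-class counts for the perfect loci.
#'
#' @param loci data.frame from the SSR pipeline (after optional
#'   [mergeCompound()] / [filterFlanks()]).
#' @param sequencesExamined Number of sequences scanned.
#' @return An [SsrSummary-class].
#' @export
summarizeSsrs <- function(loci, sequencesExamined) {
  total <- nrow(loci)
  perfect <- loci[loci$ssr_type != "c", , drop = FALSE]
  compound <- loci[loci$ssr_type == "c", , drop = FALSE]
  perSeq <- table(loci$sequence_id)
  ulCounts <- setNames(numeric(6), paste0("p", 1:6))
  if (nrow(perfect)) {
    tb <- table(factor(perfect$unit_length, levels = 1:6))
    ulCounts[] <- as.numeric(tb)
  }
  ulPct <- if (total > 0) 100 * ulCounts / total else ulCounts * 0
  classCounts <- numeric(0)
  if (nrow(perfect)) {
    cls <- canonicalMotif(perfect$motif)
    tb <- sort(table(cls), decreasing = TRUE)
    classCounts <- setNames(as.numeric(tb), names(tb))
  }
  new("SsrSummary",
      sequencesExamined = as.numeric(sequencesExamined),
      totalSsrs = total,
      sequencesWithSsr = length(perSeq),
      sequencesWithMoreThanOne = sum(perSeq > 1),
      compoundSsrs = nrow(compound),
      ssrsInCompound = if (nrow(compound)) sum(compound$n_members) else 0,
      unitLengthCounts = ulCounts,
      unitLengthPercents = ulPct,
      classCounts = classCounts)
}

#' Percent share of a count
#'
#' A small display utility for "x of n" table entries (SSR type shares,
#' ortholog-completeness percentages and the like).
#'
#' @param count Numerator.
#' @param total Denominator (> 0).
#' @param digits Decimal places (default 2).
#' @return numeric, `round(100 * count / total, digits)`. Vectorized.
#' @examples
#' ratioPercent(205789, 299574)       # 68.69
#' ratioPercent(3055, 4584, digits = 1)  # 66.6
#' @export
ratioPercent <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}

setMethod("show", "SsrSummary", function(object) {
  cat("SsrSummary\n")
  cat(sprintf("  sequences examined:           %s\n",
              format(object@sequencesExamined, big.mark = ",")))
  cat(sprintf("  total SSRs:                   %s\n",
              format(object@totalSsrs, big.mark = ",")))
  cat(sprintf("  sequences with SSRs:          %s\n",
              format(object@sequencesWithSsr, big.mark = ",")))
  cat(sprintf("  sequences with >1 SSR:        %s\n",
              format(object@sequencesWithMoreThanOne, big.mark = ",")))
  cat(sprintf("  SSRs in compound formation:   %s (in %s compound loci)\n",
              format(object@ssrsInCompound, big.mark = ","),
              format(object@compoundSsrs, big.mark = ",")))
  pct <- object@unitLengthPercents
  cat("  by unit length:",
      paste(sprintf("%s %.2f%%", names(pct), pct), collapse = "  "), "\n")
})

#' Write SSR loci and summary
#'
#' Loci as a MISA-style TSV (ID, SSR nr., type, SSR, size, start, end) and
#' the summary as JSON.
#'
#' @param loci data.frame of SSR loci.
#' @param summary An [SsrSummary-class].
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
writeSsrs <- function(loci, summary, prefix) {
  tsv <- paste0(prefix, ".tsv")
  misa <- data.frame(
    ID = loci$sequence_id,
    `SSR nr.` = stats::ave(seq_len(nrow(loci)), loci$sequence_id,
                           FUN = seq_along),
    type = loci$ssr_type, SSR = loci$ssr,
    size = loci$end - loci$start + 1L,
    start = loci$start, end = loci$end, check.names = FALSE)
  write.table(misa, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, "_summary.json")
  write_json(list(
    sequences_examined = summary@sequencesExamined,
    total_ssrs = summary@totalSsrs,
    sequences_with_ssr = summary@sequencesWithSsr,
    sequences_with_more_than_one = summary@sequencesWithMoreThanOne,
    compound_ssrs = summary@compoundSsrs,
    ssrs_in_compound = summary@ssrsInCompound,
    unit_length_counts = as.list(summary@unitLengthCounts),
    unit_length_percents = as.list(round(summary@unitLengthPercents, 2)),
    class_counts = as.list(summary@classCounts)
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
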