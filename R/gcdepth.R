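loadAssembly <- function(assembly) {
  if (is.character(assembly) && length(assembly) == 1 &&
      file.exists(assembly))
    assembly <- readDNAStringSet(assembly)
  if (is.character(assembly))
    assembly <- DNAStringSet(assembly)
  if (!is(assembly, "DNAStringSet"))
    stop("assembly must be a FASTA path, character vector or DNAStringSet")
  if (length(assembly) == 0 || sum(width(assembly)) == 0)
    stop("empty assembly")
  if (is.null(names(assembly)))
    names(assembly) <- sprintf("seq_%d", seq_along(assembly))
  names(assembly) <- sub("\\s.*$", "", names(assembly))
  assembly
}

#' GC content in fixed non-overlapping windows
#'
#' Tiles every sequence with `floor(length / window)` full windows
#' (trailing partial windows are dropped) and reports the GC percent of
#' the non-N bases in each. All-N windows get `NA`.
#'
#' @param assembly FASTA path, character vector or
#'   [Biostrings::DNAStringSet].
#' @param window Window size in bases (default 10000).
#' @return data.frame with columns `sequence_id`, `start` (0-based
#'   inclusive), `end` (exclusive), `gc_percent`, `mean_depth` (NA until
#'   [windowDepth()] is applied).
#' @examples
#' windowGc(c(chr1 = strrep("ACGC", 600)), window = 1000)
#' @export
windowGc <- function(assembly, window = 10000) {
  if (window < 1) stop("window must be >= 1")
  assembly <- loadAssembly(assembly)
  res <- lapply(seq_along(assembly), function(i) {
    L <- width(assembly)[i]
    nwin <- floor(L / window)
    if (nwin == 0) return(NULL)
    starts <- (seq_len(nwin) - 1L) * window + 1L
    wins <- extractAt(assembly[[i]], IRanges(starts, width = window))
    af <- alphabetFrequency(wins, baseOnly = TRUE)
    acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(acgt > 0,
                 100 * rowSums(af[, c("G", "C"), drop = FALSE]) / acgt,
                 NA_real_)
    data.frame(sequence_id = names(assembly)[i],
               start = starts - 1L, end = starts - 1L + window,
               gc_percent = gc, mean_depth = NA_real_)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), gc_percent = numeric(),
                      mean_depth = numeric())
  rownames(out) <- NULL
  out
}

#' Mean read depth per window from k-mer multiplicities
#'
#' Alignment-free depth proxy: the depth of a window is the mean, over its
#' N-free k-mer positions, of that canonical k-mer's occurrence count in
#' the read set. Windows with no valid k-mer get depth 0. Note the k-mer
#' depth of unique sequence is `coverage * (readLength - k + 1) /
#' readLength`, slightly below the per-base coverage.
#'
#' @param windows data.frame from [windowGc()].
#' @param assembly The same assembly.
#' @param index A [KmerIndex-class] built from the read set.
#' @param k Word size; must match the index.
#' @return The `windows` data.frame with `mean_depth` filled in.
#' @export
windowDepth <- function(windows, assembly, index, k = 17L) {
  stopifnot(is(index, "KmerIndex"))
  k <- checkK(k)
  if (k != index@k)
    stop("k (", k, ") does not match the index (k = ", index@k, ")")
  assembly <- loadAssembly(assembly)
  for (sid in unique(windows$sequence_id)) {
    if (!sid %in% names(assembly))
      stop("sequence ", sid, " not found in the assembly")
    counts <- kmerCounts(index, assembly[[match(sid, names(assembly))]])
    rows <- which(windows$sequence_id == sid)
    for (r in rows) {
      lo <- windows$start[r] + 1L              # first k-mer start, 1-based
      hi <- min(windows$end[r] - k + 1L, length(counts))
      vals <- if (lo <= hi) counts[lo:hi] else numeric()
      vals <- vals[!is.na(vals)]
      windows$mean_depth[r] <- if (length(vals)) mean(vals) else 0
    }
  }
  windows
}

#' Write a GC/depth window table
#'
#' @param windows data.frame from [windowGc()] / [windowDepth()].
#' @param file Output TSV path. All-N windows (undefined GC) are omitted.
#' @return Invisibly, `file`.
#' @export
writeGcDepth <- function(windows, file) {
  keep <- !is.na(windows$gc_percent)
  write.table(windows[keep, , drop = FALSE], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}
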