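# Quality characters are Phred+33; reads here never exceed Q40 ('I') but
# accounting tolerates the full Illumina 1.8+ range up to Q41.
QUAL_CHARS <- strsplit(rawToChar(as.raw(33:74)), "")[[1]]
QUAL_SCORES <- 0:41

# per-base counts of each quality score over a BStringSet, collapsed
qualityCounts <- function(qual) {
  joined <- unlist(qual)
  counts <- letterFrequency(joined, letters = QUAL_CHARS)
  as.numeric(counts)
}

# per-read count of bases with quality < 5 (Phred+33 chars '!' .. '%')
lowQualPerRead <- function(qual) {
  lf <- letterFrequency(qual, letters = QUAL_CHARS[1:5])
  rowSums(lf)
}

#' Per-library base-level quality statistics
#'
#' Computes the usual sequencing-report columns from a set of read pairs:
#' Q20/Q30 (percent of bases with quality at or above 20/30), GC content
#' (percent of non-N bases that are G or C) and the quality-implied error
#' rate (mean over bases of `10^(-Q/10)`, as a percent).
#'
#' @param pairs A [ReadPairs-class].
#' @return A [QcReport-class] with `rawBases == cleanBases` and zero drop
#'   counts.
#' @examples
#' qcStats(ReadPairs("GGCC", "GGCC", "IIII", "IIII"))
#' @export
qcStats <- function(pairs) {
  stopifnot(is(pairs, "ReadPairs"))
  if (length(pairs) == 0)
    stop("qcStats: empty read stream")
  bases <- sum(width(pairs@seq1)) + sum(width(pairs@seq2))
  qc <- qualityCounts(pairs@qual1) + qualityCounts(pairs@qual2)
  total <- sum(qc)
  q20 <- 100 * sum(qc[QUAL_SCORES >= 20]) / total
  q30 <- 100 * sum(qc[QUAL_SCORES >= 30]) / total
  err <- 100 * sum(qc * 10^(-QUAL_SCORES / 10)) / total
  af <- colSums(alphabetFrequency(pairs@seq1, baseOnly = TRUE)) +
    colSums(alphabetFrequency(pairs@seq2, baseOnly = TRUE))
  acgt <- sum(af[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) 100 * sum(af[c("G", "C")]) / acgt else NA_real_
  new("QcReport", rawBases = bases, cleanBases = bases,
      errorRate = err, q20 = q20, q30 = q30, gcContent = gc,
      pairsIn = length(pairs), pairsOut = length(pairs),
      pairsDroppedAdapter = 0, pairsDroppedN = 0, pairsDroppedLowq = 0)
}

#' Filter read pairs by adapter, N content and base quality
#'
#' A pair is dropped when (in this order, each pair counted once under the
#' first rule it fails): (1) either mate contains the adapter sequence as
#' an exact substring, when an adapter is supplied; (2) at least 10% of
#' the bases of either mate are N; (3) strictly more than 50% of the bases
#' of either mate have quality below 5. Surviving pairs are unchanged.
#'
#' @param pairs A [ReadPairs-class].
#' @param adapter Optional adapter sequence (character(1)); `NULL`
#'   disables rule 1.
#' @param nMaxFraction N-fraction threshold (a pair fails at or above it).
#' @param lowQualMaxFraction Low-quality fraction threshold (a pair fails
#'   strictly above it).
#' @return `list(pairs = <clean ReadPairs>, report = <QcReport>)`. Base
#'   statistics in the report are computed on the clean pairs;
#'   `rawBases` counts the input.
#' @examples
#' p <- ReadPairs(c("ACGT", "NNNA"), c("ACGT", "ACGT"),
#'                c("IIII", "IIII"), c("IIII", "IIII"))
#' filterReadPairs(p)$report
#' @export
filterReadPairs <- function(pairs, adapter = NULL, nMaxFraction = 0.10,
                            lowQualMaxFraction = 0.50) {
  stopifnot(is(pairs, "ReadPairs"))
  n <- length(pairs)
  if (n == 0) stop("filterReadPairs: empty read stream")

  failAdapter <- rep(FALSE, n)
  if (!is.null(adapter) && nzchar(adapter)) {
    failAdapter <- vcountPattern(adapter, pairs@seq1) > 0 |
      vcountPattern(adapter, pairs@seq2) > 0
  }
  nFrac1 <- letterFrequency(pairs@seq1, "N") / width(pairs@seq1)
  nFrac2 <- letterFrequency(pairs@seq2, "N") / width(pairs@seq2)
  failN <- as.vector(nFrac1 >= nMaxFraction | nFrac2 >= nMaxFraction)
  lq1 <- lowQualPerRead(pairs@qual1) / width(pairs@qual1)
  lq2 <- lowQualPerRead(pairs@qual2) / width(pairs@qual2)
  failQ <- lq1 > lowQualMaxFraction | lq2 > lowQualMaxFraction

  droppedAdapter <- failAdapter
  droppedN <- !failAdapter & failN
  droppedQ <- !failAdapter & !failN & failQ
  keep <- !(failAdapter | failN | failQ)

  rawBases <- sum(width(pairs@seq1)) + sum(width(pairs@seq2))
  clean <- pairs[keep]
  if (length(clean) > 0) {
    rep0 <- qcStats(clean)
  } else {
    rep0 <- new("QcReport", rawBases = 0, cleanBases = 0,
                errorRate = NA_real_, q20 = NA_real_, q30 = NA_real_,
                gcContent = NA_real_, pairsIn = 0, pairsOut = 0,
                pairsDroppedAdapter = 0, pairsDroppedN = 0,
                pairsDroppedLowq = 0)
  }
  report <- new("QcReport",
    rawBases = rawBases, cleanBases = rep0@cleanBases,
    errorRate = rep0@errorRate, q20 = rep0@q20, q30 = rep0@q30,
    gcContent = rep0@gcContent,
    pairsIn = n, pairsOut = sum(keep),
    pairsDroppedAdapter = sum(droppedAdapter),
    pairsDroppedN = sum(droppedN),
    pairsDroppedLowq = sum(droppedQ))
  list(pairs = clean, report = report)
}

#' Effective rate of a library
#'
#' Clean bases over raw bases, as a percent.
#'
#' @param x A [QcReport-class], or the raw base count when `clean` is
#'   given.
#' @param clean Optional clean base count.
#' @param digits Rounding for display (default 2, matching sequencing
#'   reports); use `NA` for full precision.
#' @return numeric(1), percent.
#' @examples
#' effectiveRate(55808601300, 55699379400)
#' @export
effectiveRate <- function(x, clean = NULL, digits = 2) {
  if (is(x, "QcReport")) {
    raw <- x@rawBases
    clean <- x@cleanBases
  } else {
    raw <- x
    if (is.null(clean)) stop("supply a QcReport or raw and clean counts")
  }
  if (raw <= 0) stop("raw base count must be positive")
  r <- 100 * clean / raw
  if (is.na(digits)) r else round(r, digits)
}

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n")
  cat(sprintf("  raw bases:   %s\n  clean bases: %s (effective %.2f%%)\n",
              format(object@rawBases, big.mark = ","),
              format(object@cleanBases, big.mark = ","),
              effectiveRate(object, digits = NA)))
  cat(sprintf("  error %.4f%%  Q20 %.2f%%  Q30 %.2f%%  GC %.2f%%\n",
              object@errorRate, object@q20, object@q30, object@gcContent))
  cat(sprintf("  pairs: %d in, %d out (adapter %d, N %d, low-quality %d)\n",
              as.integer(object@pairsIn), as.integer(object@pairsOut),
              as.integer(object@pairsDroppedAdapter),
              as.integer(object@pairsDroppedN),
              as.integer(object@pairsDroppedLowq)))
})

#' Serialize a QcReport
#'
#' Writes the report as JSON plus a one-row TSV with the columns of a
#' standard sequencing summary table (raw/clean bases, effective rate,
#' error rate, Q20, Q30, GC), percents rounded to 2 decimals.
#'
#' @param report A [QcReport-class].
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
writeQcReport <- function(report, prefix) {
  row <- qcReportRow(report)
  tsv <- paste0(prefix, ".tsv")
  write.table(row, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  write_json(as.list(row), js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}

qcReportRow <- function(report) {
  data.frame(
    raw_bases = report@rawBases,
    effective_rate = round(effectiveRate(report, digits = NA), 2),
    clean_bases = report@cleanBases,
    error_rate = round(report@errorRate, 2),
    q20 = round(report@q20, 2),
    q30 = round(report@q30, 2),
    gc_content = round(report@gcContent, 2),
    pairs_dropped_adapter = report@pairsDroppedAdapter,
    pairs_dropped_n = report@pairsDroppedN,
    pairs_dropped_lowq = report@pairsDroppedLowq
  )
}
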