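#' In-memory canonical k-mer index
#'
#' Wraps a native hash map from packed canonical k-mer codes to counts.
#' Built by [kmerIndex()]; query per-window counts with [kmerCounts()].
#' The pointer is session-local and cannot be saved to disk.
#'
#' @slot ptr external pointer to the native map.
#' @slot k integer(1). Word size.
#' @export
setClass("KmerIndex", slots = c(ptr = "externalptr", k = "integer"))

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k = %d, %s distinct canonical k-mers\n",
              object@k,
              format(cpp_kmer_index_size(object@ptr), big.mark = ",")))
})

#' @describeIn KmerIndex-class Word size.
#' @param x A `KmerIndex`.
#' @export
setMethod("kmerSize", "KmerIndex", function(x) x@k)

inputToSequences <- function(x) {
  if (is(x, "ReadPairs"))
    return(c(as.character(x@seq1), as.character(x@seq2)))
  if (is(x, "XStringSet"))
    return(as.character(x))
  if (is(x, "XString"))
    return(as.character(x))
  if (is.character(x)) {
    if (length(x) > 0 && all(file.exists(x))) {
      seqs <- unlist(lapply(x, function(f) {
        ext <- sub("\\.gz$", "", basename(f))
        fmt <- if (grepl("\\.(fq|fastq)$", ext)) "fastq" else "fasta"
        as.character(readDNAStringSet(f, format = fmt))
      }))
      return(unname(seqs))
    }
    return(x)
  }
  stop("unsupported sequence input of class ", class(x)[1])
}

checkK <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L)
    stop("k must be an integer in [1, 31]")
  k
}

#' @rdname kmerIndex
#' @export
setMethod("kmerIndex", "ANY", function(x, k = 17L) {
  k <- checkK(k)
  seqs <- inputToSequences(x)
  new("KmerIndex", ptr = cpp_kmer_index(seqs, k), k = k)
})

#' Per-window k-mer counts of a sequence in an index
#'
#' @param index A [KmerIndex-class].
#' @param sequence A single sequence (character or
#'   [Biostrings::DNAString]).
#' @return numeric vector of length `nchar(sequence) - k + 1`; windows
#'   containing non-ACGT characters are `NA`.
#' @export
kmerCounts <- function(index, sequence) {
  stopifnot(is(index, "KmerIndex"))
  cpp_kmer_query(index@ptr, as.character(sequence), index@k)
}

#' Construct a KmerHistogram
#'
#' @param depth integer vector of occurrence counts.
#' @param species numeric vector of distinct-k-mer counts per depth.
#' @param k Word size.
#' @return A [KmerHistogram-class]; depths are aggregated and sorted.
#' @export
KmerHistogram <- function(depth, species, k = 17L) {
  k <- checkK(k)
  depth <- as.integer(depth)
  species <- as.numeric(species)
  keep <- species != 0
  depth <- depth[keep]
  species <- species[keep]
  if (anyDuplicated(depth)) {
    species <- as.numeric(tapply(species, depth, sum))
    depth <- sort(unique(depth))
  } else {
    o <- order(depth)
    depth <- depth[o]
    species <- species[o]
  }
  obj <- new("KmerHistogram", k = k, depth = depth, species = species)
  validObject(obj)
  obj
}

#' @rdname countKmers
#' @export
setMethod("countKmers", "ANY", function(x, k = 17L) {
  if (is(x, "KmerIndex")) {
    h <- cpp_kmer_histogram(x@ptr)
    return(KmerHistogram(h$depth, h$species, k = x@k))
  }
  idx <- kmerIndex(x, k)
  h <- cpp_kmer_histogram(idx@ptr)
  KmerHistogram(h$depth, h$species, k = idx@k)
})

setMethod("show", "KmerHistogram", function(object) {
  cat(sprintf(
    "KmerHistogram: k = %d, %s species, %s individuals, depths %s..%s\n",
    object@k, format(totalSpecies(object), big.mark = ","),
    format(totalIndividuals(object), big.mark = ","),
    if (length(object@depth)) min(object@depth) else "-",
    if (length(object@depth)) max(object@depth) else "-"))
})

#' @rdname totalIndividuals
#' @export
setMethod("totalIndividuals", "KmerHistogram", function(x)
  sum(as.numeric(x@depth) * x@species))

#' @rdname totalSpecies
#' @export
setMethod("totalSpecies", "KmerHistogram", function(x) sum(x@species))

#' @rdname kmerSize
#' @export
setMethod("kmerSize", "KmerHistogram", function(x) x@k)

#' @describeIn KmerHistogram Coerce to a data.frame with columns `depth`
#'   and `species`.
#' @param x A `KmerHistogram`.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "KmerHistogram", function(x, ...)
  data.frame(depth = x@depth, species = x@species))

#' Read/write a k-mer histogram as two-column TSV
#'
#' The common k-mer-counter "histo" dialect: depth, species count, no
#' header.
#'
#' @param hist A [KmerHistogram-class] (for writing).
#' @param file Path.
#' @param k Word size to record when reading.
#' @return `writeKmerHistogram` invisibly returns `file`;
#'   `readKmerHistogram` returns a [KmerHistogram-class].
#' @export
writeKmerHistogram <- function(hist, file) {
  write.table(as.data.frame(hist), file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeKmerHistogram
#' @export
readKmerHistogram <- function(file, k = 17L) {
  d <- read.table(file, sep = "\t", header = FALSE,
                  col.names = c("depth", "species"))
  KmerHistogram(d$depth, d$species, k = k)
}

# species counts on a dense depth grid
denseSpecies <- function(hist, depths) {
  s <- numeric(length(depths))
  m <- match(hist@depth, depths)
  ok <- !is.na(m)
  s[m[ok]] <- hist@species[ok]
  s
}

#' Locate the main peak of a k-mer spectrum
#'
#' Returns the depth with the largest species count at or above
#' `minDepth`; the low-frequency (error) region below the cutoff is
#' ignored. Ties break toward the smaller depth.
#'
#' @param hist A [KmerHistogram-class].
#' @param minDepth Low-frequency cutoff; depths below it are discarded
#'   (default 6, i.e. depths <= 5 are treated as error-dominated).
#' @param smooth Apply a centered width-3 moving average before the argmax
#'   (off by default).
#' @return integer(1) peak depth.
#' @examples
#' detectPeak(KmerHistogram(c(3, 74, 75), c(1e6, 500, 499)))
#' @export
detectPeak <- function(hist, minDepth = 6L, smooth = FALSE) {
  keep <- hist@depth >= minDepth
  if (!any(keep) || sum(hist@species[keep]) == 0)
    stop("detectPeak: no histogram mass at or above minDepth")
  depths <- seq.int(minDepth, max(hist@depth[keep]))
  s <- denseSpecies(hist, depths)
  if (smooth && length(s) >= 3) {
    sm <- as.numeric(stats::filter(s, rep(1 / 3, 3), sides = 2))
    s <- ifelse(is.na(sm), s, sm)
  }
  as.integer(depths[which.max(s)])
}

#' Genome size from k-mer number and peak depth
#'
#' The basic estimator: genome size = k-mer number / peak depth.
#'
#' @param kmerNumber Total k-mer individuals after the low-frequency
#'   cutoff.
#' @param peakDepth Modal k-mer depth.
#' @return numeric(1) genome size in bases.
#' @examples
#' genomeSizeFromKmers(45374105016, 74) / 1e6  # Mbp
#' @export
genomeSizeFromKmers <- function(kmerNumber, peakDepth) {
  if (peakDepth < 1) stop("peakDepth must be >= 1")
  if (kmerNumber <= 0) stop("kmerNumber must be positive")
  kmerNumber / peakDepth
}

#' Estimate genome size from a k-mer spectrum
#'
#' k-mer number is the count of individuals at depth >= `minDepth`;
#' genome size = k-mer number / peak depth. The erroneous-k-mer rate is
#' the discarded low-frequency fraction of all individuals, and the
#' revised genome size is `genomeSize * (1 - errorRateKmer)`.
#'
#' @param hist A [KmerHistogram-class].
#' @param peakDepth Peak depth (from [detectPeak()]).
#' @param minDepth Low-frequency cutoff.
#' @return list with `genomeSize`, `kmerNumber`, `errorRateKmer`,
#'   `revisedGenomeSize` (bases / counts / fraction / bases).
#' @export
estimateGenomeSize <- function(hist, peakDepth, minDepth = 6L) {
  if (peakDepth < 1) stop("peakDepth must be >= 1")
  keep <- hist@depth >= minDepth
  ind <- as.numeric(hist@depth) * hist@species
  kmerNumber <- sum(ind[keep])
  if (kmerNumber == 0) stop("estimateGenomeSize: zero k-mer number")
  allInd <- sum(ind)
  errorRate <- sum(ind[!keep]) / allInd
  genomeSize <- genomeSizeFromKmers(kmerNumber, peakDepth)
  list(genomeSize = genomeSize, kmerNumber = kmerNumber,
       errorRateKmer = errorRate,
       revisedGenomeSize = genomeSize * (1 - errorRate))
}

#' Fraction of heterozygous k-mer species from the half-depth peak
#'
#' In a diploid, k-mers spanning a SNP occur on only one haplotype and sit
#' at half the homozygous depth. This fits a two-component mixture of
#' depth kernels centered at `peakDepth / 2` and `peakDepth` to the
#' species counts between `minDepth` and `multiplier * peakDepth`
#' (weighted least squares on the curve, with the overall scale profiled
#' out) and returns the heterozygous mixture weight.
#'
#' @param hist A [KmerHistogram-class].
#' @param peakDepth Homozygous peak depth (>= 4).
#' @param minDepth Low-frequency cutoff.
#' @param multiplier Upper bound of the fit range as a multiple of the
#'   peak (default 1.8, the repeat cutoff).
#' @param overdispersed Use a negative-binomial kernel with variance
#'   2 * mean instead of a Poisson kernel.
#' @return numeric(1), the heterozygous species fraction `aHalf` in
#'   \[0, 1\].
#' @export
estimateHetFraction <- function(hist, peakDepth, minDepth = 6L,
                                multiplier = 1.8, overdispersed = FALSE) {
  if (peakDepth < 4) stop("estimateHetFraction: peakDepth must be >= 4")
  depths <- seq.int(minDepth, max(minDepth, floor(multiplier * peakDepth)))
  s <- denseSpecies(hist, depths)
  if (sum(s) == 0)
    stop("estimateHetFraction: no species in the fit range [",
         minDepth, ", ", max(depths), "]")
  kern <- function(mu) {
    if (overdispersed) dnbinom(depths, mu = mu, size = mu)
    else dpois(depths, mu)
  }
  g1 <- kern(peakDepth)      # homozygous component
  g2 <- kern(peakDepth / 2)  # heterozygous (half-depth) component
  sse <- function(w) {
    g <- (1 - w) * g1 + w * g2
    nHat <- sum(s * g) / sum(g * g)
    sum((s - nHat * g)^2)
  }
  fit <- optimize(sse, c(0, 1))
  aHalf <- min(1, max(0, fit$minimum))
  if (!is.finite(aHalf))
    stop("estimateHetFraction: degenerate histogram, fit failed")
  aHalf
}

#' Per-base heterozygosity from the heterozygous k-mer fraction
#'
#' Each SNP contributes 2k heterozygous k-mer species while removing k
#' homozygous species, which gives
#' `heterozygosity = aHalf / (k * (2 - aHalf))`.
#'
#' @param aHalf Heterozygous k-mer species fraction in \[0, 1\].
#' @param k Word size.
#' @return numeric, per-base SNP rate (fraction). Vectorized over
#'   `aHalf`.
#' @examples
#' heterozygosityRate(0.1, 17)
#' @export
heterozygosityRate <- function(aHalf, k) {
  if (any(is.na(aHalf)) || any(aHalf < 0) || any(aHalf > 1))
    stop("aHalf must lie in [0, 1]")
  if (k < 1) stop("k must be >= 1")
  aHalf / (k * (2 - aHalf))
}

#' Repeat ratio from the high-depth tail
#'
#' Fraction of k-mer individuals at depth strictly beyond
#' `multiplier * peakDepth`, relative to the individuals retained after
#' the low-frequency cutoff — a proxy for the repetitive genome fraction.
#'
#' @param hist A [KmerHistogram-class].
#' @param peakDepth Peak depth.
#' @param multiplier Tail cutoff as a multiple of the peak (default 1.8).
#' @param minDepth Low-frequency cutoff.
#' @return numeric(1) in \[0, 1\].
#' @export
repeatRatio <- function(hist, peakDepth, multiplier = 1.8, minDepth = 6L) {
  if (peakDepth < 1) stop("peakDepth must be >= 1")
  ind <- as.numeric(hist@depth) * hist@species
  denom <- sum(ind[hist@depth >= minDepth])
  if (denom == 0) stop("repeatRatio: no individuals above the cutoff")
  sum(ind[hist@depth > multiplier * peakDepth]) / denom
}

#' Run the full k-mer survey
#'
#' Composes counting, peak detection, genome size, heterozygosity and
#' repeat content into one set of estimates (one survey-table row).
#'
#' @param x Read input accepted by [countKmers()] (FASTQ paths,
#'   [ReadPairs-class], sequences) or an already-computed
#'   [KmerHistogram-class].
#' @param k Word size (default 17).
#' @param minDepth Low-frequency cutoff (default 6).
#' @param multiplier Repeat / fit-range multiplier (default 1.8).
#' @param overdispersed Passed to [estimateHetFraction()].
#' @return A [SurveyEstimates-class].
#' @export
runSurvey <- function(x, k = 17L, minDepth = 6L, multiplier = 1.8,
                      overdispersed = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("survey stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  hist <- if (is(x, "KmerHistogram")) x
          else stage("count", countKmers(x, k))
  if (length(hist@depth) == 0)
    stop("survey stage 'count': no k-mers counted (empty input?)")
  peak <- stage("peak", detectPeak(hist, minDepth))
  gs <- stage("size", estimateGenomeSize(hist, peak, minDepth))
  aHalf <- stage("het", estimateHetFraction(hist, peak, minDepth,
                                            multiplier, overdispersed))
  het <- stage("het", heterozygosityRate(aHalf, hist@k))
  rr <- stage("repeat", repeatRatio(hist, peak, multiplier, minDepth))
  nKspecies <- sum(hist@species[hist@depth >= minDepth])
  new("SurveyEstimates",
      k = hist@k, peakDepth = peak,
      kmerNumber = gs$kmerNumber, nKspecies = nKspecies, aHalf = aHalf,
      genomeSize = gs$genomeSize, errorRateKmer = gs$errorRateKmer,
      revisedGenomeSize = gs$revisedGenomeSize,
      heterozygosityRate = het, repeatRatio = rr)
}

setMethod("show", "SurveyEstimates", function(object) {
  cat("SurveyEstimates\n")
  cat(sprintf("  k = %d, peak depth = %d\n", object@k, object@peakDepth))
  cat(sprintf("  k-mer number:        %s\n",
              format(object@kmerNumber, big.mark = ",")))
  cat(sprintf("  genome size:         %.2f Mbp\n", object@genomeSize / 1e6))
  cat(sprintf("  revised genome size: %.2f Mbp\n",
              object@revisedGenomeSize / 1e6))
  cat(sprintf("  heterozygosity:      %.2f%%\n",
              100 * object@heterozygosityRate))
  cat(sprintf("  repeat ratio:        %.2f%%\n", 100 * object@repeatRatio))
})

surveyEstimatesRow <- function(est) {
  data.frame(
    k = est@k,
    kmer_depth = est@peakDepth,
    kmer_number = est@kmerNumber,
    genome_size_mbp = round(est@genomeSize / 1e6, 2),
    revised_genome_size_mbp = round(est@revisedGenomeSize / 1e6, 2),
    heterozygous_ratio_pct = round(100 * est@heterozygosityRate, 2),
    repeat_pct = round(100 * est@repeatRatio, 2)
  )
}

#' Serialize SurveyEstimates
#'
#' JSON (full precision) plus a one-row TSV with the survey-table columns
#' (Mbp and percents rounded to 2 decimals).
#'
#' @param est A [SurveyEstimates-class].
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
writeSurveyEstimates <- function(est, prefix) {
  tsv <- paste0(prefix, ".tsv")
  write.table(surveyEstimatesRow(est), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  js <- paste0(prefix, ".json")
  nms <- slotNames("SurveyEstimates")
  write_json(setNames(lapply(nms, function(n) slot(est, n)), nms), js,
             auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
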