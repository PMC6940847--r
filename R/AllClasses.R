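#' Parameterization of a synthetic diploid genome and read set
#'
#' A `SimulationSpec` fully determines a simulated survey input: a diploid
#' genome with known SNP heterozygosity, exact repeat copies and target GC
#' content, plus uniformly sampled paired-end reads with a constant-quality
#' substitution error model. Identical specs (including `seed`) yield
#' bit-identical output.
#'
#' @slot genomeLength numeric(1). Haploid genome length in bases.
#' @slot gcFraction numeric(1) in \[0,1\]. Per-base probability of G or C.
#' @slot hetRate numeric(1) in \[0,1\]. Per-base SNP probability between the
#'   two haplotypes.
#' @slot repeatFraction numeric(1) in \[0,1\]. Fraction of the genome
#'   occupied by exact dispersed repeat families (2-5 copies each).
#' @slot repeatUnitLength numeric(1). Length in bases of each repeat copy.
#' @slot coverage numeric(1) > 0. Total sequencing depth (fold) over the
#'   diploid sample.
#' @slot readLength numeric(1). Read length in bases (default 150).
#' @slot insertSize numeric(1). Fragment (insert) size in bases (default
#'   350).
#' @slot baseErrorRate numeric(1) in \[0,1\]. Per-base substitution error
#'   probability.
#' @slot nFractionContaminated numeric(1) in \[0,1\]. Fraction of pairs to
#'   corrupt with N runs (for QC tests).
#' @slot lowqFractionContaminated numeric(1) in \[0,1\]. Fraction of pairs
#'   to corrupt with sub-Q5 qualities.
#' @slot seed integer(1). RNG seed.
#'
#' @seealso [SimulationSpec()], [simulateDiploidGenome()],
#'   [simulateReads()], [injectArtifacts()]
#' @export
setClass("SimulationSpec",
  slots = c(
    genomeLength = "numeric",
    gcFraction = "numeric",
    hetRate = "numeric",
    repeatFraction = "numeric",
    repeatUnitLength = "numeric",
    coverage = "numeric",
    readLength = "numeric",
    insertSize = "numeric",
    baseErrorRate = "numeric",
    nFractionContaminated = "numeric",
    lowqFractionContaminated = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  chkFrac <- function(name) {
    x <- slot(object, name)
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      sprintf("%s must be a single value in [0, 1]", name)
    else
      NULL
  }
  msgs <- c(
    chkFrac("gcFraction"), chkFrac("hetRate"), chkFrac("repeatFraction"),
    chkFrac("baseErrorRate"), chkFrac("nFractionContaminated"),
    chkFrac("lowqFractionContaminated")
  )
  if (object@coverage <= 0)
    msgs <- c(msgs, "coverage must be > 0")
  if (object@genomeLength < 2 * object@insertSize)
    msgs <- c(msgs, "genomeLength must be at least 2 * insertSize")
  if (object@readLength > object@insertSize)
    msgs <- c(msgs, "readLength must not exceed insertSize")
  if (object@readLength < 1)
    msgs <- c(msgs, "readLength must be >= 1")
  if (object@repeatUnitLength < 1)
    msgs <- c(msgs, "repeatUnitLength must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated diploid genome
#'
#' @slot haplotypeA,haplotypeB [Biostrings::DNAString] haplotypes of equal
#'   length; B differs from A only at `snpPositions`.
#' @slot snpPositions integer. 1-based positions where the haplotypes
#'   differ, strictly increasing.
#' @slot plantedRepeats data.frame with columns `family`, `position`,
#'   `length`, `copyCount` describing each placed repeat copy.
#' @slot realizedGc numeric(1). Realized GC fraction of haplotype A.
#' @export
setClass("DiploidTruth",
  slots = c(
    haplotypeA = "DNAString",
    haplotypeB = "DNAString",
    snpPositions = "integer",
    plantedRepeats = "data.frame",
    realizedGc = "numeric"
  )
)

setValidity("DiploidTruth", function(object) {
  msgs <- character()
  if (length(object@haplotypeA) != length(object@haplotypeB))
    msgs <- c(msgs, "haplotypes must have equal length")
  if (is.unsorted(object@snpPositions, strictly = TRUE))
    msgs <- c(msgs, "snpPositions must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Paired-end reads with per-base qualities
#'
#' A container for paired short reads: mate sequences as
#' [Biostrings::DNAStringSet] and Phred+33 quality strings as
#' [Biostrings::BStringSet]. The `corrupted` slot tags pairs deliberately
#' damaged by [injectArtifacts()] (`"none"`, `"n"` or `"lowq"`).
#'
#' @slot id character. Pair identifiers.
#' @slot seq1,seq2 [Biostrings::DNAStringSet]. Mate 1 / mate 2 sequences.
#' @slot qual1,qual2 [Biostrings::BStringSet]. Phred+33 quality strings.
#' @slot corrupted character. Artifact tag per pair.
#' @export
setClass("ReadPairs",
  slots = c(
    id = "character",
    seq1 = "DNAStringSet",
    seq2 = "DNAStringSet",
    qual1 = "BStringSet",
    qual2 = "BStringSet",
    corrupted = "character"
  )
)

setValidity("ReadPairs", function(object) {
  n <- length(object@id)
  msgs <- character()
  if (length(object@seq1) != n || length(object@seq2) != n ||
      length(object@qual1) != n || length(object@qual2) != n ||
      length(object@corrupted) != n)
    msgs <- c(msgs, "all slots must have the same length")
  else {
    if (any(width(object@seq1) != width(object@qual1)) ||
        any(width(object@seq2) != width(object@qual2)))
      msgs <- c(msgs, "sequence and quality widths differ")
  }
  if (length(msgs)) msgs else TRUE
})

#' k-mer depth histogram
#'
#' The depth-to-species-count table of canonical k-mer multiplicities in a
#' read set or sequence collection: `species[i]` distinct k-mers each occur
#' exactly `depth[i]` times. Individuals at a depth are
#' `depth * species`.
#'
#' @slot k integer(1). Word size (1..31).
#' @slot depth integer. Occurrence counts (>= 1), strictly increasing.
#' @slot species numeric. Number of distinct k-mers at each depth.
#' @seealso [countKmers()], [detectPeak()], [estimateGenomeSize()]
#' @export
setClass("KmerHistogram",
  slots = c(k = "integer", depth = "integer", species = "numeric")
)

setValidity("KmerHistogram", function(object) {
  msgs <- character()
  if (object@k < 1 || object@k > 31)
    msgs <- c(msgs, "k must be in [1, 31]")
  if (length(object@depth) != length(object@species))
    msgs <- c(msgs, "depth and species lengths differ")
  if (length(object@depth) && (any(object@depth < 1) ||
      is.unsorted(object@depth, strictly = TRUE)))
    msgs <- c(msgs, "depth must be strictly increasing and >= 1")
  if (any(object@species < 0))
    msgs <- c(msgs, "species counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Read-pair quality control accounting
#'
#' One library's QC summary: raw and clean base totals, effective rate,
#' quality-derived error rate, Q20/Q30 percentages, GC content and per-rule
#' dropped-pair counts.
#'
#' @slot rawBases,cleanBases numeric(1). Base totals before/after filtering.
#' @slot errorRate numeric(1). Mean per-base error probability implied by
#'   qualities, as a percent.
#' @slot q20,q30 numeric(1). Percent of clean bases with quality >= 20 / 30.
#' @slot gcContent numeric(1). Percent of non-N clean bases that are G or C.
#' @slot pairsIn,pairsOut numeric(1). Pair counts before/after filtering.
#' @slot pairsDroppedAdapter,pairsDroppedN,pairsDroppedLowq numeric(1).
#'   Pairs dropped by each rule (first failing rule counts).
#' @export
setClass("QcReport",
  slots = c(
    rawBases = "numeric", cleanBases = "numeric",
    errorRate = "numeric", q20 = "numeric", q30 = "numeric",
    gcContent = "numeric",
    pairsIn = "numeric", pairsOut = "numeric",
    pairsDroppedAdapter = "numeric", pairsDroppedN = "numeric",
    pairsDroppedLowq = "numeric"
  )
)

setValidity("QcReport", function(object) {
  msgs <- character()
  if (object@cleanBases > object@rawBases)
    msgs <- c(msgs, "cleanBases must not exceed rawBases")
  pct <- c(object@q20, object@q30, object@gcContent)
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    msgs <- c(msgs, "percentages must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' Genome survey estimates from a k-mer spectrum
#'
#' One full set of survey statistics for a library: peak depth, k-mer
#' number after the low-frequency cutoff, genome size (k-mer number /
#' peak depth), the erroneous-k-mer rate and revised genome size,
#' heterozygous k-mer species fraction and derived per-base heterozygosity
#' rate, and the repeat ratio from the high-depth tail.
#'
#' @slot k integer(1). Word size.
#' @slot peakDepth integer(1). Modal k-mer depth above the cutoff.
#' @slot kmerNumber numeric(1). k-mer individuals at depth >= cutoff.
#' @slot nKspecies numeric(1). k-mer species at depth >= cutoff.
#' @slot aHalf numeric(1). Fitted fraction of heterozygous (half-depth)
#'   k-mer species.
#' @slot genomeSize numeric(1). Estimated genome size in bases.
#' @slot errorRateKmer numeric(1). Fraction of k-mer individuals below the
#'   cutoff (attributed to sequencing error).
#' @slot revisedGenomeSize numeric(1). genomeSize * (1 - errorRateKmer).
#' @slot heterozygosityRate numeric(1). Per-base SNP rate (fraction).
#' @slot repeatRatio numeric(1). Fraction of k-mer individuals beyond the
#'   repeat multiplier times the peak.
#' @export
setClass("SurveyEstimates",
  slots = c(
    k = "integer", peakDepth = "integer",
    kmerNumber = "numeric", nKspecies = "numeric", aHalf = "numeric",
    genomeSize = "numeric", errorRateKmer = "numeric",
    revisedGenomeSize = "numeric", heterozygosityRate = "numeric",
    repeatRatio = "numeric"
  )
)

setValidity("SurveyEstimates", function(object) {
  msgs <- character()
  if (!is.na(object@aHalf) && (object@aHalf < 0 || object@aHalf > 1))
    msgs <- c(msgs, "aHalf must lie in [0, 1]")
  if (!is.na(object@repeatRatio) &&
      (object@repeatRatio < 0 || object@repeatRatio > 1))
    msgs <- c(msgs, "repeatRatio must lie in [0, 1]")
  if (!is.na(object@revisedGenomeSize) && !is.na(object@genomeSize) &&
      object@revisedGenomeSize > object@genomeSize)
    msgs <- c(msgs, "revisedGenomeSize must not exceed genomeSize")
  if (length(msgs)) msgs else TRUE
})

#' Microsatellite (SSR) summary statistics
#'
#' @slot sequencesExamined,totalSsrs,sequencesWithSsr,sequencesWithMoreThanOne,compoundSsrs,ssrsInCompound numeric(1)
#'   counts mirroring the usual MISA summary.
#' @slot unitLengthCounts numeric. Perfect-locus counts by unit length 1..6.
#' @slot unitLengthPercents numeric. Shares of `totalSsrs`, as percents.
#' @slot classCounts numeric. Named counts per canonical motif class.
#' @export
setClass("SsrSummary",
  slots = c(
    sequencesExamined = "numeric", totalSsrs = "numeric",
    sequencesWithSsr = "numeric", sequencesWithMoreThanOne = "numeric",
    compoundSsrs = "numeric", ssrsInCompound = "numeric",
    unitLengthCounts = "numeric", unitLengthPercents = "numeric",
    classCounts = "numeric"
  )
)

#' Result of screening one marker against one target
#'
#' @slot markerId character(1).
#' @slot present logical(1). Containment at or above the presence
#'   threshold.
#' @slot kmerContainment numeric(1). Fraction of the marker's canonical
#'   k-mers found in the target.
#' @slot bestIdentity numeric(1). Percent identity of the best global
#'   alignment against an assembled target, or NA when screened against an
#'   unassembled index.
#' @slot bestLocation character(1). "seqid:start-end" of the best match, or
#'   NA.
#' @export
setClass("MarkerHit",
  slots = c(
    markerId = "character", present = "logical",
    kmerContainment = "numeric", bestIdentity = "numeric",
    bestLocation = "character"
  )
)

#' Consolidated survey report
#'
#' @slot qc [QcReport-class] for the library.
#' @slot estimates [SurveyEstimates-class] from the k-mer spectrum.
#' @slot ssrSummary [SsrSummary-class] or NULL when no assembly was given.
#' @slot gcDepthPath character(1). Path of the written GC/depth table, or
#'   NA.
#' @slot markerHits list of [MarkerHit-class].
#' @slot provenance list. Inputs, parameters, seed and package version.
#' @export
setClass("SurveyReport",
  slots = c(
    qc = "QcReport", estimates = "SurveyEstimates",
    ssrSummary = "ANY", gcDepthPath = "character",
    markerHits = "list", provenance = "list"
  )
)
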