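#' Total k-mer individuals in a histogram
#'
#' Individuals are occurrence-weighted counts: `sum(depth * species)`.
#'
#' @param x A [KmerHistogram-class].
#' @return numeric(1).
#' @export
setGeneric("totalIndividuals", function(x) standardGeneric("totalIndividuals"))

#' Total k-mer species in a histogram
#'
#' @param x A [KmerHistogram-class].
#' @return numeric(1).
#' @export
setGeneric("totalSpecies", function(x) standardGeneric("totalSpecies"))

#' Word size of a k-mer object
#'
#' @param x A [KmerHistogram-class] or [KmerIndex-class].
#' @return integer(1).
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' Count canonical k-mers
#'
#' Counts canonical (strand-collapsed) k-mers — the lexicographically
#' smaller of each word and its reverse complement — over all input
#' sequences. Windows containing non-ACGT characters (e.g. N) are skipped.
#'
#' @param x Sequences: a character vector, a [Biostrings::DNAStringSet], a
#'   [ReadPairs-class] object (both mates are counted), or paths to
#'   FASTA/FASTQ files (optionally gzipped).
#' @param k integer(1). Word size, 1..31 (default 17).
#' @return A [KmerHistogram-class].
#' @examples
#' countKmers("ACGTACGTACGTACGTA", k = 17)
#' @export
setGeneric("countKmers", function(x, k = 17L) standardGeneric("countKmers"))

#' Build a queryable canonical k-mer index
#'
#' Unlike [countKmers()], the index retains per-k-mer multiplicities so
#' individual sequences can be looked up (window depth, marker
#' containment). The index lives in memory only and cannot be serialized.
#'
#' @inheritParams countKmers
#' @return A [KmerIndex-class].
#' @export
setGeneric("kmerIndex", function(x, k = 17L) standardGeneric("kmerIndex"))
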