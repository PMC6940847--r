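#' k-mer containment of a marker in a target
#'
#' Fraction of the marker's canonical k-mers (N-free windows) present at
#' least once in the target's k-mer index — a fast presence screen that
#' works on unassembled read sets.
#'
#' @param marker Marker sequence (character, [Biostrings::DNAString], or a
#'   length-1 [Biostrings::DNAStringSet]).
#' @param index A [KmerIndex-class] built from the target (reads or
#'   assembly).
#' @return numeric(1) in \[0, 1\].
#' @export
kmerContainment <- function(marker, index) {
  stopifnot(is(index, "KmerIndex"))
  if (is(marker, "DNAStringSet")) marker <- marker[[1]]
  marker <- as.character(marker)
  if (nchar(marker) < index@k)
    stop("marker (", nchar(marker), " bp) is shorter than k = ", index@k)
  counts <- kmerCounts(index, marker)
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0)
    stop("marker has no N-free k-mer windows")
  mean(counts >= 1)
}

#' Percent identity of a global alignment
#'
#' Needleman-Wunsch global alignment (defaults: match +1, mismatch -1, gap
#' -2 per base) via [Biostrings::pairwiseAlignment]; identity is 100 x
#' matches / alignment columns (gaps included).
#'
#' @param a,b Sequences (character or [Biostrings::DNAString]).
#' @param match,mismatch Substitution scores.
#' @param gap Per-base gap penalty (score contribution, i.e. negative).
#' @return numeric(1) percent in \[0, 100\].
#' @examples
#' percentIdentity("ACGTACGT", "ACGTACGT")
#' @export
percentIdentity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as.character(a)
  b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                      baseOnly = TRUE)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
                           substitutionMatrix = mat,
                           gapOpening = 0, gapExtension = -gap)
  cols <- nchar(as.character(alignedPattern(aln)))
  100 * nmatch(aln) / cols
}

MarkerHit <- function(markerId, present, containment,
                      bestIdentity = NA_real_,
                      bestLocation = NA_character_) {
  new("MarkerHit", markerId = markerId, present = present,
      kmerContainment = containment, bestIdentity = bestIdentity,
      bestLocation = bestLocation)
}

setMethod("show", "MarkerHit", function(object) {
  cat(sprintf("MarkerHit '%s': %s (containment %.3f%s%s)\n",
              object@markerId,
              if (object@present) "present" else "absent",
              object@kmerContainment,
              if (is.na(object@bestIdentity)) ""
              else sprintf(", identity %.1f%%", object@bestIdentity),
              if (is.na(object@bestLocation)) ""
              else paste0(" at ", object@bestLocation)))
})

asMarkerIndex <- function(target, k) {
  if (is(target, "KmerIndex")) {
    if (target@k != k)
      stop("target index k (", target@k, ") does not match k = ", k)
    return(target)
  }
  kmerIndex(target, k)
}

#' Screen a candidate sex-linked marker against two targets
#'
#' Computes k-mer containment of the marker in a male and a female target
#' (read sets or assemblies). The marker is called present when
#' containment reaches `presenceThreshold` and absent when containment is
#' below `1 - presenceThreshold`; `sexSpecific` (male-specific) requires
#' presence in the male and absence in the female, `femaleSpecific` the
#' converse.
#'
#' @param marker Marker sequence, or a FASTA path / named
#'   [Biostrings::DNAStringSet] (first sequence is used).
#' @param maleTarget,femaleTarget [KmerIndex-class] objects or any input
#'   [kmerIndex()] accepts.
#' @param k Word size (default 17); must match prebuilt indexes.
#' @param presenceThreshold Containment needed to call presence (default
#'   0.5).
#' @return list with elements `male`, `female` ([MarkerHit-class]),
#'   `sexSpecific` and `femaleSpecific` (logicals).
#' @export
screenMarker <- function(marker, maleTarget, femaleTarget, k = 17L,
                         presenceThreshold = 0.5) {
  k <- checkK(k)
  markerId <- "marker"
  if (is.character(marker) && length(marker) == 1 && file.exists(marker))
    marker <- readDNAStringSet(marker)
  if (is(marker, "DNAStringSet")) {
    if (!is.null(names(marker))) markerId <- names(marker)[1]
    marker <- marker[[1]]
  }
  maleIdx <- asMarkerIndex(maleTarget, k)
  femaleIdx <- asMarkerIndex(femaleTarget, k)
  cM <- kmerContainment(marker, maleIdx)
  cF <- kmerContainment(marker, femaleIdx)
  hitM <- MarkerHit(markerId, cM >= presenceThreshold, cM)
  hitF <- MarkerHit(markerId, cF >= presenceThreshold, cF)
  list(male = hitM, female = hitF,
       sexSpecific = hitM@present && cF < 1 - presenceThreshold,
       femaleSpecific = hitF@present && cM < 1 - presenceThreshold)
}
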