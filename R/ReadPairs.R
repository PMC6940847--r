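#' Construct a ReadPairs container
#'
#' @param seq1,seq2 Mate sequences: character vectors or
#'   [Biostrings::DNAStringSet].
#' @param qual1,qual2 Phred+33 quality strings (character or
#'   [Biostrings::BStringSet]), same widths as the sequences.
#' @param id Pair identifiers; generated when omitted.
#' @param corrupted Optional artifact tags (see [injectArtifacts()]).
#' @return A [ReadPairs-class] object.
#' @examples
#' ReadPairs("ACGT", "TTTT", "IIII", "IIII")
#' @export
ReadPairs <- function(seq1, seq2, qual1, qual2, id = NULL, corrupted = NULL) {
  seq1 <- as(seq1, "DNAStringSet")
  seq2 <- as(seq2, "DNAStringSet")
  qual1 <- as(qual1, "BStringSet")
  qual2 <- as(qual2, "BStringSet")
  n <- length(seq1)
  if (is.null(id)) id <- sprintf("pair_%06d", seq_len(n))
  if (is.null(corrupted)) corrupted <- rep("none", n)
  new("ReadPairs", id = as.character(id), seq1 = seq1, seq2 = seq2,
      qual1 = qual1, qual2 = qual2, corrupted = corrupted)
}

#' @describeIn ReadPairs Number of pairs.
#' @param x A `ReadPairs` object.
#' @export
setMethod("length", "ReadPairs", function(x) length(x@id))

#' @describeIn ReadPairs Subset pairs.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ReadPairs", function(x, i, j, ..., drop = TRUE) {
  new("ReadPairs", id = x@id[i], seq1 = x@seq1[i], seq2 = x@seq2[i],
      qual1 = x@qual1[i], qual2 = x@qual2[i], corrupted = x@corrupted[i])
})

setMethod("show", "ReadPairs", function(object) {
  cat(sprintf("ReadPairs with %d pairs (%s total bases)\n",
              length(object),
              format(sum(width(object@seq1)) + sum(width(object@seq2)),
                     big.mark = ",")))
})

#' Artifact tags of a ReadPairs object
#'
#' @param x A [ReadPairs-class] object.
#' @return character vector ("none", "n" or "lowq" per pair).
#' @export
corruptionTags <- function(x) {
  stopifnot(is(x, "ReadPairs"))
  x@corrupted
}

#' Pair identifiers
#'
#' @param x A [ReadPairs-class] object.
#' @return character vector.
#' @export
readIds <- function(x) {
  stopifnot(is(x, "ReadPairs"))
  x@id
}

#' Read paired FASTQ files
#'
#' @param file1,file2 Paths to mate 1 / mate 2 FASTQ files (optionally
#'   gzipped), in matching order.
#' @return A [ReadPairs-class] object.
#' @export
readReadPairs <- function(file1, file2) {
  readFq <- function(f) {
    # readQualityScaledDNAStringSet warns that FASTQ metadata columns are
    # dropped; the read names and qualities we need are kept
    withCallingHandlers(
      readQualityScaledDNAStringSet(f),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  r1 <- readFq(file1)
  r2 <- readFq(file2)
  if (length(r1) != length(r2))
    stop("mate files contain different numbers of reads")
  ids <- sub("[/ ].*$", "", names(r1))
  ReadPairs(as(r1, "DNAStringSet"), as(r2, "DNAStringSet"),
            BStringSet(quality(r1)), BStringSet(quality(r2)), id = ids)
}

#' Write a ReadPairs object as paired FASTQ
#'
#' @param pairs A [ReadPairs-class] object.
#' @param file1,file2 Output paths; a `.gz` suffix triggers compression.
#' @return Invisibly, `c(file1, file2)`.
#' @export
writeReadPairs <- function(pairs, file1, file2) {
  stopifnot(is(pairs, "ReadPairs"))
  writeMate <- function(seqs, quals, file, suffix) {
    names(seqs) <- paste0(pairs@id, suffix)
    writeXStringSet(seqs, file, format = "fastq", qualities = quals,
                    compress = grepl("\\.gz$", file))
  }
  writeMate(pairs@seq1, pairs@qual1, file1, "/1")
  writeMate(pairs@seq2, pairs@qual2, file2, "/2")
  invisible(c(file1, file2))
}
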