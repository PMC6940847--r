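#' Create a SimulationSpec
#'
#' Defaults emulate a small-scale version of a typical teleost genome
#' survey: heterozygosity 0.37%, repeat fraction 27%, GC 41.8%, 150-bp
#' paired-end reads with a 350-bp insert at 70x, per-base error 0.03%.
#'
#' @param genomeLength Haploid genome length in bases.
#' @param gcFraction Target GC fraction.
#' @param hetRate Per-base SNP rate between haplotypes.
#' @param repeatFraction Fraction of the genome occupied by exact
#'   dispersed repeat copies.
#' @param repeatUnitLength Repeat copy length in bases.
#' @param coverage Total fold coverage of the diploid sample.
#' @param readLength Read length in bases.
#' @param insertSize Insert (fragment) size in bases.
#' @param baseErrorRate Per-base substitution error probability.
#' @param nFractionContaminated Fraction of pairs for [injectArtifacts()]
#'   to corrupt with N runs.
#' @param lowqFractionContaminated Fraction of pairs for
#'   [injectArtifacts()] to corrupt with sub-Q5 qualities.
#' @param seed RNG seed (integer).
#' @return A validated [SimulationSpec-class].
#' @examples
#' SimulationSpec(genomeLength = 1e5, coverage = 10, seed = 1)
#' @export
SimulationSpec <- function(genomeLength = 1e6, gcFraction = 0.418,
                           hetRate = 0.0037, repeatFraction = 0.27,
                           repeatUnitLength = 500, coverage = 70,
                           readLength = 150, insertSize = 350,
                           baseErrorRate = 0.0003,
                           nFractionContaminated = 0,
                           lowqFractionContaminated = 0, seed = 1L) {
  obj <- new("SimulationSpec",
    genomeLength = as.numeric(genomeLength),
    gcFraction = as.numeric(gcFraction), hetRate = as.numeric(hetRate),
    repeatFraction = as.numeric(repeatFraction),
    repeatUnitLength = as.numeric(repeatUnitLength),
    coverage = as.numeric(coverage), readLength = as.numeric(readLength),
    insertSize = as.numeric(insertSize),
    baseErrorRate = as.numeric(baseErrorRate),
    nFractionContaminated = as.numeric(nFractionContaminated),
    lowqFractionContaminated = as.numeric(lowqFractionContaminated),
    seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    paste0("SimulationSpec: %s bp, GC %.3f, het %.4f, repeats %.2f ",
           "(unit %d bp)\n  reads: %dx, %d bp, insert %d bp, error %.5f, ",
           "seed %d\n"),
    format(object@genomeLength, big.mark = ","), object@gcFraction,
    object@hetRate, object@repeatFraction, as.integer(object@repeatUnitLength),
    as.integer(object@coverage), as.integer(object@readLength),
    as.integer(object@insertSize), object@baseErrorRate, object@seed))
})

#' Simulate a diploid genome with known truth
#'
#' Haplotype A is drawn base by base with P(G or C) = `gcFraction`; exact
#' dispersed repeat families of 2-5 copies are then planted on disjoint
#' unit-aligned slots until `repeatFraction` of the genome consists of
#' repeat copies.
#' Haplotype B carries i.i.d. biallelic substitutions at `hetRate`.
#' Deterministic given `spec@seed`.
#'
#' @param spec A [SimulationSpec-class].
#' @return A [DiploidTruth-class].
#' @examples
#' truth <- simulateDiploidGenome(SimulationSpec(genomeLength = 1e4,
#'   coverage = 5, hetRate = 0.01, repeatFraction = 0, seed = 7))
#' length(truth@snpPositions)
#' @export
simulateDiploidGenome <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  L <- as.integer(spec@genomeLength)
  gc <- spec@gcFraction
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  planted <- data.frame(position = integer(), length = integer(),
                        copyCount = integer())
  u <- as.integer(spec@repeatUnitLength)
  targetBases <- spec@repeatFraction * L
  if (targetBases >= u) {
    # repeat families of 2..5 exact dispersed copies on disjoint
    # unit-aligned slots; every copy counts toward the repeat fraction
    needed <- max(2L, as.integer(round(targetBases / u)))
    copyCounts <- integer()
    while (sum(copyCounts) < needed) {
      rem <- needed - sum(copyCounts)
      nxt <- if (rem <= 5L) max(2L, rem) else 2L + (length(copyCounts) %% 4L)
      copyCounts <- c(copyCounts, nxt)
    }
    nSlots <- floor(L / u)
    if (sum(copyCounts) > nSlots)
      stop("repeatFraction too high for repeatUnitLength: ",
           "not enough disjoint slots")
    slots <- sample.int(nSlots, sum(copyCounts))
    fam <- rep(seq_along(copyCounts), copyCounts)
    pos <- integer(0)
    off <- 0L
    for (i in seq_along(copyCounts)) {
      fs <- slots[off + seq_len(copyCounts[i])]
      off <- off + copyCounts[i]
      from <- (fs[1] - 1L) * u + seq_len(u)
      for (d in fs[-1]) bases[(d - 1L) * u + seq_len(u)] <- bases[from]
      pos <- c(pos, (fs - 1L) * u + 1L)
    }
    planted <- data.frame(
      family = fam,
      position = as.integer(pos),
      length = u,
      copyCount = as.integer(rep(copyCounts, copyCounts)))
    planted <- planted[order(planted$position), , drop = FALSE]
    rownames(planted) <- NULL
  }

  basesB <- bases
  snp <- which(runif(L) < spec@hetRate)
  if (length(snp)) {
    # substitute with one of the three other bases, uniformly
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3, length(snp), replace = TRUE)
    basesB[snp] <- alt[cbind(match(bases[snp], rownames(alt)), pick)]
  }

  new("DiploidTruth",
      haplotypeA = DNAString(paste(bases, collapse = "")),
      haplotypeB = DNAString(paste(basesB, collapse = "")),
      snpPositions = as.integer(snp),
      plantedRepeats = planted,
      realizedGc = mean(bases %in% c("G", "C")))
}

setMethod("show", "DiploidTruth", function(object) {
  cat(sprintf(
    "DiploidTruth: %s bp, %d SNPs, %d repeat copies, GC %.4f\n",
    format(length(object@haplotypeA), big.mark = ","),
    length(object@snpPositions), nrow(object@plantedRepeats),
    object@realizedGc))
})

# constant Phred quality whose error probability matches the target rate
errorRateToPhred <- function(e) {
  if (e <= 0) return(40L)
  max(2L, min(40L, as.integer(round(-10 * log10(e)))))
}

#' Simulate paired-end reads from a diploid genome
#'
#' Draws `round(coverage * genomeLength / (2 * readLength))` fragments,
#' each from a uniformly chosen haplotype and a uniform start; mate 2 is
#' the reverse complement of the fragment end. Substitution errors occur
#' i.i.d. at `baseErrorRate`; every base gets the constant Phred quality
#' whose error probability equals that rate. Deterministic given
#' `spec@seed`.
#'
#' @param truth A [DiploidTruth-class] from [simulateDiploidGenome()].
#' @param spec The same [SimulationSpec-class].
#' @return A [ReadPairs-class]; fragment starts and source haplotypes are
#'   kept in `attr(, "fragmentStart")` and `attr(, "haplotype")` for
#'   validation.
#' @export
simulateReads <- function(truth, spec) {
  validObject(spec)
  L <- length(truth@haplotypeA)
  nPairs <- round(spec@coverage * L / (2 * spec@readLength))
  if (nPairs < 1) stop("coverage too low: no read pairs to draw")
  set.seed(spec@seed + 1L)
  sim <- cpp_simulate_reads(as.character(truth@haplotypeA),
                            as.character(truth@haplotypeB),
                            as.integer(nPairs),
                            as.integer(spec@readLength),
                            as.integer(spec@insertSize),
                            spec@baseErrorRate)
  q <- errorRateToPhred(spec@baseErrorRate)
  qstr <- strrep(rawToChar(as.raw(q + 33L)), as.integer(spec@readLength))
  pairs <- ReadPairs(sim$seq1, sim$seq2,
                     rep(qstr, nPairs), rep(qstr, nPairs),
                     id = sprintf("sim_%07d", seq_len(nPairs)))
  attr(pairs, "fragmentStart") <- sim$start
  attr(pairs, "haplotype") <- sim$hap
  pairs
}

#' Corrupt a controlled fraction of read pairs
#'
#' Marks exact fractions of pairs with the two failure modes the QC filter
#' must catch: `nFractionContaminated` pairs get `ceiling(0.1 * width)` N
#' bases in mate 1 (an N fraction of at least 10%), and
#' `lowqFractionContaminated` pairs get `floor(0.5 * width) + 1` bases of
#' mate 2 set to quality 2 (strictly more than 50% below Q5). Corrupted
#' pairs are tagged in the `corrupted` slot.
#'
#' @param pairs A [ReadPairs-class].
#' @param spec A [SimulationSpec-class] (fractions and seed are used).
#' @return A [ReadPairs-class] with tags set.
#' @export
injectArtifacts <- function(pairs, spec) {
  validObject(spec)
  n <- length(pairs)
  nN <- round(spec@nFractionContaminated * n)
  nQ <- round(spec@lowqFractionContaminated * n)
  if (nN + nQ > n)
    stop("contamination fractions sum to more than the number of pairs")
  if (nN + nQ == 0) return(pairs)
  set.seed(spec@seed + 2L)
  idx <- sample.int(n, nN + nQ)
  seq1 <- as.character(pairs@seq1)
  qual2 <- as.character(pairs@qual2)
  corrupted <- pairs@corrupted
  if (nN > 0) {
    iN <- idx[seq_len(nN)]
    w <- nchar(seq1[iN])
    nrun <- ceiling(0.1 * w)
    seq1[iN] <- paste0(strrep("N", nrun),
                       substring(seq1[iN], nrun + 1L, w))
    corrupted[iN] <- "n"
  }
  if (nQ > 0) {
    iQ <- idx[nN + seq_len(nQ)]
    w <- nchar(qual2[iQ])
    nlow <- floor(0.5 * w) + 1L
    qual2[iQ] <- paste0(strrep("#", nlow),  # '#' is Phred 2
                        substring(qual2[iQ], nlow + 1L, w))
    corrupted[iQ] <- "lowq"
  }
  ReadPairs(seq1, as.character(pairs@seq2), as.character(pairs@qual1),
            qual2, id = pairs@id, corrupted = corrupted)
}

#' Write a simulated dataset to disk
#'
#' Writes the two haplotypes as FASTA, the reads as paired FASTQ and the
#' truth (SNP positions, planted repeats, realized GC, spec parameters) as
#' JSON.
#'
#' @param truth A [DiploidTruth-class].
#' @param pairs A [ReadPairs-class].
#' @param spec The [SimulationSpec-class] used.
#' @param prefix Output path prefix.
#' @param gzip Compress the FASTQ files.
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(truth, pairs, spec, prefix, gzip = FALSE) {
  haps <- DNAStringSet(list(haplotypeA = truth@haplotypeA,
                            haplotypeB = truth@haplotypeB))
  fa <- paste0(prefix, "_haplotypes.fasta")
  writeXStringSet(haps, fa)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  fq1 <- paste0(prefix, "_1", ext)
  fq2 <- paste0(prefix, "_2", ext)
  writeReadPairs(pairs, fq1, fq2)
  js <- paste0(prefix, "_truth.json")
  write_json(list(
    snpPositions = truth@snpPositions,
    plantedRepeats = truth@plantedRepeats,
    realizedGc = truth@realizedGc,
    spec = specAsList(spec)
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(haplotypes = fa, fastq1 = fq1, fastq2 = fq2, truth = js))
}

specAsList <- function(spec) {
  nms <- slotNames("SimulationSpec")
  setNames(lapply(nms, function(nm) slot(spec, nm)), nms)
}
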