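test_that("spec validation names the offending field", {
  expect_error(SimulationSpec(hetRate = 2), "hetRate")
  expect_error(SimulationSpec(coverage = 0), "coverage")
  expect_error(SimulationSpec(genomeLength = 100, insertSize = 350),
               "genomeLength")
  expect_error(SimulationSpec(readLength = 400, insertSize = 350),
               "readLength")
})

test_that("zero het rate gives identical haplotypes", {
  truth <- simulateDiploidGenome(smallSpec(hetRate = 0))
  expect_identical(as.character(truth@haplotypeA),
                   as.character(truth@haplotypeB))
  expect_length(truth@snpPositions, 0)
})

test_that("SNP count and positions match a direct hamming oracle", {
  spec <- smallSpec(genomeLength = 1e6, hetRate = 0.0037, coverage = 1,
                    seed = 42L)
  truth <- simulateDiploidGenome(spec)
  a <- strsplit(as.character(truth@haplotypeA), "")[[1]]
  b <- strsplit(as.character(truth@haplotypeB), "")[[1]]
  mism <- which(a != b)
  expect_identical(as.integer(mism), truth@snpPositions)
  # binomial band: 3700 +- 4 * sqrt(3700 * 0.9963)
  expect_lt(abs(length(mism) - 3700), 4 * sqrt(3700 * 0.9963))
})

test_that("realized GC tracks the target for repeat-free genomes", {
  truth <- simulateDiploidGenome(smallSpec(genomeLength = 1e5,
                                           gcFraction = 0.5, seed = 5L))
  expect_gt(truth@realizedGc, 0.48)
  expect_lt(truth@realizedGc, 0.52)
  af <- Biostrings::alphabetFrequency(truth@haplotypeA, baseOnly = TRUE)
  expect_equal(truth@realizedGc, sum(af[c("G", "C")]) / sum(af))
})

test_that("planted repeats are exact copies covering the requested fraction", {
  spec <- smallSpec(genomeLength = 2e5, repeatFraction = 0.27,
                    repeatUnitLength = 500, seed = 9L)
  truth <- simulateDiploidGenome(spec)
  pr <- truth@plantedRepeats
  expect_equal(sum(pr$length), 0.27 * 2e5, tolerance = 0.02)
  # all copies within a family are identical substrings
  g <- as.character(truth@haplotypeA)
  seqs <- substring(g, pr$position, pr$position + pr$length - 1)
  identicalPerFamily <- tapply(seqs, pr$family,
                               function(s) length(unique(s)) == 1)
  expect_true(all(identicalPerFamily))
  # family sizes match the recorded copy counts
  expect_equal(as.vector(table(pr$family)[as.character(pr$family)]),
               pr$copyCount)
})

test_that("read-pair count follows round(coverage * L / (2 * readLength))", {
  spec <- smallSpec(genomeLength = 1e6, coverage = 0.0003)
  truth <- simulateDiploidGenome(spec)
  expect_equal(length(simulateReads(truth, spec)), 1)
  spec2 <- smallSpec(genomeLength = 1e4, coverage = 74)
  expect_equal(length(simulateReads(simulateDiploidGenome(spec2), spec2)),
               round(74 * 1e4 / 300))
})

test_that("error-free reads substring-match a haplotype exactly", {
  spec <- smallSpec(genomeLength = 2e4, coverage = 2, seed = 3L)
  truth <- simulateDiploidGenome(spec)
  pairs <- simulateReads(truth, spec)
  g <- Biostrings::DNAStringSet(list(a = truth@haplotypeA,
                                     b = truth@haplotypeB))
  gr <- Biostrings::reverseComplement(g)
  hit <- function(read) {
    any(Biostrings::vcountPattern(read, g) > 0) ||
      any(Biostrings::vcountPattern(read, gr) > 0)
  }
  r1 <- as.character(pairs@seq1)
  r2 <- as.character(pairs@seq2)
  expect_true(all(vapply(r1, hit, logical(1))))
  expect_true(all(vapply(r2, hit, logical(1))))
})

test_that("realized base error rate matches the model within 3 binomial SDs", {
  spec <- smallSpec(genomeLength = 5e4, coverage = 20,
                    baseErrorRate = 0.005, seed = 7L)
  truth <- simulateDiploidGenome(spec)
  pairs <- simulateReads(truth, spec)
  starts <- attr(pairs, "fragmentStart")
  haps <- attr(pairs, "haplotype")
  g <- list(as.character(truth@haplotypeA), as.character(truth@haplotypeB))
  rl <- 150L
  mism <- 0L
  for (i in seq_len(length(pairs))) {
    src <- substring(g[[haps[i]]], starts[i], starts[i] + rl - 1L)
    mism <- mism + sum(strsplit(as.character(pairs@seq1[[i]]), "")[[1]] !=
                         strsplit(src, "")[[1]])
  }
  nb <- length(pairs) * rl
  p <- mism / nb
  # per-base substitution may revert is impossible (errors always change
  # the base), so the realized rate is binomial around baseErrorRate
  expect_lt(abs(p - 0.005), 3 * sqrt(0.005 * 0.995 / nb))
})

test_that("simulation is deterministic given the seed", {
  spec <- smallSpec(seed = 123L, baseErrorRate = 0.001,
                    nFractionContaminated = 0.05)
  run <- function() {
    truth <- simulateDiploidGenome(spec)
    pairs <- injectArtifacts(simulateReads(truth, spec), spec)
    d <- tempfile()
    dir.create(d)
    writeSimulation(truth, pairs, spec, file.path(d, "sim"))
    files <- sort(list.files(d, full.names = TRUE))
    setNames(lapply(files, function(f) readLines(f)), basename(files))
  }
  expect_identical(run(), run())
})

test_that("mean k-mer depth of error-free reads matches coverage geometry", {
  spec <- smallSpec(genomeLength = 2e5, coverage = 30, seed = 2L)
  truth <- simulateDiploidGenome(spec)
  pairs <- simulateReads(truth, spec)
  hist <- countKmers(pairs, 17)
  # k-mer coverage = coverage * (readLength - k + 1) / readLength
  expKmerCov <- 30 * (150 - 17 + 1) / 150
  meanDepth <- totalIndividuals(hist) / totalSpecies(hist)
  expect_equal(meanDepth, expKmerCov, tolerance = 0.02)
})

test_that("injectArtifacts corrupts exact fractions and is identity at zero", {
  spec <- smallSpec(genomeLength = 1e5, coverage = 3, seed = 8L)
  truth <- simulateDiploidGenome(spec)
  pairs <- simulateReads(truth, spec)  # 1000 pairs
  expect_identical(length(pairs), 1000L)
  expect_identical(corruptionTags(injectArtifacts(pairs, spec)),
                   corruptionTags(pairs))
  spec2 <- smallSpec(genomeLength = 1e5, coverage = 3, seed = 8L,
                     nFractionContaminated = 0.1,
                     lowqFractionContaminated = 0.05)
  art <- injectArtifacts(pairs, spec2)
  tags <- corruptionTags(art)
  expect_equal(sum(tags == "n"), 100)
  expect_equal(sum(tags == "lowq"), 50)
  # every n-tagged pair carries >= 15 N in a 150-bp mate
  nN <- Biostrings::letterFrequency(art@seq1[tags == "n"], "N")
  expect_true(all(nN >= 15))
})
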