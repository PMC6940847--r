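test_that("counting handles degenerate windows", {
  h <- countKmers("ACGTACGTACGTACGTA", 17)  # one 17-base window
  expect_equal(as.data.frame(h), data.frame(depth = 1L, species = 1))
  h2 <- countKmers("ACGTACGTAC", 17)        # too short
  expect_equal(totalSpecies(h2), 0)
  expect_error(countKmers("ACGT", 0), "k must be")
  expect_error(countKmers("ACGT", 32), "k must be")
})

test_that("window conservation: individuals equal N-free window count", {
  set.seed(1)
  s <- randomDna(100)
  expect_equal(totalIndividuals(countKmers(s, 17)), 100 - 17 + 1)
  reads <- replicate(50, randomDna(150, withN = 0.02))
  h <- countKmers(reads, 17)
  windows <- sum(vapply(reads, function(r) {
    w <- substring(r, 1:(nchar(r) - 16), 17:nchar(r))
    sum(!grepl("N", w, fixed = TRUE))
  }, numeric(1)))
  expect_equal(totalIndividuals(h), windows)
})

test_that("counter equals the naive enumeration oracle", {
  set.seed(7)
  for (i in 1:5) {
    seqs <- replicate(sample(1:4, 1), randomDna(sample(200:2000, 1),
                                                gc = runif(1, 0.3, 0.6),
                                                withN = 0.01))
    for (k in c(3L, 9L, 17L)) {
      got <- as.data.frame(countKmers(seqs, k))
      want <- naiveKmerHistogram(seqs, k)
      expect_equal(got$depth, want$depth)
      expect_equal(got$species, want$species)
    }
  }
  # strand collapse: a sequence and its reverse complement give one species
  # set at doubled depth
  s <- randomDna(500)
  both <- countKmers(c(s, revcompChar(s)), 17)
  one <- countKmers(s, 17)
  expect_equal(totalSpecies(both), totalSpecies(one))
  expect_equal(totalIndividuals(both), 2 * totalIndividuals(one))
})

test_that("peak detection ignores the low-frequency region and breaks ties low", {
  expect_equal(detectPeak(KmerHistogram(c(6, 74, 75), c(50, 500, 499))), 74)
  expect_equal(detectPeak(KmerHistogram(c(3, 74), c(1e6, 500))), 74)
  expect_equal(detectPeak(KmerHistogram(c(40, 60), c(100, 100))), 40)
  expect_error(detectPeak(KmerHistogram(c(1, 3), c(10, 10))), "minDepth")
  # Poisson-shaped spectrum peaks at its mean
  d <- 1:200
  pk <- detectPeak(KmerHistogram(d, round(1e5 * dpois(d, 68))))
  expect_lte(abs(pk - 68), 1)
})

test_that("genome size follows kmerNumber / peakDepth with error revision", {
  gs <- estimateGenomeSize(KmerHistogram(74, 1000), 74)
  expect_equal(gs$genomeSize, 1000)
  expect_equal(gs$errorRateKmer, 0)
  expect_equal(gs$revisedGenomeSize, 1000)
  h <- KmerHistogram(c(1, 2, 50, 100), c(1000, 500, 2000, 10))
  gs2 <- estimateGenomeSize(h, 50)
  expect_equal(gs2$kmerNumber, 50 * 2000 + 100 * 10)
  expect_equal(gs2$errorRateKmer, 2000 / (2000 + 101000))
  expect_equal(gs2$genomeSize * 50, gs2$kmerNumber)
  expect_equal(gs2$revisedGenomeSize,
               gs2$genomeSize * (1 - gs2$errorRateKmer))
  expect_error(estimateGenomeSize(KmerHistogram(2, 100), 74), "zero")
})

test_that("heterozygosity transform matches its closed form", {
  expect_equal(heterozygosityRate(0, 17), 0)
  expect_equal(heterozygosityRate(0.1, 17), 0.1 / (17 * 1.9))
  expect_equal(round(heterozygosityRate(0.1, 17), 6), 0.003096)
  expect_equal(heterozygosityRate(0.11836, 17), 0.0037, tolerance = 1e-3)
  # strictly increasing, and ~ aHalf / (2k) near zero
  a <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(heterozygosityRate(a, 17)) > 0))
  expect_equal(heterozygosityRate(1e-4, 17), 1e-4 / 34, tolerance = 1e-4)
  expect_error(heterozygosityRate(1.2, 17), "aHalf")
})

test_that("mixture fit recovers known component weights", {
  d <- 1:200
  s <- 10000 * dpois(d, 74) + 1000 * dpois(d, 37)
  a <- estimateHetFraction(KmerHistogram(d, s), 74)
  expect_equal(a, 1000 / 11000, tolerance = 0.01)
  # homozygous spectrum: essentially no half-depth weight
  s0 <- 10000 * dpois(d, 74)
  expect_lt(estimateHetFraction(KmerHistogram(d, s0), 74), 0.01)
  expect_error(estimateHetFraction(KmerHistogram(74, 10), 3), "peakDepth")
})

test_that("repeat ratio is the individual fraction beyond the tail cutoff", {
  expect_equal(repeatRatio(KmerHistogram(74, 100), 74), 0)
  got <- repeatRatio(KmerHistogram(c(74, 140), c(100, 10)), 74)
  expect_equal(got, 1400 / (7400 + 1400))
  # boundary is strict: depth exactly 1.8 * peak is not repeat
  expect_equal(repeatRatio(KmerHistogram(c(10, 18), c(100, 5)), 10), 0)
})

test_that("survey recovers simulator truth on a homozygous genome", {
  # coverage 74 gives expected k-mer depth 66.1; an integer peak off by one
  # changes the size estimate by under 2%
  spec <- smallSpec(genomeLength = 2e5, coverage = 74, seed = 13L)
  truth <- simulateDiploidGenome(spec)
  est <- runSurvey(countKmers(simulateReads(truth, spec), 17))
  expect_equal(est@genomeSize, 2e5, tolerance = 0.02)
  expect_lt(est@heterozygosityRate, 5e-4)
  expect_lt(est@repeatRatio, 0.01)
})

test_that("survey recovers genome size within 2 percent across seeds", {
  sizes <- vapply(c(101L, 202L, 303L), function(sd) {
    spec <- smallSpec(genomeLength = 1e5, coverage = 74, seed = sd)
    est <- runSurvey(countKmers(simulateReads(simulateDiploidGenome(spec),
                                              spec), 17))
    est@genomeSize
  }, numeric(1))
  expect_lt(median(abs(sizes - 1e5) / 1e5), 0.02)
})

test_that("survey recovers the repeat fraction", {
  spec <- smallSpec(genomeLength = 3e5, repeatFraction = 0.27,
                    coverage = 74, seed = 3L)
  est <- runSurvey(countKmers(simulateReads(simulateDiploidGenome(spec),
                                            spec), 17))
  expect_equal(est@repeatRatio, 0.27, tolerance = 0.12)
  expect_lt(abs(est@repeatRatio - 0.27), 0.03)
})

test_that("empty input and stage errors carry stage names", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(), fq)
  expect_error(runSurvey(c(fq, fq)), "count")
})

test_that("histogram TSV round trip preserves the spectrum", {
  h <- KmerHistogram(c(2, 10, 74), c(5, 100, 2000))
  f <- tempfile(fileext = ".tsv")
  writeKmerHistogram(h, f)
  h2 <- readKmerHistogram(f)
  expect_equal(as.data.frame(h2), as.data.frame(h))
  expect_equal(runSurvey(h2)@genomeSize, runSurvey(h)@genomeSize)
})
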