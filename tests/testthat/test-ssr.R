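test_that("detection thresholds match the MISA defaults", {
  hit <- findSsrs(c(x = "ACACACACACAC"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "AC")
  expect_equal(hit$repeat_number, 6)
  expect_equal(hit$ssr_type, "p2")
  expect_equal(nrow(findSsrs(c(x = "ACACACACAC"))), 0)  # 5 units: below
  mono <- findSsrs(c(x = strrep("A", 10)))
  expect_equal(mono$ssr, "(A)10")
  expect_equal(nrow(findSsrs(c(x = strrep("A", 9)))), 0)
  tri <- findSsrs(c(x = strrep("AGG", 5)))
  expect_equal(tri$motif, "AGG")
  expect_error(findSsrs(c(x = "ACGTX")), "non-DNA")
})

test_that("runs are maximal, truncated to whole units, and N-broken", {
  # 13 bases of AC: 6 whole units, partial trailing base dropped
  hit <- findSsrs(c(x = paste0("ACACACACACACA")))
  expect_equal(hit$start, 1)
  expect_equal(hit$end, 12)
  # an N splits a run into two sub-threshold halves
  broken <- paste0(strrep("AC", 4), "N", strrep("AC", 4))
  expect_equal(nrow(findSsrs(c(x = broken))), 0)
  # run not at the sequence start ("CAT" cannot extend the hexamer run)
  off <- paste0("CAT", strrep("TTAGGG", 5))
  hx <- findSsrs(c(x = off))
  expect_equal(hx$unit_length, 6)
  expect_equal(hx$start, 4)
})

test_that("motifs are primitive: powers collapse to the shorter unit", {
  hit <- findSsrs(c(x = strrep("A", 20)))
  expect_equal(hit$unit_length, 1)  # never reported as (AA)10 or (AAAA)5
  hit2 <- findSsrs(c(x = strrep("ACG", 10)))
  expect_equal(hit2$unit_length, 3)
  expect_true(all(nchar(hit2$motif) == 3))
})

test_that("scanner equals the regex oracle on random sequences", {
  set.seed(99)
  for (i in 1:100) {
    # low-cardinality alphabet stretches make tandem repeats common
    s <- paste0(randomDna(5000),
                paste(sample(c("AC", "AG", "AT", "A", "TTA", "GGC"),
                             200, replace = TRUE), collapse = ""),
                randomDna(3000))
    got <- findSsrs(c(x = s))
    want <- regexSsrOracle(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$motif, want$motif)
    expect_equal(got$repeat_number, want$repeat_number)
  }
})

test_that("compound merging follows the gap rule", {
  set.seed(77)
  spacer <- randomDna(200)
  farApart <- paste0(strrep("AC", 6), spacer, strrep("AG", 6))
  lociFar <- findSsrs(c(x = farApart))
  expect_equal(nrow(lociFar), 2)  # the spacer itself is SSR-free
  expect_equal(nrow(mergeCompound(lociFar, maxGap = 100)), 2)
  close <- paste0(strrep("AC", 6), strrep("T", 9), strrep("AG", 6))
  lociClose <- findSsrs(c(x = close))
  expect_equal(nrow(lociClose), 2)
  merged <- mergeCompound(lociClose, maxGap = 100)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$ssr_type, "c")
  expect_equal(merged$n_members, 2)
  expect_equal(merged$start, 1)
  expect_equal(merged$end, 12 + 9 + 12)
  # single locus untouched; remove action drops close loci
  single <- findSsrs(c(x = strrep("AC", 6)))
  expect_identical(mergeCompound(single), single)
  expect_equal(nrow(mergeCompound(lociClose, action = "remove")), 0)
})

test_that("flank filtering removes loci near contig ends", {
  set.seed(78)
  contig <- paste0(strrep("G", 4), strrep("AC", 6), randomDna(5000),
                   strrep("AT", 6), randomDna(5000))
  loci <- findSsrs(c(ctg = contig))
  kept <- filterFlanks(loci, c(ctg = nchar(contig)), minFlank = 100)
  # the AC locus sits 4 bp from the contig start and must go; the AT locus
  # has >= 100 bp on both sides and must stay
  expect_false("AC" %in% kept$motif)
  expect_true("AT" %in% kept$motif)
  expect_true(all(kept$start - 1 >= 100 &
                    nchar(contig) - kept$end >= 100))
  # short contigs lose everything
  shortC <- strrep("AC", 75)  # 150 bp
  lociS <- findSsrs(c(s = shortC))
  expect_equal(nrow(filterFlanks(lociS, c(s = 150))), 0)
  expect_equal(nrow(filterFlanks(lociS, c(s = 150), minFlank = 0)), 1)
  expect_error(filterFlanks(lociS, c(s = 100)), "bounds")
})

test_that("canonical classes group rotations and reverse complements", {
  expect_equal(canonicalMotif("GT"), "AC/GT")
  expect_equal(canonicalMotif("CCT"), "AGG/CCT")
  expect_equal(canonicalMotif("A"), "A/T")
  set.seed(12)
  for (i in 1:50) {
    m <- randomDna(sample(1:6, 1))
    cls <- canonicalMotif(m)
    rot <- sample(nchar(m), 1)
    rotated <- paste0(substring(m, rot + 1), substring(m, 1, rot))
    expect_equal(canonicalMotif(rotated), cls)
    expect_equal(canonicalMotif(revcompChar(m)), cls)
  }
  expect_error(canonicalMotif("ACGTACG"), "1-6")
})

test_that("reverse complement preserves the canonical class multiset", {
  set.seed(13)
  s <- paste0(randomDna(2000),
              paste(sample(c("AC", "AAG", "T"), 300, TRUE), collapse = ""),
              randomDna(2000))
  fwd <- findSsrs(c(x = s))
  rev <- findSsrs(c(x = revcompChar(s)))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(canonicalMotif(fwd$motif)),
               sort(canonicalMotif(rev$motif)))
  expect_equal(sort(fwd$repeat_number), sort(rev$repeat_number))
})

test_that("summary reconciles counts against a hand-planted fixture", {
  set.seed(14)
  c1 <- paste0(randomDna(300), strrep("AC", 8), randomDna(300),
               strrep("AAG", 6), randomDna(300))
  c2 <- paste0(randomDna(300), strrep("A", 12), randomDna(300))
  c3 <- randomDna(400)
  loci <- findSsrs(c(c1 = c1, c2 = c2, c3 = c3))
  s <- summarizeSsrs(loci, sequencesExamined = 3)
  expect_equal(s@totalSsrs, 3)
  expect_equal(s@sequencesWithSsr, 2)
  expect_equal(s@sequencesWithMoreThanOne, 1)
  expect_equal(unname(s@unitLengthCounts[1:3]), c(1, 1, 1))
  expect_equal(sum(s@unitLengthPercents), 100)
  empty <- summarizeSsrs(findSsrs(c(x = randomDna(100))), 1)
  expect_equal(empty@totalSsrs, 0)
  # published-table arithmetic
  expect_equal(ratioPercent(205789, 299574), 68.69)
  expect_equal(ratioPercent(31228, 299574), 10.42)
})

test_that("compound members are accounted once in totals", {
  set.seed(15)
  s <- paste0(randomDna(200), strrep("AC", 6), strrep("T", 9),
              strrep("AG", 6), randomDna(200))
  loci <- mergeCompound(findSsrs(c(x = s)))
  sm <- summarizeSsrs(loci, 1)
  expect_equal(sm@totalSsrs, 1)
  expect_equal(sm@compoundSsrs, 1)
  expect_equal(sm@ssrsInCompound, 2)
})
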