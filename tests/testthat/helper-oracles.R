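# Independent oracles used across the suite. These deliberately avoid the
# package's native code paths: plain R string handling and dynamic
# programming only.

randomDna <- function(n, gc = 0.5, withN = 0) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (withN > 0) {
    idx <- sample.int(n, max(1, round(withN * n)))
    b[idx] <- "N"
  }
  paste(b, collapse = "")
}

revcompChar <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

# naive canonical k-mer histogram by substring enumeration
naiveKmerHistogram <- function(seqs, k) {
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }))
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0)
    return(data.frame(depth = integer(), species = numeric()))
  canon <- pmin(words, revcompChar(words))
  counts <- table(canon)
  h <- table(as.integer(counts))
  data.frame(depth = as.integer(names(h)), species = as.numeric(h))
}

# brute-force perfect-SSR enumeration with backreference regexes
regexSsrOracle <- function(seq, minRepeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  out <- list()
  isPrimitive <- function(m) {
    u <- nchar(m)
    for (d in seq_len(u - 1)) {
      if (u %% d != 0) next
      if (m == strrep(substring(m, 1, d), u / d)) return(FALSE)
    }
    TRUE
  }
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, minRepeats[u] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      reps <- len[i] %/% u
      motif <- substring(seq, m[i], m[i] + u - 1L)
      if (!isPrimitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m[i]), end = as.integer(m[i] + reps * u - 1L),
        motif = motif, unit_length = u, repeat_number = reps)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_length = integer(),
                      repeat_number = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Needleman-Wunsch global alignment score, match/mismatch/gap
nwScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (a[i] == b[j]) match else mismatch
      S[i + 1, j + 1] <- max(d, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  S[n + 1, m + 1]
}

smallSpec <- function(...) {
  args <- list(genomeLength = 5e4, gcFraction = 0.42, hetRate = 0,
               repeatFraction = 0, coverage = 10, baseErrorRate = 0,
               seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(SimulationSpec, args)
}
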