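---
title: "Genome survey analysis from k-mer spectra: methods and assumptions"
author: "kmerSurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey analysis from k-mer spectra: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerSurvey)
```

# Overview

`kmerSurvey` implements the standard desk-scale genome survey: estimate a
diploid organism's genome size, heterozygosity and repeat content from
the frequency spectrum of canonical 17-mers in unassembled short reads.
This vignette documents the statistical model, every default parameter
and why it has the value it does, the simulator used for validation, and
the known limitations of the approach.

# The k-mer spectrum model

## Counting

A k-mer is counted in **canonical** form: a k-mer and its reverse
complement are the same species, represented by the
lexicographically smaller 2-bit encoding. Windows containing `N` are
skipped; an `N` resets the rolling window, so a read with one `N` loses
exactly `k` windows around it. The C++ counter packs bases two bits each
into a 64-bit word, which bounds `k` at 31; `k = 17` is the default
because 4^17 ≈ 1.7 × 10^10 comfortably exceeds vertebrate genome sizes,
making chance k-mer collisions negligible while keeping memory modest.

Two totals matter:

* **species** — distinct canonical k-mers;
* **individuals** (the "k-mer number") — total occurrences,
  Σ depth × species(depth).

## Genome size (Eq. 1)

Each genomic position is covered by about
`coverage × (L − k + 1) / L` k-mer windows for read length `L`
(`74 × 134/150 ≈ 66.1` at the defaults), so the histogram of a
single-copy genome peaks at that depth. The estimator is simply

```
genome_size = kmer_number / peak_depth
```

where `kmer_number` counts individuals at depth ≥ `minDepth` and
`peak_depth` is the histogram mode at depth ≥ `minDepth`. Because both
numerator and denominator scale with the k-mer (not base) coverage, the
read-length factor cancels and never needs to be known.

* **`minDepth = 6`** (the "low-frequency cutoff", i.e. depths ≤ 5 are
  discarded): at ~70× coverage, k-mers created by sequencing errors are
  overwhelmingly rare species at depth 1–5, while true single-copy
  k-mers have negligible Poisson mass down there. At much lower coverage
  (≲ 20×) this cutoff would eat into the true distribution — see
  Limitations.
* **Revised size**: `genome_size × (1 − error_rate_kmer)`, with
  `error_rate_kmer` the share of *all* individuals that fall below
  `minDepth`. This removes the inflation of the k-mer number caused by
  error k-mers.
* **Peak detection** takes the argmax of species count over a dense
  depth grid; ties break toward the smaller depth (a deliberate,
  documented choice — ties are essentially only hit in synthetic data).
  An optional width-3 moving average (`smooth = TRUE`) is available for
  shallow, noisy histograms but is off by default so that published
  integer peaks are reproduced exactly.

## Heterozygosity (Eq. 2)

A SNP between the two haplotypes makes up to `2k` k-mer species
*haplotype-private*: they occur at half the usual depth. The spectrum is
modeled as a two-component mixture with Poisson kernels centered at the
peak `λ` and at `λ/2`:

```
species(d) ≈ N · [ (1 − w) · Pois(d; λ) + w · Pois(d; λ/2) ]
```

The weight `w = a_1/2` is fit by least squares on depths in
`[minDepth, 1.8 × peak]` (beyond that, repeat k-mers dominate); the
overall scale `N` is profiled out in closed form, leaving a 1-D
optimization over `w ∈ [0, 1]`. The per-base rate follows from
inverting the species accounting:

```
het_rate = a_1/2 / (k × (2 − a_1/2))
```

The Poisson kernel is adequate for the simulator's uniform, error-free
or low-error reads; real libraries are overdispersed
(`overdispersed = TRUE` switches to a negative-binomial kernel).

## Repeat ratio

The fraction of k-mer individuals at depth **strictly greater than**
`multiplier × peak` with `multiplier = 1.8`, out of all individuals at
depth ≥ `minDepth`. 1.8 (rather than 2.0) catches the lower Poisson tail
of two-copy repeats while staying clear of the single-copy peak's upper
tail; the boundary is exclusive so that a depth of exactly 1.8 × peak
does not count as repeat.

# Read-pair quality control

`filterReadPairs()` applies three rules to each pair, in a fixed order,
and attributes each dropped pair to the **first** failing rule:

1. **adapter** — exact substring match of the adapter in either mate
   (disabled unless an adapter is given);
2. **N fraction** — ≥ 10 % of either mate's bases are `N` (the boundary
   itself fails: 15 N in a 150-bp read is dropped);
3. **low quality** — more than 50 % of either mate's bases below Q5
   (the boundary itself passes: exactly half at Q4 is kept).

The report carries Q20/Q30 (percent of bases at or above the threshold),
mean error rate (average of `10^(−Q/10)` as a percent), GC over non-N
bases, and the effective rate `100 × clean_bases / raw_bases`.

# The simulator

`simulateDiploidGenome()` + `simulateReads()` produce ground truth for
validation. What is emulated:

* a diploid as two haplotypes differing by independent per-site SNPs at
  rate `hetRate` (default 0.0037);
* exact dispersed repeat families: unit-length-500 slots copied to
  2–5 dispersed locations until `repeatFraction` (default 0.27) of the
  genome is repeat copies. Copy counts cycle 2, 3, 4, 5 (the last family
  shrinks to land within one unit of the target) because a pure
  two-copy model puts all repeat k-mers at exactly 2 × peak, where
  ~15 % of their Poisson mass falls below the 1.8 × cutoff; mixing in
  higher copy numbers matches how dispersed repeats actually spread
  across the depth axis;
* uniformly placed read pairs of fixed length (150 bp) and insert size
  (350 bp), mate 2 reverse-complemented, per-base substitution errors at
  `baseErrorRate`, constant Phred quality `round(−10 log10 e)`;
* QC artifacts on exact fractions of pairs: N-blocks in mate 1,
  low-quality (`#`, Q2) tails in mate 2.

What is **not** emulated: indels, structural variation, tandem/nested
repeat families, GC-dependent coverage bias, quality-score decay along
the read, optical duplicates, adapter read-through. These all exist in
real libraries and are out of scope for a validation simulator.

Determinism: the genome uses `seed`, reads `seed + 1`, artifacts
`seed + 2`, so the same spec always yields byte-identical FASTQ.

# SSR mining

`findSsrs()` reports maximal perfect tandem runs with per-unit-length
minimum repeat counts `c(10, 6, 5, 5, 5, 5)` for units of 1–6 bp — the
conventional microsatellite-search thresholds. Details that matter:

* runs are truncated to whole units (13 bases of `AC` is `(AC)6`);
* motifs are **primitive** (a poly-A run is `(A)n`, never `(AA)m`);
* `N` breaks runs;
* `mergeCompound()` joins loci whose gap (`start2 − end1 − 1`) is
  ≤ 100 bp into compound loci (or removes them, `action = "remove"`);
* `filterFlanks()` keeps loci with ≥ 100 bp of sequence on both sides,
  the usual requirement for primer design;
* `canonicalMotif()` groups motifs under rotation and reverse
  complement (`"AC/GT"`), the standard reporting classes.

The scanner is validated against a PCRE backreference oracle
(`([ACGT]{u})\1{m−1,}`) on hundreds of random sequences in the test
suite.

# Marker screening

`kmerContainment()` measures the fraction of a marker's canonical
k-mers present in a target index — a presence screen that works on
unassembled reads. `screenMarker()` calls a marker present at
containment ≥ 0.5 and absent below 0.5; *sex-specific* requires presence
in one sex and containment < 0.5 in the other. `percentIdentity()`
(global alignment, match +1 / mismatch −1 / gap −2, identity =
matches / alignment columns) serves exon-scale comparisons against
assembled targets.

# Problem sizes and cost

The implementation is aimed at desk scale: genomes up to a few megabases
at up to ~100× simulated coverage. A 1-Mb genome at 74× (the acceptance
benchmark) indexes ~66 M k-mer occurrences and completes the full
simulate–QC–survey loop in about 30 s and well under 2 GB of memory.
Real 600-Mb libraries need an external k-mer counter; their
depth–species histograms can be loaded with `readKmerHistogram()` and
fed to `runSurvey()` unchanged.

# Limitations

* The integer peak quantizes the size estimate: the relative bias is up
  to `1/peak`, so surveys should run at coverage giving a peak ≥ ~50.
* The half-depth mixture assumes isolated SNPs; at rates where SNPs
  frequently co-occur within one k-mer window (`2kh` not ≪ 1), distinct
  het k-mers merge and Eq. 2 underestimates slightly (~4 % relative at
  h = 0.0037, k = 17). Repetitive k-mers leaking into the fit range push
  the other way.
* The repeat ratio is a depth-tail proxy, not an annotation: diverged
  repeats below 1.8 × peak are missed, and high-copy exact repeats are
  counted by occurrence, not by family.
* Poisson kernels understate real-library depth variance; use
  `overdispersed = TRUE` for real data.

```{r example, eval = FALSE}
# end-to-end run on simulated data (about half a minute)
spec <- SimulationSpec(genomeLength = 1e6, hetRate = 0.0037,
                       repeatFraction = 0.27, coverage = 74, seed = 42L)
report <- runFullSurvey(list(simulation = spec), tempfile("survey"))
report
```
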