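Package: kmerSurvey
Title: Genome Survey Analysis from Short Reads via k-mer Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for desk-scale genome survey analysis of diploid
    organisms from paired-end short reads: read-pair quality filtering
    with Q20/Q30/GC accounting, canonical 17-mer spectrum estimation of
    genome size, heterozygosity and repeat content, GC-versus-depth
    windowing over assemblies, MISA-style microsatellite (SSR) mining
    with compound merging and flank filtering, and k-mer containment
    screening of candidate sex-linked markers. Includes a seeded
    simulator of diploid genomes and reads with known heterozygosity,
    repeat fraction, GC content and error rate, so every estimator can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, QualityControl, GenomeAssembly, Coverage
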