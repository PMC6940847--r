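markerHitAsList <- function(hit) {
  list(marker_id = hit@markerId, present = hit@present,
       kmer_containment = hit@kmerContainment,
       best_identity = hit@bestIdentity,
       best_location = hit@bestLocation)
}

#' Run the full genome survey on one sample
#'
#' Orchestrates QC filtering, the k-mer survey and (given an assembly) the
#' GC/depth and SSR stages, plus optional marker screening, writing all
#' stage outputs under one directory. The input is either a
#' [SimulationSpec-class] (reads are simulated) or a pair of FASTQ paths.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{simulation}{a [SimulationSpec-class], or}
#'     \item{fastq1, fastq2}{paired FASTQ paths;}
#'     \item{assembly}{optional FASTA path / DNAStringSet for the GC-depth
#'       and SSR stages;}
#'     \item{adapter}{optional adapter sequence for QC;}
#'     \item{markers}{optional named DNAStringSet / FASTA of candidate
#'       markers, screened by containment against this sample's reads;}
#'     \item{k, minDepth, multiplier, window, minRepeats, maxGap,
#'       minFlank}{stage parameters with the usual defaults (17, 6, 1.8,
#'       10000, c(10,6,5,5,5,5), 100, 100);}
#'     \item{presenceThreshold}{marker presence threshold (0.5).}
#'   }
#' @param outDir Output directory (created if needed).
#' @return A [SurveyReport-class]. Side effects: `report.json`,
#'   `table1.tsv`, `table2.tsv`, `histogram.tsv` and, when an assembly is
#'   given, `gcdepth.tsv`, `ssr.tsv` and `table5.tsv` under `outDir`.
#' @export
runFullSurvey <- function(config, outDir) {
  par <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  k <- checkK(par("k", 17L))
  minDepth <- as.integer(par("minDepth", 6L))
  multiplier <- par("multiplier", 1.8)
  window <- par("window", 10000)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("survey stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- input ------------------------------------------------------------
  if (!is.null(config$simulation)) {
    spec <- config$simulation
    if (!is(spec, "SimulationSpec"))
      stop("config$simulation must be a SimulationSpec")
    truth <- stage("simulate", simulateDiploidGenome(spec))
    pairs <- stage("simulate", simulateReads(truth, spec))
    pairs <- stage("simulate", injectArtifacts(pairs, spec))
    seed <- spec@seed
    inputs <- list(simulation = specAsList(spec))
  } else if (!is.null(config$fastq1) && !is.null(config$fastq2)) {
    pairs <- stage("read", readReadPairs(config$fastq1, config$fastq2))
    seed <- NA_integer_
    inputs <- list(fastq1 = config$fastq1, fastq2 = config$fastq2)
  } else {
    stop("config must provide either 'simulation' or 'fastq1'/'fastq2'")
  }

  # --- qc ---------------------------------------------------------------
  qcRes <- stage("qc", filterReadPairs(pairs, adapter = par("adapter", NULL)))
  clean <- qcRes$pairs
  writeQcReport(qcRes$report, file.path(outDir, "table1"))

  # --- k-mer survey -----------------------------------------------------
  hist <- stage("kmer", countKmers(clean, k))
  writeKmerHistogram(hist, file.path(outDir, "histogram.tsv"))
  est <- stage("kmer", runSurvey(hist, k = k, minDepth = minDepth,
                                 multiplier = multiplier))
  writeSurveyEstimates(est, file.path(outDir, "table2"))

  # --- gc-depth + ssr (need an assembly) --------------------------------
  ssrSummary <- NULL
  gcPath <- NA_character_
  if (!is.null(config$assembly)) {
    assembly <- loadAssembly(config$assembly)
    idx <- kmerIndex(clean, k)
    wins <- stage("gcdepth", windowGc(assembly, window = window))
    wins <- stage("gcdepth", windowDepth(wins, assembly, idx, k = k))
    gcPath <- file.path(outDir, "gcdepth.tsv")
    writeGcDepth(wins, gcPath)

    loci <- stage("ssr", findSsrs(assembly,
                                  par("minRepeats", c(10L, 6L, 5L, 5L, 5L, 5L))))
    loci <- stage("ssr", mergeCompound(loci, maxGap = par("maxGap", 100)))
    loci <- stage("ssr", filterFlanks(loci, assembly,
                                      minFlank = par("minFlank", 100)))
    ssrSummary <- summarizeSsrs(loci, length(assembly))
    writeSsrs(loci, ssrSummary, file.path(outDir, "ssr"))
    file.rename(file.path(outDir, "ssr_summary.json"),
                file.path(outDir, "table5.json"))
  }

  # --- markers ----------------------------------------------------------
  markerHits <- list()
  if (!is.null(config$markers)) {
    markers <- config$markers
    if (is.character(markers) && length(markers) == 1 &&
        file.exists(markers))
      markers <- readDNAStringSet(markers)
    markers <- as(markers, "DNAStringSet")
    if (is.null(names(markers)))
      names(markers) <- sprintf("marker_%d", seq_along(markers))
    idx <- kmerIndex(clean, k)
    thr <- par("presenceThreshold", 0.5)
    markerHits <- lapply(seq_along(markers), function(i) {
      cont <- kmerContainment(markers[[i]], idx)
      MarkerHit(names(markers)[i], cont >= thr, cont)
    })
    names(markerHits) <- names(markers)
  }

  provenance <- list(
    inputs = inputs,
    parameters = list(k = k, minDepth = minDepth, multiplier = multiplier,
                      window = window, adapter = par("adapter", NULL)),
    seed = seed,
    tool = "kmerSurvey",
    version = as.character(packageVersion("kmerSurvey")))

  report <- new("SurveyReport", qc = qcRes$report, estimates = est,
                ssrSummary = ssrSummary, gcDepthPath = gcPath,
                markerHits = markerHits, provenance = provenance)
  writeSurveyReport(report, file.path(outDir, "report.json"))
  report
}

#' Serialize a SurveyReport to JSON
#'
#' @param report A [SurveyReport-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeSurveyReport <- function(report, file) {
  est <- report@estimates
  nmsE <- slotNames("SurveyEstimates")
  out <- list(
    qc = as.list(qcReportRow(report@qc)),
    estimates = setNames(lapply(nmsE, function(n) slot(est, n)), nmsE),
    gc_depth_path = report@gcDepthPath,
    marker_hits = lapply(report@markerHits, markerHitAsList),
    provenance = report@provenance)
  if (!is.null(report@ssrSummary)) {
    s <- report@ssrSummary
    out$ssr_summary <- list(
      sequences_examined = s@sequencesExamined,
      total_ssrs = s@totalSsrs,
      sequences_with_ssr = s@sequencesWithSsr,
      sequences_with_more_than_one = s@sequencesWithMoreThanOne,
      compound_ssrs = s@compoundSsrs,
      ssrs_in_compound = s@ssrsInCompound,
      unit_length_percents = as.list(round(s@unitLengthPercents, 2)))
  }
  write_json(out, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

setMethod("show", "SurveyReport", function(object) {
  cat("SurveyReport\n--- QC ---\n")
  show(object@qc)
  cat("--- k-mer survey ---\n")
  show(object@estimates)
  if (!is.null(object@ssrSummary)) {
    cat("--- SSR ---\n")
    show(object@ssrSummary)
  }
  if (length(object@markerHits)) {
    cat("--- markers ---\n")
    for (h in object@markerHits) show(h)
  }
})
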