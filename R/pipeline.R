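#' Pipeline run configuration
#'
#' Declarative configuration for the end-to-end workflow. The b-pair
#' defaults are the acquisition the metrics were proposed for: SDC from
#' b = 500/750, DDVD from b = 0/10, ADC from b = 0/1000 s/mm^2. Every run
#' writes its resolved configuration next to its outputs.
#'
#' @param outDir output directory.
#' @param cohortCsv path to an existing cohort CSV, or `NULL` to simulate.
#' @param dwiPath,bvalPath,maskPath optional imaging inputs for the
#'   map/ROI stage; `NULL` simulates the default phantom instead.
#' @param sdcPair,ddvdPair,adcPair b-value pairs (s/mm^2), each strictly
#'   increasing.
#' @param label cohort label column for ROC and model fitting.
#' @param excludePartial drop IHC partially-positive cases where the
#'   analysis is IHC-based.
#' @param thresholds optional fixed cutoff thresholds (otherwise all
#'   midpoints).
#' @param probabilityThreshold classification threshold on the predicted
#'   probability.
#' @param seed integer seed governing all simulation in the run.
#' @return a validated `runConfig` list.
#' @export
runConfig <- function(outDir,
                      cohortCsv = NULL,
                      dwiPath = NULL, bvalPath = NULL, maskPath = NULL,
                      sdcPair = c(500, 750), ddvdPair = c(0, 10),
                      adcPair = c(0, 1000),
                      label = "idh_gene", excludePartial = FALSE,
                      thresholds = NULL, probabilityThreshold = 0.5,
                      seed = 1L) {
  for (p in list(sdc = sdcPair, ddvd = ddvdPair, adc = adcPair)) {
    if (length(p) != 2L || p[1] >= p[2])
      stop(sprintf("invalid b-pair (%s): must be two increasing b-values",
                   paste(p, collapse = ", ")), call. = FALSE)
  }
  for (f in c(cohortCsv, dwiPath, bvalPath, maskPath))
    if (!is.null(f) && !file.exists(f))
      stop("input not found: ", f, call. = FALSE)
  structure(list(outDir = outDir, cohortCsv = cohortCsv,
                 dwiPath = dwiPath, bvalPath = bvalPath,
                 maskPath = maskPath, sdcPair = sdcPair,
                 ddvdPair = ddvdPair, adcPair = adcPair, label = label,
                 excludePartial = excludePartial, thresholds = thresholds,
                 probabilityThreshold = probabilityThreshold,
                 seed = as.integer(seed)),
            class = "runConfig")
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: phantom/maps/ROI (simulated when no imaging inputs are given),
#' cohort generation or loading, group statistics, ROC and cutoff table,
#' and the genotype model (reference-model classification plus a refit).
#' Writes `report.json` (machine-readable, schema-versioned),
#' `report.md` (human-readable tables), the cutoff table CSV and the
#' resolved configuration into `config$outDir`. Identical config + seed
#' gives byte-identical JSON.
#'
#' @param config a [runConfig()].
#' @return the report, invisibly (as a list).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  # -- imaging stage: maps + ROI triplet on real or simulated data -------
  maps0 <- stageTry("maps", {
    if (!is.null(config$dwiPath)) {
      series <- loadDWISeries(config$dwiPath, config$bvalPath)
      mask <- loadROIMask(config$maskPath, series)
      note("loaded DWI series (%d b-values) and mask (%d voxels)",
           length(bValues(series)), pixelCount(mask))
      list(series = series, mask = mask)
    } else {
      ph <- simulatePhantom(phantomSpec(seed = config$seed))
      mask <- roiMask(ph$regionMap == 3L)
      note("simulated default phantom (seed %d); ROI = mutant-like region (%d voxels)",
           config$seed, pixelCount(mask))
      list(series = ph$series, mask = mask)
    }
  })
  mm <- stageTry("maps", computeMetricMaps(maps0$series,
                                           config$sdcPair,
                                           config$ddvdPair,
                                           config$adcPair))
  trip <- stageTry("roi", roiAggregate(mm, maps0$mask))
  note("resolved b-pairs: SDC %s, DDVD %s, ADC %s",
       paste(config$sdcPair, collapse = "/"),
       paste(config$ddvdPair, collapse = "/"),
       paste(config$adcPair, collapse = "/"))

  # -- cohort stage ------------------------------------------------------
  cohort <- stageTry("cohort", {
    if (!is.null(config$cohortCsv)) readCohort(config$cohortCsv)
    else simulateCohort(defaultCohortSpec(seed = config$seed))
  })
  nAll <- nrow(cohort)
  if (config$excludePartial && "idh_ihc" %in% names(cohort)) {
    cohort <- cohort[cohort$idh_ihc != 0.5, , drop = FALSE]
    note("excluded %d IHC partially-positive subjects (%d remain)",
         nAll - nrow(cohort), nrow(cohort))
  }
  stats <- stageTry("cohort-stats", cohortSummary(cohort, config$label))

  # -- ROC / cutoffs on SDC ---------------------------------------------
  lab <- cohort[[config$label]]
  roc <- stageTry("roc", rocCurve(cohort$sdc_au_per_s, lab))
  cuts <- stageTry("roc", cutoffTable(cohort$sdc_au_per_s, lab,
                                      thresholds = config$thresholds))

  # -- genotype model ----------------------------------------------------
  ref <- referenceModel()
  cls <- stageTry("genotype", classifyCohort(cohort, ref,
                                             config$probabilityThreshold))
  refit <- stageTry("genotype", fitLogistic(cohort, config$label,
                                            config$excludePartial))

  report <- list(
    schema = "gliomaSDC-report/1",
    # outDir is volatile run metadata; it lives in resolved_config.json so
    # that identical config + seed gives byte-identical report JSON
    config = unclass(config)[setdiff(names(config), "outDir")],
    roiTriplet = list(sdc_au_per_s = trip@sdc,
                      ddvd_au_per_pixel = trip@ddvd,
                      adc_e4_mm2_per_s = trip@adc,
                      nInvalid = as.list(trip@nInvalid)),
    cohortStats = stats,
    roc = list(auc = auc(roc), nPositive = roc@nPositive,
               nNegative = roc@nNegative),
    cutoffs = cuts,
    genotype = list(
      reference = as.list(coef(ref)),
      refit = c(as.list(coef(refit$coeffs)),
                list(se = as.list(refit$se), auc = refit$auc,
                     converged = refit$converged, n = refit$n)),
      nPredictedPositive = sum(cls$predictedClass)
    ),
    log = log
  )
  validateReport(report)
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.csv(cuts, file.path(config$outDir, "cutoff_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$outDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(reportMarkdown(report), file.path(config$outDir, "report.md"))
  invisible(report)
}

validateReport <- function(report) {
  need <- c("schema", "config", "roiTriplet", "cohortStats", "roc",
            "cutoffs", "genotype", "log")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("report schema violation: missing section(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!identical(report$schema, "gliomaSDC-report/1"))
    stop("unknown report schema: ", report$schema, call. = FALSE)
  invisible(TRUE)
}

fmtRow <- function(...) paste(c("|", sapply(list(...), format), "|"),
                              collapse = " ")

reportMarkdown <- function(report) {
  cuts <- report$cutoffs
  top <- youdenRow(cuts)
  c("# gliomaSDC pipeline report",
    "",
    "## ROI metric triplet",
    sprintf("- SDC  %.4f au/s", report$roiTriplet$sdc_au_per_s),
    sprintf("- DDVD %.4f au/pixel", report$roiTriplet$ddvd_au_per_pixel),
    sprintf("- ADC  %.4f x 1e-4 mm2/s", report$roiTriplet$adc_e4_mm2_per_s),
    "",
    sprintf("## ROC (SDC, %d positives vs %d negatives)",
            report$roc$nPositive, report$roc$nNegative),
    sprintf("- AUC = %.3f", report$roc$auc),
    "",
    "## Youden-optimal cutoff",
    "| threshold | sensitivity % (95% CI) | specificity % (95% CI) | LR+ |",
    "|---|---|---|---|",
    sprintf("| > %.4f | %.2f (%.2f-%.2f) | %.2f (%.2f-%.2f) | %.3g |",
            top$threshold, top$sensitivity, top$sensLow, top$sensHigh,
            top$specificity, top$specLow, top$specHigh,
            top$likelihoodRatio),
    "",
    "## Genotype model (refit)",
    sprintf("- eta = %.3f*SDC %+.3f*DDVD %+.3f*ADC %+.3f  (in-sample AUC %.3f)",
            report$genotype$refit$sdc, report$genotype$refit$ddvd,
            report$genotype$refit$adc, report$genotype$refit$intercept,
            report$genotype$refit$auc),
    "",
    "## Log",
    paste("-", report$log))
}
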