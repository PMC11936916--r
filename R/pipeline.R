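#' Read a pipeline run configuration
#'
#' YAML file with optional sections: `cohort` (arguments to
#' [cohortConfig()]), `thresholds` (`meaningful_change`, `sd_floor`,
#' `multiplier`), `analysis` (`apply_correction`, `pooled_vessel_fit`,
#' `force_slope1`), and `seed`.
#'
#' @param path YAML file path.
#' @return list with elements `cohort`, `thresholds`, `analysis`, `seed`.
#' @export
readRunConfig <- function(path) {
  .requireFile(path, "run configuration")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  list(cohort = if (is.null(cfg$cohort)) list() else cfg$cohort,
       thresholds = if (is.null(cfg$thresholds)) list() else cfg$thresholds,
       analysis = if (is.null(cfg$analysis)) list() else cfg$analysis,
       seed = cfg$seed)
}

#' Simulate a synthetic study into a directory
#'
#' @param outDir output directory.
#' @param seed RNG seed (overrides any seed in `cohortArgs`).
#' @param cohortArgs list of arguments for [cohortConfig()].
#' @param quiet suppress progress messages.
#' @return the generated [SyntheticStudy-class], invisibly.
#' @export
runSimulate <- function(outDir, seed = 1L, cohortArgs = list(), quiet = FALSE) {
  cohortArgs$seed <- as.integer(seed)
  config <- do.call(cohortConfig, cohortArgs)
  study <- generateCohort(config)
  writeStudy(study, outDir)
  if (!quiet) {
    message(sprintf("simulated %d subjects x %d sessions (%s fidelity) -> %s",
                    nSubjects(study), nSessions(study),
                    config@fidelity, outDir))
    tr <- trueParams(study)
    message(sprintf("  true CVR(HC) %.2f +/- %.2f %%/mmHg; CVR(HX) %.3f +/- %.3f %%/-mmHg; %d paradoxical subject(s)",
                    mean(tr$cvr_hc_true), stats::sd(tr$cvr_hc_true),
                    mean(tr$cvr_hx_true), stats::sd(tr$cvr_hx_true),
                    length(unique(tr$subject[tr$responder_class == "paradoxical"]))))
  }
  invisible(study)
}

#' Quantify per-vessel flows for a study directory
#'
#' Flow-fidelity studies pass through; image-fidelity studies have every
#' cine background-corrected and quantified. Writes `vessel_flows.csv`.
#'
#' @param studyDir directory written by [runSimulate()] / [writeStudy()].
#' @param outDir where to write `vessel_flows.csv` (default: `studyDir`).
#' @param quiet suppress progress messages.
#' @return the quantified [SyntheticStudy-class], invisibly.
#' @export
runQuantify <- function(studyDir, outDir = studyDir, quiet = FALSE) {
  study <- readStudy(studyDir)
  nCine <- sum(!is.na(study@acquisitions$cine_id))
  study <- quantifyStudy(study)
  acq <- study@acquisitions
  flows <- acq[, c("subject", "session", "acq_id", "phase", "placement",
                   paste0("flow_", .VESSELS))]
  flows$total_cbf_mL_min <- rowSums(acq[, paste0("flow_", .VESSELS)])
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .writeCsv(flows, file.path(outDir, "vessel_flows.csv"))
  if (!quiet)
    message(sprintf("quantified %d acquisitions (%d from cines) -> %s",
                    nrow(acq), nCine, file.path(outDir, "vessel_flows.csv")))
  invisible(study)
}

#' Run the CVR and reliability analysis for a study directory
#'
#' Writes `acq_physio.csv`, `cvr_results.csv`, `placement_model.json`,
#' `phase_tests.csv` and `reliability_report.json`.
#'
#' @param studyDir study directory.
#' @param outDir output directory (default: `studyDir`).
#' @param thresholds list: optional `meaningful_change`, `sd_floor`,
#'   `multiplier` overrides.
#' @param analysisOpts list: optional `apply_correction`,
#'   `pooled_vessel_fit`, `force_slope1` toggles.
#' @param quiet suppress progress messages.
#' @return list with the `CVRAnalysis` and `ReliabilityReport`, invisibly.
#' @export
runAnalyze <- function(studyDir, outDir = studyDir, thresholds = list(),
                       analysisOpts = list(), quiet = FALSE) {
  study <- readStudy(studyDir)
  study <- quantifyStudy(study)
  if (!quiet)
    message(sprintf("read %d acquisitions across %d sessions",
                    nrow(study@acquisitions),
                    nrow(unique(study@acquisitions[, c("subject", "session")]))))

  opt <- function(lst, name, default)
    if (is.null(lst[[name]])) default else lst[[name]]
  analysis <- analyzeCvr(
    study,
    multiplier = opt(thresholds, "multiplier", 1.96),
    sdFloor = opt(thresholds, "sd_floor", 1),
    pooledVesselFit = opt(analysisOpts, "pooled_vessel_fit", FALSE),
    forceSlope1 = opt(analysisOpts, "force_slope1", FALSE),
    applyCorrection = opt(analysisOpts, "apply_correction", TRUE),
    threshold = thresholds$meaningful_change)
  nSub <- sum(analysis$substitutions$sub_L_VA) +
          sum(analysis$substitutions$sub_R_VA)
  if (!quiet)
    message(sprintf("analysis: %d sessions, %d vertebral substitution(s), threshold %.2f mL/100 g/min",
                    nrow(analysis$cvr), nSub, analysis$threshold))
  if (!all(is.finite(analysis$cvr$cvr_hc)))
    warning(sum(!is.finite(analysis$cvr$cvr_hc)),
            " session(s) lack a hypercapnic phase; corrected hypoxic CVR unavailable there")

  report <- reliabilityReport(analysis)
  tests <- phaseComparisons(study)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  phys <- acquisitionPhysio(study)
  .writeCsv(phys, file.path(outDir, "acq_physio.csv"))
  .writeCsv(analysis$cvr, file.path(outDir, "cvr_results.csv"))
  jsonlite::write_json(
    lapply(analysis$placementModels, unclass),
    file.path(outDir, "placement_model.json"),
    auto_unbox = TRUE, digits = NA)
  .writeCsv(tests, file.path(outDir, "phase_tests.csv"))
  jsonlite::write_json(
    .reportToList(report),
    file.path(outDir, "reliability_report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  if (!quiet)
    message("wrote cvr_results.csv, placement_model.json, phase_tests.csv, reliability_report.json")
  invisible(list(analysis = analysis, report = report, phaseTests = tests))
}

.reportToList <- function(report) {
  out <- unclass(report)
  out$responseCounts$decreaseHxBySession <-
    as.list(out$responseCounts$decreaseHxBySession)
  out
}
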