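#' Build a synthetic-cohort configuration
#'
#' Defaults describe the study conditions the generator emulates: a four-phase
#' gas protocol (baseline, isocapnic hypoxia, recovery baseline, hypercapnia)
#' in a healthy adult cohort. Baseline physiology and achieved stimuli follow
#' the group values of that protocol: resting nCBF 63 +/- 9 mL/100 g/min,
#' PETCO2 41.0 +/- 2.6 mmHg, PETO2 112.3 +/- 8.8 mmHg, SpO2 98 +/- 1 %;
#' achieved hypoxic PETO2 61.6 +/- 3.6 mmHg against a 55-70 mmHg target;
#' hypercapnia targets +6 mmHg PETCO2 and attains it on average
#' (+6.0 +/- 0.8 mmHg between sessions); during
#' hypoxia PETCO2 drifts by -0.4 +/- 0.9 mmHg despite isocapnic targeting.
#' True reactivity: hypercapnic CVR 4.33 %/mmHg (subject SD 1.13, session SD
#' 1.37); hypoxic CVR 0.10 %/-mmHg (subject SD 0.07, session SD 0.14), with a
#' 15% paradoxical-responder mixture whose subject-level hypoxic CVR is
#' negative. Acquisition noise SD 2.1 mL/100 g/min makes the median absolute
#' back-to-back nCBF difference ~2 mL/100 g/min (median of |N(0, 2*sigma^2)|
#' = sigma*sqrt(2)*qnorm(0.75) = 2.0 at sigma = 2.1).
#'
#' @param nSubjects,nSessions cohort dimensions (defaults 21 and 3).
#' @param seed integer RNG seed; the whole study is deterministic given it.
#' @param fidelity `"flow"` writes per-vessel flows directly; `"image"`
#'   additionally renders cine velocity maps that must be quantified.
#' @param vesselSplit named fractions of total flow per vessel (ICAs carry
#'   most of it; 0.38/0.38/0.12/0.12 by default).
#' @param brainVolumeMean,brainVolumeSd total brain volume (mL); the default
#'   1166 mL corresponds to a 1236 g brain at 1.06 g/mL, so that 779 mL/min
#'   of total flow normalises to 63 mL/100 g/min.
#' @param placementAffectFraction fraction of sessions in which slice
#'   placement 1 under-captures one vertebral artery; the affected vessel's
#'   placement-1 flows are attenuated by a factor drawn from
#'   `placementAlphaRange`.
#' @param traceNoiseScale multiplier on physiological trace noise (0 gives
#'   noise-free plateaus).
#' @param dropoutSpec optional data.frame (subject, session, phase) of phases
#'   to omit, emulating incomplete sessions.
#' @param ... overrides for any other [CohortConfig-class] slot
#'   (e.g. `cvrHcMean`, `ncbfNoiseSd`, `hxPetco2PerturbMean`).
#' @return a validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nSubjects = 4, nSessions = 2, seed = 1)
#' nSubjects(cfg)
#' @export
cohortConfig <- function(nSubjects = 21L, nSessions = 3L, seed = 1L,
                         fidelity = c("flow", "image"),
                         vesselSplit = c(L_ICA = 0.38, R_ICA = 0.38,
                                         L_VA = 0.12, R_VA = 0.12),
                         brainVolumeMean = 1166, brainVolumeSd = 110,
                         placementAffectFraction = 0.15,
                         traceNoiseScale = 1,
                         dropoutSpec = NULL, ...) {
  fidelity <- match.arg(fidelity)
  if (is.null(dropoutSpec))
    dropoutSpec <- data.frame(subject = character(0), session = integer(0),
                              phase = character(0), stringsAsFactors = FALSE)
  defaults <- list(
    nSubjects = as.integer(nSubjects), nSessions = as.integer(nSessions),
    seed = as.integer(seed), fidelity = fidelity,
    baselineNcbfMean = 63, baselineNcbfSd = 9,
    baselinePetco2Mean = 41.0, baselinePetco2Sd = 2.6,
    baselinePeto2Mean = 112.3, baselinePeto2Sd = 8.8,
    baselineSpo2Mean = 98, baselineSpo2Sd = 1,
    hrBaselineMean = 67, hrBaselineSd = 8,
    veBaselineMean = 9.2, veBaselineSd = 2.5,
    hcPetco2Delta = 6,
    hcPetco2AchievedMean = 6.0, hcPetco2AchievedSd = 0.8,
    hxPeto2TargetRange = c(55, 70),
    hxPeto2AchievedMean = 61.6, hxPeto2AchievedSd = 3.6,
    hxPetco2PerturbMean = -0.4, hxPetco2PerturbSd = 0.9,
    cvrHcMean = 4.33, cvrHcSdSubject = 1.13, cvrHcSdSession = 1.37,
    cvrHxMean = 0.10, cvrHxSdSubject = 0.07, cvrHxSdSession = 0.14,
    paradoxFraction = 0.15, paradoxMagMean = 0.08, paradoxMagSd = 0.04,
    ncbfNoiseSd = 2.1,
    traceNoiseScale = traceNoiseScale,
    spo2Peto2Slope = 0.158, spo2NoiseSd = 1.6,
    vesselSplit = vesselSplit,
    brainVolumeMean = brainVolumeMean, brainVolumeSd = brainVolumeSd,
    gmFraction = 0.6,
    placementAffectFraction = placementAffectFraction,
    placementAlphaRange = c(0.70, 1.0),
    cineGrid = 160L, cinePixelCm = 0.02,
    cineNoiseSd = 0, cineOffsetRange = c(-0.5, 0.5),
    dropoutSpec = dropoutSpec
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop("unknown CohortConfig field(s): ", paste(unknown, collapse = ", "))
  defaults[names(extra)] <- extra
  defaults$nSubjects <- as.integer(defaults$nSubjects)
  defaults$nSessions <- as.integer(defaults$nSessions)
  defaults$seed <- as.integer(defaults$seed)
  defaults$cineGrid <- as.integer(defaults$cineGrid)
  do.call(methods::new, c(list(Class = "CohortConfig"), defaults))
}

#' Strip all measurement imperfections from a configuration
#'
#' Returns a copy of `config` with acquisition noise, trace noise, cine
#' voxel noise and placement attenuation all set to zero/disabled. Under such
#' a configuration the analysis pipeline recovers every session's true CVR
#' exactly, which is the basis of the parameter-recovery checks.
#'
#' @param config a [CohortConfig-class].
#' @return a [CohortConfig-class] describing an idealised, noise-free study.
#' @export
zeroNoiseConfig <- function(config) {
  config@ncbfNoiseSd <- 0
  config@traceNoiseScale <- 0
  config@cineNoiseSd <- 0
  config@placementAffectFraction <- 0
  methods::validObject(config)
  config
}
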