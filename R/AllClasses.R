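
## Canonical vessel order used everywhere: flows, masks, splits.
.VESSELS <- c("L_ICA", "R_ICA", "L_VA", "R_VA")
.VA_VESSELS <- c("L_VA", "R_VA")
.PHASES <- c("BL", "HX", "RBL", "HC")
.N_BINS <- 8L

## Integer codes used in mask label arrays; static tissue is 9.
.MASK_CODES <- c(L_ICA = 1L, R_ICA = 2L, L_VA = 3L, R_VA = 4L)
.STATIC_CODE <- 9L

## Brain tissue density (g/mL) used to convert segmented volume to mass.
.TISSUE_DENSITY <- 1.06

#' CohortConfig: parameters of the synthetic study generator
#'
#' Holds every tunable of the synthetic cohort: cohort size, seed,
#' baseline physiology (normalised CBF, end-tidal gases, SpO2, heart rate,
#' ventilation), the achieved respiratory stimuli for the four-phase
#' protocol (baseline / hypoxia / recovery baseline / hypercapnia), true
#' reactivity distributions (subject- and session-level SDs), the
#' paradoxical-responder mixture, measurement noise, the vessel flow split,
#' and slice-placement attenuation of vertebral flows. Construct with
#' [cohortConfig()]; validity enforces the documented invariants.
#'
#' @slot nSubjects,nSessions,seed cohort dimensions and RNG seed.
#' @slot fidelity `"flow"` (per-vessel flows written directly) or `"image"`
#'   (cine velocity maps rendered and quantified downstream).
#' @slot vesselSplit fractions of total flow through L/R internal carotid and
#'   L/R vertebral arteries; must sum to 1.
#' @slot dropoutSpec data.frame (subject, session, phase) of omitted phases.
#' @keywords classes
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer",
  nSessions = "integer",
  seed = "integer",
  fidelity = "character",
  baselineNcbfMean = "numeric", baselineNcbfSd = "numeric",
  baselinePetco2Mean = "numeric", baselinePetco2Sd = "numeric",
  baselinePeto2Mean = "numeric", baselinePeto2Sd = "numeric",
  baselineSpo2Mean = "numeric", baselineSpo2Sd = "numeric",
  hrBaselineMean = "numeric", hrBaselineSd = "numeric",
  veBaselineMean = "numeric", veBaselineSd = "numeric",
  hcPetco2Delta = "numeric",
  hcPetco2AchievedMean = "numeric", hcPetco2AchievedSd = "numeric",
  hxPeto2TargetRange = "numeric",
  hxPeto2AchievedMean = "numeric", hxPeto2AchievedSd = "numeric",
  hxPetco2PerturbMean = "numeric", hxPetco2PerturbSd = "numeric",
  cvrHcMean = "numeric", cvrHcSdSubject = "numeric", cvrHcSdSession = "numeric",
  cvrHxMean = "numeric", cvrHxSdSubject = "numeric", cvrHxSdSession = "numeric",
  paradoxFraction = "numeric",
  paradoxMagMean = "numeric", paradoxMagSd = "numeric",
  ncbfNoiseSd = "numeric",
  traceNoiseScale = "numeric",
  spo2Peto2Slope = "numeric", spo2NoiseSd = "numeric",
  vesselSplit = "numeric",
  brainVolumeMean = "numeric", brainVolumeSd = "numeric",
  gmFraction = "numeric",
  placementAffectFraction = "numeric",
  placementAlphaRange = "numeric",
  cineGrid = "integer", cinePixelCm = "numeric",
  cineNoiseSd = "numeric", cineOffsetRange = "numeric",
  dropoutSpec = "data.frame"
))

setValidity("CohortConfig", function(object) {
  msgs <- character(0)
  chkSd <- function(slot) {
    if (methods::slot(object, slot) < 0)
      msgs <<- c(msgs, sprintf("'%s' must be >= 0", slot))
  }
  if (object@nSubjects < 1L) msgs <- c(msgs, "'nSubjects' must be >= 1")
  if (object@nSessions < 1L) msgs <- c(msgs, "'nSessions' must be >= 1")
  if (!object@fidelity %in% c("flow", "image"))
    msgs <- c(msgs, "'fidelity' must be \"flow\" or \"image\"")
  for (s in c("baselineNcbfSd", "baselinePetco2Sd", "baselinePeto2Sd",
              "baselineSpo2Sd", "hrBaselineSd", "veBaselineSd",
              "hcPetco2AchievedSd", "hxPeto2AchievedSd", "hxPetco2PerturbSd",
              "cvrHcSdSubject", "cvrHcSdSession", "cvrHxSdSubject",
              "cvrHxSdSession", "paradoxMagSd", "ncbfNoiseSd", "spo2NoiseSd",
              "brainVolumeSd", "cineNoiseSd"))
    chkSd(s)
  if (abs(sum(object@vesselSplit) - 1) > 1e-9)
    msgs <- c(msgs, "'vesselSplit' must sum to 1 (tolerance 1e-9)")
  if (length(object@vesselSplit) != 4L ||
      !identical(names(object@vesselSplit), .VESSELS))
    msgs <- c(msgs, sprintf("'vesselSplit' must be named %s",
                            paste(.VESSELS, collapse = ", ")))
  if (any(object@vesselSplit < 0))
    msgs <- c(msgs, "'vesselSplit' fractions must be >= 0")
  rng <- object@hxPeto2TargetRange
  if (length(rng) != 2L || rng[1] > rng[2] || rng[1] <= 0 ||
      rng[2] >= object@baselinePeto2Mean)
    msgs <- c(msgs, "'hxPeto2TargetRange' must lie within (0, baselinePeto2Mean)")
  if (object@hxPeto2AchievedMean <= 0 ||
      object@hxPeto2AchievedMean >= object@baselinePeto2Mean)
    msgs <- c(msgs, "'hxPeto2AchievedMean' must lie within (0, baselinePeto2Mean)")
  if (object@paradoxFraction < 0 || object@paradoxFraction > 1)
    msgs <- c(msgs, "'paradoxFraction' must be in [0, 1]")
  if (object@gmFraction <= 0 || object@gmFraction >= 1)
    msgs <- c(msgs, "'gmFraction' must be in (0, 1)")
  if (length(object@placementAlphaRange) != 2L ||
      object@placementAlphaRange[1] > object@placementAlphaRange[2] ||
      object@placementAlphaRange[1] <= 0 || object@placementAlphaRange[2] > 1)
    msgs <- c(msgs, "'placementAlphaRange' must be an increasing pair in (0, 1]")
  if (object@traceNoiseScale < 0)
    msgs <- c(msgs, "'traceNoiseScale' must be >= 0")
  if (nrow(object@dropoutSpec) &&
      !all(c("subject", "session", "phase") %in% names(object@dropoutSpec)))
    msgs <- c(msgs, "'dropoutSpec' needs columns subject, session, phase")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PhysioTrace: continuous physiological recordings for one session
#'
#' Time-stamped end-tidal gas, oximetry, heart-rate and ventilation channels
#' on a common monotonic grid, with a per-sample protocol phase label
#' (BL, HX, RBL, HC or transition).
#'
#' @slot time seconds, strictly increasing.
#' @slot petco2,peto2 end-tidal partial pressures, mmHg.
#' @slot spo2 oxygen saturation, percent, in (0, 100].
#' @slot heartRate beats/min.
#' @slot minuteVentilation L/min.
#' @slot phase character phase label per sample.
#' @keywords classes
#' @export
setClass("PhysioTrace", representation(
  time = "numeric", petco2 = "numeric", peto2 = "numeric",
  spo2 = "numeric", heartRate = "numeric", minuteVentilation = "numeric",
  phase = "character"
))

setValidity("PhysioTrace", function(object) {
  n <- length(object@time)
  lens <- c(length(object@petco2), length(object@peto2), length(object@spo2),
            length(object@heartRate), length(object@minuteVentilation),
            length(object@phase))
  if (any(lens != n)) return("all channels must have the same length as 'time'")
  if (n > 1 && any(diff(object@time) <= 0))
    return("'time' must be strictly increasing")
  if (any(object@spo2 <= 0 | object@spo2 > 100))
    return("'spo2' must lie in (0, 100]")
  TRUE
})

#' VelocityCine: one velocity-encoded cine acquisition
#'
#' Through-plane velocity maps over cardiac bins together with integer-coded
#' ROI masks (vessel codes 1-4 in canonical vessel order, static tissue 9)
#' and the in-plane pixel area. Velocities are cm/s; the mask array has the
#' same dimensions as the velocity array, so ROIs may differ between bins.
#'
#' @slot velocity numeric array (x, y, bin), cm/s.
#' @slot mask integer array (x, y, bin); 0 background, 1-4 vessels, 9 static.
#' @slot pixelArea cm^2 per pixel.
#' @keywords classes
#' @export
setClass("VelocityCine", representation(
  velocity = "array", mask = "array", pixelArea = "numeric"
))

setValidity("VelocityCine", function(object) {
  dv <- dim(object@velocity)
  if (length(dv) != 3L) return("'velocity' must be a 3-d array (x, y, bin)")
  if (dv[3] != .N_BINS) return(sprintf("'velocity' must have %d cardiac bins", .N_BINS))
  if (!identical(dim(object@mask), dv))
    return("'mask' must have the same dimensions as 'velocity'")
  if (!all(is.finite(object@velocity))) return("velocities must be finite")
  codes <- unique(as.integer(object@mask))
  if (!all(codes %in% c(0L, unname(.MASK_CODES), .STATIC_CODE)))
    return("mask codes must be 0, 1-4 (vessels) or 9 (static tissue)")
  if (length(object@pixelArea) != 1L || object@pixelArea <= 0)
    return("'pixelArea' must be a positive scalar")
  TRUE
})

#' SyntheticStudy: a complete simulated study
#'
#' Bundles everything one cohort run produces: the generating configuration,
#' per-session physiological traces, the acquisition table (timing, placement,
#' phase, per-vessel flows or cine references), per-subject anatomy, rendered
#' cines (image fidelity only), and the latent ground-truth parameter table.
#'
#' @slot config the [CohortConfig-class] used.
#' @slot traces named list of [PhysioTrace-class], keys `"<subject>_<session>"`.
#' @slot acquisitions data.frame, one row per scan.
#' @slot anatomy data.frame: subject, gm_vol_mL, wm_vol_mL.
#' @slot truth data.frame of true per-session parameters.
#' @slot cines named list of [VelocityCine-class] (empty at flow fidelity).
#' @keywords classes
#' @export
setClass("SyntheticStudy", representation(
  config = "CohortConfig",
  traces = "list",
  acquisitions = "data.frame",
  anatomy = "data.frame",
  truth = "data.frame",
  cines = "list"
))

setValidity("SyntheticStudy", function(object) {
  acq <- object@acquisitions
  need <- c("subject", "session", "acq_id", "phase", "placement",
            "start_s", "duration_s", "spo2_start", "hr_start",
            paste0("flow_", .VESSELS), "cine_id")
  if (!all(need %in% names(acq)))
    return(sprintf("acquisitions table missing column(s): %s",
                   paste(setdiff(need, names(acq)), collapse = ", ")))
  if (nrow(acq) && any(acq$duration_s <= 0))
    return("acquisition durations must be > 0")
  if (!all(c("subject", "gm_vol_mL", "wm_vol_mL") %in% names(object@anatomy)))
    return("anatomy table needs subject, gm_vol_mL, wm_vol_mL")
  keys <- unique(paste(acq$subject, acq$session, sep = "_"))
  if (!all(keys %in% names(object@traces)))
    return("every acquired session needs a physiological trace")
  TRUE
})
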