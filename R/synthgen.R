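## Protocol timeline (seconds). Phases: baseline, transition to hypoxia
## (gas ramp + flow stabilisation window), steady hypoxia, short transition
## back, recovery baseline, transition to hypercapnia, steady hypercapnia.
.PHASE_WINDOWS <- data.frame(
  phase = c("BL", "transition", "HX", "transition", "RBL", "transition", "HC"),
  start = c(0, 720, 1170, 1770, 1830, 2070, 2220),
  end   = c(720, 1170, 1770, 1830, 2070, 2220, 2760),
  stringsAsFactors = FALSE
)

## Scan schedule within a session: three steady scans per stimulus phase
## (two at placement 1, one at placement 2), transition scans at placement 1,
## a single recovery-baseline scan. 60 s scans.
.ACQ_SCHEDULE <- data.frame(
  phase = c("BL", "BL", "BL", "transition", "transition", "transition",
            "HX", "HX", "HX", "RBL", "transition", "HC", "HC", "HC"),
  placement = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 2L),
  start = c(480, 560, 640, 780, 900, 1020, 1200, 1280, 1360, 1950, 2100,
            2280, 2360, 2440),
  duration = 60,
  stringsAsFactors = FALSE
)

## Fixed phase offsets relative to baseline for heart rate (bpm) and minute
## ventilation (L/min): HX, RBL, HC.
.HR_OFFSETS <- c(HX = 5, RBL = -2, HC = 1)
.VE_OFFSETS <- c(HX = 1.6, RBL = -0.3, HC = 5.4)
.SPO2_HC_OFFSET <- 0.2

## Per-channel white-noise SDs on the continuous traces (scaled by
## traceNoiseScale).
.TRACE_NOISE <- c(petco2 = 0.5, peto2 = 1.5, spo2 = 0.4, hr = 2.0, ve = 0.8)

#' Draw the latent parameters of one synthetic subject
#'
#' Uses the current RNG stream (seed it, or let [generateCohort()] do so).
#' Subject-level means are drawn from the configured distributions; per-session
#' true reactivities add independent session-level deviations. The
#' paradoxical-responder mixture replaces a fraction of subjects' hypoxic
#' reactivity with a negative value; non-paradoxical subjects are drawn from
#' the positive part of the configured normal, so `paradoxFraction = 0`
#' guarantees no negative subject-level hypoxic CVR.
#'
#' @param config a [CohortConfig-class].
#' @return list with elements `ncbfBase`, `brainVolume`, `petco2Bl`,
#'   `peto2Bl`, `spo2Bl`, `hrBl`, `veBl`, subject-level `cvrHcSubject` /
#'   `cvrHxSubject`, per-session vectors `cvrHc` / `cvrHx`, and
#'   `responderClass` (`"typical"`, `"minimal"` or `"paradoxical"`).
#' @export
sampleSubjectParams <- function(config) {
  methods::validObject(config)
  k <- config@nSessions
  ncbfBase <- max(20, stats::rnorm(1, config@baselineNcbfMean, config@baselineNcbfSd))
  brainVolume <- max(600, stats::rnorm(1, config@brainVolumeMean, config@brainVolumeSd))
  petco2Bl <- stats::rnorm(1, config@baselinePetco2Mean, config@baselinePetco2Sd)
  peto2Bl <- stats::rnorm(1, config@baselinePeto2Mean, config@baselinePeto2Sd)
  spo2Bl <- min(100, stats::rnorm(1, config@baselineSpo2Mean, config@baselineSpo2Sd))
  hrBl <- stats::rnorm(1, config@hrBaselineMean, config@hrBaselineSd)
  veBl <- max(2, stats::rnorm(1, config@veBaselineMean, config@veBaselineSd))

  cvrHcSubject <- stats::rnorm(1, config@cvrHcMean, config@cvrHcSdSubject)
  paradox <- stats::runif(1) < config@paradoxFraction
  if (paradox) {
    cvrHxSubject <- -abs(stats::rnorm(1, config@paradoxMagMean, config@paradoxMagSd))
  } else if (config@cvrHxSdSubject == 0) {
    cvrHxSubject <- config@cvrHxMean
    if (cvrHxSubject < 0)
      stop("cvrHxMean < 0 with zero subject SD cannot satisfy a non-paradoxical draw")
  } else {
    repeat {                 # positive-part normal for non-paradoxical subjects
      cvrHxSubject <- stats::rnorm(1, config@cvrHxMean, config@cvrHxSdSubject)
      if (cvrHxSubject >= 0) break
    }
  }
  cvrHc <- cvrHcSubject + stats::rnorm(k, 0, config@cvrHcSdSession)
  cvrHx <- cvrHxSubject + stats::rnorm(k, 0, config@cvrHxSdSession)

  ## Expected hypoxic nCBF change at the nominal stimulus decides "minimal".
  nominalDrop <- config@baselinePeto2Mean - config@hxPeto2AchievedMean
  expectedDelta <- ncbfBase * cvrHxSubject / 100 * nominalDrop
  responderClass <- if (cvrHxSubject < 0) "paradoxical"
                    else if (abs(expectedDelta) < 2) "minimal"
                    else "typical"

  list(ncbfBase = ncbfBase, brainVolume = brainVolume,
       petco2Bl = petco2Bl, peto2Bl = peto2Bl, spo2Bl = spo2Bl,
       hrBl = hrBl, veBl = veBl,
       cvrHcSubject = cvrHcSubject, cvrHxSubject = cvrHxSubject,
       cvrHc = cvrHc, cvrHx = cvrHx, responderClass = responderClass)
}

## Piecewise-linear channel profile over the session timeline: constant
## plateaus per phase, linear ramps across the gas-retargeting windows.
.channelProfile <- function(tt, bl, hx, rbl, hc) {
  knots <- c(0, 720, 900, 1770, 1830, 2070, 2160, 2760)
  vals  <- c(bl, bl, hx, hx, rbl, rbl, hc, hc)
  stats::approx(knots, vals, xout = tt, rule = 2)$y
}

.phaseLabels <- function(tt) {
  lab <- character(length(tt))
  for (i in seq_len(nrow(.PHASE_WINDOWS)))
    lab[tt >= .PHASE_WINDOWS$start[i] & tt < .PHASE_WINDOWS$end[i]] <-
      .PHASE_WINDOWS$phase[i]
  lab[lab == ""] <- "transition"
  lab
}

## Build one session's physiological trace from its plateau values.
.makeTrace <- function(plateaus, noiseScale) {
  tt <- seq(0, 2759, by = 1)
  n <- length(tt)
  noise <- function(ch) stats::rnorm(n, 0, .TRACE_NOISE[[ch]] * noiseScale)
  p <- plateaus
  petco2 <- .channelProfile(tt, p$petco2["BL"], p$petco2["HX"], p$petco2["RBL"], p$petco2["HC"]) + noise("petco2")
  peto2  <- .channelProfile(tt, p$peto2["BL"],  p$peto2["HX"],  p$peto2["RBL"],  p$peto2["HC"])  + noise("peto2")
  spo2   <- .channelProfile(tt, p$spo2["BL"],   p$spo2["HX"],   p$spo2["RBL"],   p$spo2["HC"])   + noise("spo2")
  hr     <- .channelProfile(tt, p$hr["BL"],     p$hr["HX"],     p$hr["RBL"],     p$hr["HC"])     + noise("hr")
  ve     <- .channelProfile(tt, p$ve["BL"],     p$ve["HX"],     p$ve["RBL"],     p$ve["HC"])     + noise("ve")
  methods::new("PhysioTrace", time = tt, petco2 = petco2, peto2 = peto2,
               spo2 = pmin(100, pmax(0.5, spo2)),
               heartRate = hr, minuteVentilation = pmax(0.5, ve),
               phase = .phaseLabels(tt))
}

#' Generate a complete synthetic study
#'
#' Draws a cohort of subjects and sessions with known ground truth and builds,
#' per session, a continuous physiological trace and the full scan schedule
#' (three steady-state scans per stimulus phase, transition scans, one
#' recovery-baseline scan; two slice placements). Steady flows equal the
#' subject's true baseline nCBF modulated through the session's true
#' reactivities by the gas levels the trace actually shows inside each scan
#' window (so the downstream estimates are exactly recoverable at zero
#' noise), converted to mL/min by brain mass, split across the four neck
#' vessels, and perturbed by acquisition noise. Placement-1 vertebral flows
#' are attenuated in a configurable fraction of sessions, emulating
#' non-orthogonal slice placement. At image fidelity each acquisition is also
#' rendered as a cine velocity map (see [synthVelocityCine()]) and the flow
#' columns are left `NA` for the quantification stage to fill.
#'
#' The generator is fully deterministic given `config`'s seed.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticStudy-class].
#' @examples
#' study <- generateCohort(cohortConfig(nSubjects = 2, nSessions = 2, seed = 7))
#' study
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  subjects <- sprintf("S%02d", seq_len(config@nSubjects))
  split <- config@vesselSplit

  traces <- list()
  acqRows <- list()
  truthRows <- list()
  anatomyRows <- list()
  cineJobs <- list()

  p1Steady <- function(phase) which(.ACQ_SCHEDULE$phase == phase &
                                    .ACQ_SCHEDULE$placement == 1L)

  for (si in seq_along(subjects)) {
    subj <- subjects[si]
    sp <- sampleSubjectParams(config)
    mass <- (sp$brainVolume) * .TISSUE_DENSITY
    anatomyRows[[subj]] <- data.frame(
      subject = subj,
      gm_vol_mL = sp$brainVolume * config@gmFraction,
      wm_vol_mL = sp$brainVolume * (1 - config@gmFraction),
      stringsAsFactors = FALSE)

    for (ses in seq_len(config@nSessions)) {
      ## Session-level achieved physiology.
      petco2Bl <- sp$petco2Bl + stats::rnorm(1, 0, 0.5)
      peto2Bl <- sp$peto2Bl + stats::rnorm(1, 0, 1.0)
      spo2Bl <- min(100, sp$spo2Bl + stats::rnorm(1, 0, 0.3))
      hrBl <- sp$hrBl + stats::rnorm(1, 0, 2)
      veBl <- max(2, sp$veBl + stats::rnorm(1, 0, 0.5))
      perturb <- stats::rnorm(1, config@hxPetco2PerturbMean, config@hxPetco2PerturbSd)
      hcDelta <- stats::rnorm(1, config@hcPetco2AchievedMean, config@hcPetco2AchievedSd)
      peto2Hx <- min(peto2Bl - 10,
                     max(25, stats::rnorm(1, config@hxPeto2AchievedMean,
                                          config@hxPeto2AchievedSd)))
      spo2Hx <- min(100, max(55,
        spo2Bl - config@spo2Peto2Slope * (peto2Bl - peto2Hx) +
          stats::rnorm(1, 0, config@spo2NoiseSd)))

      affected <- stats::runif(1) < config@placementAffectFraction
      alpha <- c(L_VA = 1, R_VA = 1)
      if (affected) {
        v <- sample(.VA_VESSELS, 1L)
        alpha[[v]] <- stats::runif(1, config@placementAlphaRange[1],
                                   config@placementAlphaRange[2])
      }

      plateaus <- list(
        petco2 = c(BL = petco2Bl, HX = petco2Bl + perturb,
                   RBL = petco2Bl, HC = petco2Bl + hcDelta),
        peto2 = c(BL = peto2Bl, HX = peto2Hx, RBL = peto2Bl, HC = peto2Bl),
        spo2 = c(BL = spo2Bl, HX = spo2Hx, RBL = spo2Bl,
                 HC = min(100, spo2Bl + .SPO2_HC_OFFSET)),
        hr = c(BL = hrBl, HX = hrBl + .HR_OFFSETS[["HX"]],
               RBL = hrBl + .HR_OFFSETS[["RBL"]], HC = hrBl + .HR_OFFSETS[["HC"]]),
        ve = c(BL = veBl, HX = veBl + .VE_OFFSETS[["HX"]],
               RBL = veBl + .VE_OFFSETS[["RBL"]], HC = veBl + .VE_OFFSETS[["HC"]]))
      trace <- .makeTrace(plateaus, config@traceNoiseScale)
      key <- paste(subj, ses, sep = "_")
      traces[[key]] <- trace

      ## Gas means inside each scan window, as the analysis will see them.
      win <- lapply(seq_len(nrow(.ACQ_SCHEDULE)), function(i)
        alignAcquisition(trace, .ACQ_SCHEDULE$start[i], .ACQ_SCHEDULE$duration[i]))
      wPetco2 <- vapply(win, `[[`, numeric(1), "petco2")
      wPeto2 <- vapply(win, `[[`, numeric(1), "peto2")
      wSpo2 <- vapply(win, `[[`, numeric(1), "spo2")
      wHr <- vapply(win, `[[`, numeric(1), "hr")
      refPetco2 <- mean(wPetco2[p1Steady("BL")])
      refPeto2 <- mean(wPeto2[p1Steady("BL")])

      cvrHc <- sp$cvrHc[ses]
      cvrHx <- sp$cvrHx[ses]

      nAcq <- nrow(.ACQ_SCHEDULE)
      acqNoise <- stats::rnorm(nAcq, 0, config@ncbfNoiseSd)
      ncbf <- sp$ncbfBase * (1 + cvrHc / 100 * (wPetco2 - refPetco2) +
                                 cvrHx / 100 * (refPeto2 - wPeto2)) + acqNoise
      flowMat <- (ncbf * mass / 100) %o% split
      isP1 <- .ACQ_SCHEDULE$placement == 1L
      flowMat[isP1, .VA_VESSELS] <-
        flowMat[isP1, .VA_VESSELS] * rep(alpha, each = sum(isP1))
      sesAcq <- data.frame(
        subject = subj, session = ses,
        acq_id = sprintf("%s_%d_%02d", subj, ses, seq_len(nAcq)),
        phase = .ACQ_SCHEDULE$phase, placement = .ACQ_SCHEDULE$placement,
        start_s = .ACQ_SCHEDULE$start, duration_s = .ACQ_SCHEDULE$duration,
        spo2_start = wSpo2, hr_start = wHr,
        flow_L_ICA = flowMat[, "L_ICA"], flow_R_ICA = flowMat[, "R_ICA"],
        flow_L_VA = flowMat[, "L_VA"], flow_R_VA = flowMat[, "R_VA"],
        cine_id = NA_character_, stringsAsFactors = FALSE)

      ## Drop configured (subject, session, phase) omissions.
      ds <- config@dropoutSpec
      if (nrow(ds)) {
        hit <- ds$subject == subj & ds$session == ses
        if (any(hit))
          sesAcq <- sesAcq[!(sesAcq$phase %in% ds$phase[hit]), , drop = FALSE]
      }
      acqRows[[key]] <- sesAcq

      petco2Hx <- mean(wPetco2[p1Steady("HX")])
      peto2HxMeas <- mean(wPeto2[p1Steady("HX")])
      petco2Hc <- mean(wPetco2[p1Steady("HC")])
      spo2BlMeas <- mean(wSpo2[p1Steady("BL")])
      spo2HxMeas <- mean(wSpo2[p1Steady("HX")])
      spo2Drop <- spo2BlMeas - spo2HxMeas
      truthRows[[key]] <- data.frame(
        subject = subj, session = ses,
        ncbf_base_true = sp$ncbfBase,
        brain_volume_mL = sp$brainVolume, brain_mass_g = mass,
        cvr_hc_true = cvrHc, cvr_hx_true = cvrHx,
        cvr_hx_spo2_implied = if (abs(spo2Drop) > 1e-12)
          cvrHx * (refPeto2 - peto2HxMeas) / spo2Drop else NA_real_,
        cvr_hc_subject = sp$cvrHcSubject, cvr_hx_subject = sp$cvrHxSubject,
        responder_class = sp$responderClass,
        va_alpha_L = alpha[["L_VA"]], va_alpha_R = alpha[["R_VA"]],
        petco2_bl_meas = refPetco2, petco2_hx_meas = petco2Hx,
        petco2_hc_meas = petco2Hc,
        peto2_bl_meas = refPeto2, peto2_hx_meas = peto2HxMeas,
        spo2_bl_meas = spo2BlMeas, spo2_hx_meas = spo2HxMeas,
        stringsAsFactors = FALSE)

      if (config@fidelity == "image") cineJobs[[key]] <- sesAcq
    }
  }

  acq <- do.call(rbind, acqRows)
  rownames(acq) <- NULL
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  anat <- do.call(rbind, anatomyRows)
  rownames(anat) <- NULL

  cineList <- list()
  if (config@fidelity == "image") {
    geom <- defaultCineGeometry(config)
    for (key in names(cineJobs)) {
      sesAcq <- cineJobs[[key]]
      for (i in seq_len(nrow(sesAcq))) {
        flows <- unlist(sesAcq[i, paste0("flow_", .VESSELS)])
        names(flows) <- .VESSELS
        offset <- stats::runif(1, config@cineOffsetRange[1], config@cineOffsetRange[2])
        cineList[[sesAcq$acq_id[i]]] <-
          synthVelocityCine(flows, geom, noiseSd = config@cineNoiseSd,
                            offset = offset)
      }
    }
    acq$cine_id <- acq$acq_id
    acq[paste0("flow_", .VESSELS)] <- NA_real_
  }

  methods::new("SyntheticStudy", config = config, traces = traces,
               acquisitions = acq, anatomy = anat, truth = truth,
               cines = cineList)
}
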