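#' Fit the group relationship between slice placements for one vessel
#'
#' Ordinary least squares of placement-2 steady-state flow on placement-1
#' steady-state flow, pooled across the group. The residual SD (root mean
#' squared error on n - 2 degrees of freedom) scales the outlier threshold
#' used by [reconcileVertebralPlacements()]. With `forceSlope1 = TRUE` the
#' slope is fixed at 1 and only a mean offset is fitted (n - 1 df).
#'
#' @param p1,p2 paired flows, mL/min, one pair per session and phase.
#' @param vessel label stored with the model.
#' @param forceSlope1 fix the slope at 1.
#' @return a `PlacementModel`: list with `vessel`, `slope`, `intercept`,
#'   `residualSd`, `n`.
#' @examples
#' m <- fitPlacementModel(c(50, 60, 70, 80), 1.05 * c(50, 60, 70, 80), "L_VA")
#' m$slope; m$residualSd
#' @export
fitPlacementModel <- function(p1, p2, vessel = "VA", forceSlope1 = FALSE) {
  ok <- is.finite(p1) & is.finite(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  n <- length(p1)
  if (n < 3L)
    stop("need >= 3 placement pairs to model the relationship; got ", n)
  if (stats::sd(p1) == 0)
    stop("placement-1 flows are constant; the relationship is degenerate")
  if (forceSlope1) {
    intercept <- mean(p2 - p1)
    slope <- 1
    sse <- sum((p2 - p1 - intercept)^2)
    rsd <- sqrt(sse / (n - 1))
  } else {
    fit <- stats::lm(p2 ~ p1)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    rsd <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  }
  structure(list(vessel = vessel, slope = slope, intercept = intercept,
                 residualSd = rsd, n = n),
            class = "PlacementModel")
}

#' @export
print.PlacementModel <- function(x, ...) {
  cat(sprintf("PlacementModel [%s]: p2 = %.3f + %.3f * p1, residual SD %.2f mL/min (n = %d)\n",
              x$vessel, x$intercept, x$slope, x$residualSd, x$n))
  invisible(x)
}

#' Decide whether placement-2 vertebral flows replace placement-1 flows
#'
#' A session's vertebral artery is substituted when, at any steady-state
#' timepoint of that session, the placement-2 flow exceeds the value the
#' group model predicts from placement 1 by more than `multiplier` (1.96 by
#' default) times the model's residual SD. The rule is one-sided: placement-2
#' flows below the prediction never trigger substitution. A configurable
#' floor on the residual SD prevents a degenerate zero threshold.
#'
#' @param model a `PlacementModel` from [fitPlacementModel()].
#' @param p1,p2 this session's paired steady-state flows (one pair per
#'   steady-state timepoint), mL/min.
#' @param multiplier threshold multiplier on the residual SD.
#' @param sdFloor minimum residual SD, mL/min (default 1).
#' @return list: `substitute` (logical), `deviations` (observed minus
#'   predicted p2), `threshold` (mL/min).
#' @export
reconcileVertebralPlacements <- function(model, p1, p2, multiplier = 1.96,
                                         sdFloor = 1) {
  stopifnot(length(p1) == length(p2), multiplier > 0)
  rsd <- model$residualSd
  dev <- p2 - (model$intercept + model$slope * p1)
  if (rsd <= 0 && sdFloor <= 0) {
    if (any(dev > 0))
      stop("placement model residual SD is zero with a positive deviation; ",
           "set a positive 'sdFloor' to obtain a usable threshold")
  }
  thr <- multiplier * max(rsd, sdFloor)
  list(substitute = any(dev > thr), deviations = dev, threshold = thr)
}

## Paired placement-1 / placement-2 steady-state vertebral flows, one row per
## session x phase x vessel with both placements measured.
.placementPairs <- function(steadyAll) {
  empty <- data.frame(subject = character(0), session = integer(0),
                      phase = character(0), vessel = character(0),
                      p1 = numeric(0), p2 = numeric(0))
  if (!nrow(steadyAll)) return(empty)
  out <- list()
  for (v in .VA_VESSELS) {
    col <- paste0("flow_", v)
    agg <- stats::aggregate(steadyAll[[col]],
                            by = list(subject = steadyAll$subject,
                                      session = steadyAll$session,
                                      phase = steadyAll$phase,
                                      placement = steadyAll$placement),
                            FUN = mean)
    w <- stats::reshape(agg, direction = "wide", timevar = "placement",
                        idvar = c("subject", "session", "phase"))
    if (!all(c("x.1", "x.2") %in% names(w))) next
    w <- w[is.finite(w$x.1) & is.finite(w$x.2), , drop = FALSE]
    if (!nrow(w)) next
    out[[v]] <- data.frame(subject = w$subject, session = w$session,
                           phase = w$phase, vessel = v,
                           p1 = w$x.1, p2 = w$x.2, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Steady-state CBF per phase for one session
#'
#' Carotid flows are the mean over the phase's steady-state placement-1
#' acquisitions. Vertebral flows are the same, unless the vessel is flagged
#' for substitution, in which case the phase's placement-2 flows are used
#' instead (for phases without a placement-2 acquisition, the recovery
#' baseline here, placement-1 values are retained). Phase physiology is the
#' mean over the placement-1 steady acquisitions' aligned values, regardless
#' of substitution. Missing phases are simply absent from the result.
#'
#' @param sessionAcq acquisition rows of one session, with flow columns and
#'   aligned physio columns (`petco2`, `peto2`, `ve`, `spo2`, `hr`).
#' @param mass brain mass, g.
#' @param substitutions named logical, `L_VA` and `R_VA`.
#' @return data.frame with one row per available phase: cbf (mL/min), ncbf
#'   (mL/100 g/min) and phase physiology.
#' @export
steadyStateCbf <- function(sessionAcq, mass,
                           substitutions = c(L_VA = FALSE, R_VA = FALSE)) {
  stopifnot(mass > 0)
  present <- character(0)
  cols <- c("cbf", "ncbf", "petco2", "peto2", "ve", "spo2", "hr",
            "flow_L_VA", "flow_R_VA")
  acc <- matrix(NA_real_, nrow = length(.PHASES), ncol = length(cols),
                dimnames = list(.PHASES, cols))
  isP1 <- sessionAcq$placement == 1L
  for (ph in .PHASES) {
    inPh <- sessionAcq$phase == ph
    p1 <- which(inPh & isP1)
    if (!length(p1)) next
    p2 <- which(inPh & !isP1)
    flows <- vapply(.VESSELS, function(v)
      mean(sessionAcq[[paste0("flow_", v)]][p1]), numeric(1))
    for (v in .VA_VESSELS)
      if (isTRUE(substitutions[[v]]) && length(p2))
        flows[[v]] <- mean(sessionAcq[[paste0("flow_", v)]][p2])
    cbf <- sum(flows)
    acc[ph, ] <- c(cbf, cbf / mass * 100,
                   mean(sessionAcq$petco2[p1]), mean(sessionAcq$peto2[p1]),
                   mean(sessionAcq$ve[p1]), mean(sessionAcq$spo2[p1]),
                   mean(sessionAcq$hr[p1]),
                   flows[["L_VA"]], flows[["R_VA"]])
    present <- c(present, ph)
  }
  if (!length(present)) return(NULL)
  res <- data.frame(phase = present, acc[present, , drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Hypercapnic cerebrovascular reactivity
#'
#' Percent CBF change from baseline per mmHg rise in end-tidal CO2:
#' `100 * (cbfHc - cbfBl) / cbfBl / (petco2Hc - petco2Bl)`.
#'
#' @param cbfBl,cbfHc baseline and hypercapnic CBF (any consistent units).
#' @param petco2Bl,petco2Hc end-tidal CO2, mmHg.
#' @return CVR, %/mmHg.
#' @examples
#' cvrHypercapnic(63, 77, 41.0, 46.0)
#' @export
cvrHypercapnic <- function(cbfBl, cbfHc, petco2Bl, petco2Hc) {
  stopifnot(cbfBl > 0)
  d <- petco2Hc - petco2Bl
  if (d == 0) stop("end-tidal CO2 did not change; hypercapnic CVR is undefined")
  100 * (cbfHc - cbfBl) / cbfBl / d
}

#' Hypoxic cerebrovascular reactivity relative to end-tidal O2
#'
#' Percent CBF change from baseline per mmHg *fall* in end-tidal O2:
#' `-100 * (cbfHx - cbfBl) / cbfBl / (peto2Hx - peto2Bl)`. A CBF rise as
#' PETO2 falls gives positive CVR; a paradoxical CBF fall gives negative CVR.
#'
#' @param cbfBl,cbfHx baseline and hypoxic CBF.
#' @param peto2Bl,peto2Hx end-tidal O2, mmHg.
#' @return CVR, %/-mmHg.
#' @examples
#' cvrHypoxicPeto2(63, 67, 112.3, 61.6)
#' @export
cvrHypoxicPeto2 <- function(cbfBl, cbfHx, peto2Bl, peto2Hx) {
  stopifnot(cbfBl > 0)
  d <- peto2Hx - peto2Bl
  if (d == 0) stop("end-tidal O2 did not change; hypoxic CVR is undefined")
  -100 * (cbfHx - cbfBl) / cbfBl / d
}

#' Hypoxic cerebrovascular reactivity relative to oxygen saturation
#'
#' `-100 * (cbfHx - cbfBl) / cbfBl / (spo2Hx - spo2Bl)`; positive when CBF
#' rises as saturation falls.
#'
#' @param cbfBl,cbfHx baseline and hypoxic CBF.
#' @param spo2Bl,spo2Hx oxygen saturation, percent.
#' @return CVR, %/-%SpO2.
#' @examples
#' cvrHypoxicSpo2(63, 67, 98, 90)
#' @export
cvrHypoxicSpo2 <- function(cbfBl, cbfHx, spo2Bl, spo2Hx) {
  stopifnot(cbfBl > 0)
  d <- spo2Hx - spo2Bl
  if (d == 0) stop("SpO2 did not change; hypoxic CVR is undefined")
  -100 * (cbfHx - cbfBl) / cbfBl / d
}

#' Remove the CO2-attributable component from a hypoxic CBF change
#'
#' Isocapnic targeting during hypoxia is imperfect; any concomitant end-tidal
#' CO2 change contributes its own CBF change through that session's
#' hypercapnic reactivity. The estimated contribution
#' `ncbfBl * (cvrHc / 100) * deltaPetco2Hx` is subtracted from the observed
#' hypoxic change, and the hypoxic CVR equations are then re-evaluated with
#' the corrected change. With no CO2 change the correction is the identity.
#'
#' @param deltaNcbfHx observed hypoxic nCBF change, mL/100 g/min.
#' @param ncbfBl baseline nCBF, mL/100 g/min.
#' @param cvrHc the same session's hypercapnic CVR, %/mmHg.
#' @param deltaPetco2Hx concomitant PETCO2 change (hypoxia minus baseline),
#'   mmHg.
#' @return corrected nCBF change, mL/100 g/min.
#' @examples
#' correctForPetco2(3, 63, 4.33, -0.4)   # 4.09
#' @export
correctForPetco2 <- function(deltaNcbfHx, ncbfBl, cvrHc, deltaPetco2Hx) {
  deltaNcbfHx - ncbfBl * (cvrHc / 100) * deltaPetco2Hx
}

#' Median absolute back-to-back difference
#'
#' The median of absolute differences between immediately repeated
#' steady-state measurements; CBF changes below it are treated as within
#' measurement noise and natural fluctuation.
#'
#' @param diffs numeric vector of back-to-back differences (mL/100 g/min),
#'   or the data.frame produced by [backToBackDiffs()].
#' @return the threshold, mL/100 g/min.
#' @examples
#' meaningfulChangeThreshold(c(1, -2, 3))   # 2
#' @export
meaningfulChangeThreshold <- function(diffs) {
  if (is.data.frame(diffs)) diffs <- diffs$diff
  diffs <- diffs[is.finite(diffs)]
  if (!length(diffs)) stop("no back-to-back pairs available")
  stats::median(abs(diffs))
}

#' Back-to-back steady-state nCBF differences of a study
#'
#' For every session and stimulus-or-baseline phase with repeated
#' placement-1 steady acquisitions, the difference (second minus first, in
#' acquisition order) of normalised CBF.
#'
#' @param study a [SyntheticStudy-class].
#' @return data.frame: subject, session, phase, diff (mL/100 g/min).
#' @export
backToBackDiffs <- function(study) {
  .backToBackFromTable(.steadyP1Table(study))
}

## tab needs subject, session, phase, start_s, ncbf (steady placement-1 rows)
.backToBackFromTable <- function(tab) {
  empty <- data.frame(subject = character(0), session = integer(0),
                      phase = character(0), first = numeric(0),
                      second = numeric(0), diff = numeric(0))
  if (nrow(tab) < 2L) return(empty)
  tab <- tab[order(tab$subject, tab$session, tab$phase, tab$start_s), ,
             drop = FALSE]
  key <- paste(tab$subject, tab$session, tab$phase)
  n <- nrow(tab)
  idx <- which(key[-n] == key[-1])
  if (!length(idx)) return(empty)
  data.frame(subject = tab$subject[idx], session = tab$session[idx],
             phase = tab$phase[idx],
             first = tab$ncbf[idx], second = tab$ncbf[idx + 1L],
             diff = tab$ncbf[idx + 1L] - tab$ncbf[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a CBF response against the meaningful-change threshold
#'
#' @param delta nCBF change(s), mL/100 g/min.
#' @param threshold positive threshold, mL/100 g/min.
#' @return character vector: `"increase"`, `"decrease"` or `"minimal"`.
#' @examples
#' classifyResponse(c(3, -1.5, -2.5), 2)
#' @export
classifyResponse <- function(delta, threshold) {
  stopifnot(threshold > 0)
  ifelse(!is.finite(delta), NA_character_,
         ifelse(abs(delta) < threshold, "minimal",
                ifelse(delta > 0, "increase", "decrease")))
}

#' Run the full CVR analysis on a study
#'
#' Quantifies flows if needed, aligns physiology, fits the placement
#' relationship per vertebral vessel across the group, applies the
#' substitution rule per session, combines steady-state acquisitions into
#' per-phase CBF, evaluates hypercapnic and hypoxic CVR, applies the
#' concomitant-PETCO2 correction where a hypercapnic measurement exists, and
#' classifies responses against the back-to-back meaningful-change threshold.
#'
#' @param study a [SyntheticStudy-class].
#' @param multiplier,sdFloor substitution rule tuning, see
#'   [reconcileVertebralPlacements()].
#' @param pooledVesselFit fit one placement model pooling both vertebral
#'   arteries instead of one per vessel.
#' @param forceSlope1 see [fitPlacementModel()].
#' @param applyCorrection compute the CO2-corrected hypoxic metrics.
#' @param threshold meaningful-change threshold override; by default the
#'   median absolute back-to-back difference of this study.
#' @return a `CVRAnalysis` list: `sessions` (per-phase steady-state table),
#'   `cvr` (one row per subject x session), `placementModels`,
#'   `substitutions`, `threshold`, `backToBack`.
#' @examples
#' study <- generateCohort(cohortConfig(nSubjects = 4, nSessions = 2, seed = 11))
#' res <- analyzeCvr(study)
#' head(res$cvr)
#' @export
analyzeCvr <- function(study, multiplier = 1.96, sdFloor = 1,
                       pooledVesselFit = FALSE, forceSlope1 = FALSE,
                       applyCorrection = TRUE, threshold = NULL) {
  study <- quantifyStudy(study)
  acq <- study@acquisitions
  phys <- acquisitionPhysio(study)
  acq <- cbind(acq, phys[match(acq$acq_id, phys$acq_id),
                         c("petco2", "peto2", "ve", "spo2", "hr")])
  steadyAll <- acq[acq$phase %in% .PHASES, , drop = FALSE]
  massBy <- .massLookup(study)

  pairs <- .placementPairs(steadyAll)
  models <- list()
  if (nrow(pairs) >= 3L) {
    if (pooledVesselFit) {
      m <- fitPlacementModel(pairs$p1, pairs$p2, "VA_pooled", forceSlope1)
      models <- list(L_VA = m, R_VA = m)
    } else {
      for (v in .VA_VESSELS) {
        pv <- pairs[pairs$vessel == v, , drop = FALSE]
        if (nrow(pv) >= 3L)
          models[[v]] <- fitPlacementModel(pv$p1, pv$p2, v, forceSlope1)
      }
    }
  }

  sessionsKeys <- unique(steadyAll[, c("subject", "session")])
  sessRows <- list(); cvrRows <- list(); subRows <- list()
  for (i in seq_len(nrow(sessionsKeys))) {
    subj <- sessionsKeys$subject[i]; ses <- sessionsKeys$session[i]
    sAcq <- acq[acq$subject == subj & acq$session == ses, , drop = FALSE]
    subs <- c(L_VA = FALSE, R_VA = FALSE)
    for (v in .VA_VESSELS) {
      if (is.null(models[[v]])) next
      pv <- pairs[pairs$vessel == v & pairs$subject == subj &
                  pairs$session == ses, , drop = FALSE]
      if (!nrow(pv)) next
      dec <- reconcileVertebralPlacements(models[[v]], pv$p1, pv$p2,
                                          multiplier, sdFloor)
      subs[[v]] <- dec$substitute
    }
    subRows[[i]] <- data.frame(subject = subj, session = ses,
                               sub_L_VA = subs[["L_VA"]], sub_R_VA = subs[["R_VA"]],
                               stringsAsFactors = FALSE)
    ph <- steadyStateCbf(sAcq[sAcq$phase %in% .PHASES, , drop = FALSE],
                         massBy[[subj]], subs)
    if (is.null(ph) || !nrow(ph)) next
    sessRows[[i]] <- cbind(subject = subj, session = ses, ph,
                           sub_L_VA = subs[["L_VA"]], sub_R_VA = subs[["R_VA"]])

    g <- function(phase, var) {
      r <- ph[ph$phase == phase, var]
      if (length(r)) r else NA_real_
    }
    ncbfBl <- g("BL", "ncbf")
    row <- data.frame(subject = subj, session = ses, ncbf_bl = ncbfBl,
                      delta_ncbf_hx = NA_real_, delta_ncbf_hc = NA_real_,
                      delta_petco2_hx = NA_real_,
                      cvr_hc = NA_real_, cvr_hx_peto2 = NA_real_,
                      cvr_hx_spo2 = NA_real_,
                      delta_ncbf_hx_corr = NA_real_,
                      cvr_hx_peto2_corr = NA_real_, cvr_hx_spo2_corr = NA_real_,
                      sub_L_VA = subs[["L_VA"]], sub_R_VA = subs[["R_VA"]],
                      stringsAsFactors = FALSE)
    if (is.finite(ncbfBl) && ncbfBl > 0) {
      if (is.finite(g("HC", "ncbf")) && g("HC", "petco2") != g("BL", "petco2")) {
        row$delta_ncbf_hc <- g("HC", "ncbf") - ncbfBl
        row$cvr_hc <- cvrHypercapnic(ncbfBl, g("HC", "ncbf"),
                                     g("BL", "petco2"), g("HC", "petco2"))
      }
      if (is.finite(g("HX", "ncbf"))) {
        dHx <- g("HX", "ncbf") - ncbfBl
        row$delta_ncbf_hx <- dHx
        row$delta_petco2_hx <- g("HX", "petco2") - g("BL", "petco2")
        if (g("HX", "peto2") != g("BL", "peto2"))
          row$cvr_hx_peto2 <- cvrHypoxicPeto2(ncbfBl, g("HX", "ncbf"),
                                              g("BL", "peto2"), g("HX", "peto2"))
        if (g("HX", "spo2") != g("BL", "spo2"))
          row$cvr_hx_spo2 <- cvrHypoxicSpo2(ncbfBl, g("HX", "ncbf"),
                                            g("BL", "spo2"), g("HX", "spo2"))
        if (applyCorrection && is.finite(row$cvr_hc)) {
          dCorr <- correctForPetco2(dHx, ncbfBl, row$cvr_hc, row$delta_petco2_hx)
          row$delta_ncbf_hx_corr <- dCorr
          if (g("HX", "peto2") != g("BL", "peto2"))
            row$cvr_hx_peto2_corr <- -100 * (dCorr / ncbfBl) /
              (g("HX", "peto2") - g("BL", "peto2"))
          if (g("HX", "spo2") != g("BL", "spo2"))
            row$cvr_hx_spo2_corr <- -100 * (dCorr / ncbfBl) /
              (g("HX", "spo2") - g("BL", "spo2"))
        }
      }
    }
    cvrRows[[i]] <- row
  }

  sessions <- do.call(rbind, sessRows); rownames(sessions) <- NULL
  cvr <- do.call(rbind, cvrRows); rownames(cvr) <- NULL
  p1tab <- steadyAll[steadyAll$placement == 1L, , drop = FALSE]
  p1tab$ncbf <- rowSums(p1tab[, paste0("flow_", .VESSELS)]) /
    massBy[p1tab$subject] * 100
  b2b <- .backToBackFromTable(p1tab)
  thr <- if (is.null(threshold)) meaningfulChangeThreshold(b2b) else threshold
  if (thr > 0) {
    cvr$response_hx <- classifyResponse(cvr$delta_ncbf_hx, thr)
    cvr$response_hc <- classifyResponse(cvr$delta_ncbf_hc, thr)
  } else {
    ## noise-free data: every nonzero change is real
    cvr$response_hx <- ifelse(!is.finite(cvr$delta_ncbf_hx), NA_character_,
                              ifelse(cvr$delta_ncbf_hx > 0, "increase",
                                     ifelse(cvr$delta_ncbf_hx < 0, "decrease",
                                            "minimal")))
    cvr$response_hc <- ifelse(!is.finite(cvr$delta_ncbf_hc), NA_character_,
                              ifelse(cvr$delta_ncbf_hc > 0, "increase",
                                     ifelse(cvr$delta_ncbf_hc < 0, "decrease",
                                            "minimal")))
  }
  subsTab <- do.call(rbind, subRows); rownames(subsTab) <- NULL

  structure(list(sessions = sessions, cvr = cvr, placementModels = models,
                 substitutions = subsTab, threshold = thr, backToBack = b2b),
            class = "CVRAnalysis")
}

#' @export
print.CVRAnalysis <- function(x, ...) {
  cat(sprintf("CVRAnalysis: %d session(s), %d with hypercapnic CVR, %d with hypoxic CVR\n",
              nrow(x$cvr), sum(is.finite(x$cvr$cvr_hc)),
              sum(is.finite(x$cvr$cvr_hx_peto2))))
  cat(sprintf("  meaningful-change threshold %.2f mL/100 g/min; %d vertebral substitution(s)\n",
              x$threshold, sum(x$substitutions$sub_L_VA) + sum(x$substitutions$sub_R_VA)))
  invisible(x)
}
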