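#' Align a physiological trace with one scan window
#'
#' End-tidal gas and ventilation channels are averaged over the half-open
#' window `[start, start + duration)`; a sample falling exactly at
#' `start + duration` belongs to the next window. SpO2 and heart rate are
#' taken as the sample nearest the scan start (they are spot readings, not
#' window averages); set `averageSpo2Hr = TRUE` to average them like the gas
#' channels instead.
#'
#' @param trace a [PhysioTrace-class].
#' @param start,duration window in seconds; `duration > 0`.
#' @param averageSpo2Hr average SpO2/HR over the window instead of the
#'   nearest-to-start sample.
#' @return list with `petco2`, `peto2`, `ve` (window means), `spo2`, `hr`
#'   (start values) and `n` (samples in the window).
#' @examples
#' study <- generateCohort(cohortConfig(nSubjects = 1, nSessions = 1, seed = 1))
#' alignAcquisition(physioTraces(study)[["S01_1"]], 560, 60)
#' @export
alignAcquisition <- function(trace, start, duration, averageSpo2Hr = FALSE) {
  stopifnot(duration > 0)
  tt <- trace@time
  if (start + duration <= tt[1] || start >= tt[length(tt)])
    stop(sprintf("window [%g, %g) lies outside the trace support [%g, %g]",
                 start, start + duration, tt[1], tt[length(tt)]))
  inWin <- tt >= start & tt < start + duration
  n <- sum(inWin)
  if (n < 2L)
    stop(sprintf("window [%g, %g) covers %d trace sample(s); need >= 2",
                 start, start + duration, n))
  nearest <- which.min(abs(tt - start))
  list(petco2 = mean(trace@petco2[inWin]),
       peto2 = mean(trace@peto2[inWin]),
       ve = mean(trace@minuteVentilation[inWin]),
       spo2 = if (averageSpo2Hr) mean(trace@spo2[inWin]) else trace@spo2[nearest],
       hr = if (averageSpo2Hr) mean(trace@heartRate[inWin]) else trace@heartRate[nearest],
       n = n)
}

#' Per-acquisition physiology for a whole study
#'
#' Runs [alignAcquisition()] for every row of the acquisition table against
#' that session's trace.
#'
#' @param study a [SyntheticStudy-class].
#' @param averageSpo2Hr see [alignAcquisition()].
#' @return data.frame keyed by `acq_id` with columns `petco2`, `peto2`, `ve`,
#'   `spo2`, `hr` alongside the acquisition identifiers.
#' @export
acquisitionPhysio <- function(study, averageSpo2Hr = FALSE) {
  acq <- study@acquisitions
  n <- nrow(acq)
  petco2 <- peto2 <- ve <- spo2 <- hr <- numeric(n)
  keys <- paste(acq$subject, acq$session, sep = "_")
  for (i in seq_len(n)) {
    trace <- study@traces[[keys[i]]]
    if (is.null(trace))
      stop("no physiological trace for session '", keys[i], "'")
    a <- alignAcquisition(trace, acq$start_s[i], acq$duration_s[i], averageSpo2Hr)
    petco2[i] <- a$petco2; peto2[i] <- a$peto2; ve[i] <- a$ve
    spo2[i] <- a$spo2; hr[i] <- a$hr
  }
  data.frame(acq_id = acq$acq_id, subject = acq$subject,
             session = acq$session, phase = acq$phase,
             placement = acq$placement,
             petco2 = petco2, peto2 = peto2, ve = ve, spo2 = spo2, hr = hr,
             stringsAsFactors = FALSE, row.names = NULL)
}

## Per-acquisition nCBF for steady-state placement-1 scans, with physio.
## Used by phase summaries and back-to-back repeatability.
.steadyP1Table <- function(study) {
  study <- quantifyStudy(study)
  acq <- study@acquisitions
  phys <- acquisitionPhysio(study)
  keep <- acq$phase %in% .PHASES & acq$placement == 1L
  acq <- acq[keep, , drop = FALSE]
  phys <- phys[keep, , drop = FALSE]
  massBy <- .massLookup(study)
  totalFlow <- rowSums(acq[, paste0("flow_", .VESSELS)])
  acq$ncbf <- totalFlow / massBy[acq$subject] * 100
  cbind(acq[, c("subject", "session", "acq_id", "phase", "placement",
                "start_s")],
        phys[, c("petco2", "peto2", "ve", "spo2", "hr")],
        ncbf = acq$ncbf)
}

.massLookup <- function(study) {
  anat <- study@anatomy
  m <- vapply(seq_len(nrow(anat)), function(i)
    brainMass(anat$gm_vol_mL[i], anat$wm_vol_mL[i])$mass, numeric(1))
  names(m) <- anat$subject
  m
}

#' Group summaries per protocol phase
#'
#' Session-level phase values (each the mean over that session's steady-state
#' placement-1 acquisitions) are pooled across all sessions into a mean and
#' SD per variable and phase, the layout of a group physiology table.
#' Baseline means come from the initial baseline; the recovery baseline is
#' reported as its own phase. Phases with no acquisitions are omitted with a
#' warning.
#'
#' @param study a [SyntheticStudy-class] (quantified on the fly if needed).
#' @return data.frame: phase, variable (petco2, peto2, ve, spo2, hr, ncbf),
#'   mean, sd, n (sessions contributing).
#' @export
summarizePhases <- function(study) {
  tab <- .steadyP1Table(study)
  vars <- c("petco2", "peto2", "ve", "spo2", "hr", "ncbf")
  out <- list()
  for (ph in .PHASES) {
    sub <- tab[tab$phase == ph, , drop = FALSE]
    if (!nrow(sub)) {
      warning("phase '", ph, "' has no steady-state acquisitions; omitted")
      next
    }
    bySession <- stats::aggregate(sub[vars],
                                  by = list(subject = sub$subject,
                                            session = sub$session), FUN = mean)
    for (v in vars)
      out[[paste(ph, v)]] <- data.frame(
        phase = ph, variable = v,
        mean = mean(bySession[[v]]), sd = stats::sd(bySession[[v]]),
        n = nrow(bySession), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
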