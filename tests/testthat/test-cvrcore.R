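test_that("the placement model fits the group relationship by least squares", {
  p1 <- c(50, 60, 70, 80)
  m <- fitPlacementModel(p1, 1.05 * p1, "L_VA")
  expect_equal(m$slope, 1.05)
  expect_equal(m$intercept, 0)
  expect_equal(m$residualSd, 0)

  set.seed(7)
  p1 <- runif(10, 40, 120)
  p2 <- 5 + 1.1 * p1 + rnorm(10, 0, 5)
  m2 <- fitPlacementModel(p1, p2)
  expect_lt(abs(m2$residualSd / 5 - 1), 0.5)   # small-n tolerance

  expect_error(fitPlacementModel(c(60, 60, 60), c(61, 62, 63)), "constant")
  expect_error(fitPlacementModel(c(1, 2), c(1, 2)), ">= 3")

  mf <- fitPlacementModel(p1, p1 + 3, forceSlope1 = TRUE)
  expect_equal(mf$slope, 1)
  expect_equal(mf$intercept, 3)
})

test_that("the substitution rule is one-sided at 1.96 residual SDs", {
  m <- structure(list(vessel = "L_VA", slope = 1.05, intercept = 0,
                      residualSd = 5, n = 10), class = "PlacementModel")
  ## deviation 90 - 63 = 27 > 1.96 * 5 = 9.8 -> substitute
  dec <- reconcileVertebralPlacements(m, 60, 90)
  expect_true(dec$substitute)
  expect_equal(dec$deviations, 27)
  expect_equal(dec$threshold, 9.8)
  ## exactly at the prediction, or below it: keep placement 1
  expect_false(reconcileVertebralPlacements(m, 60, 63)$substitute)
  expect_false(reconcileVertebralPlacements(m, 60, 20)$substitute)
  ## any single flagged timepoint suffices
  expect_true(reconcileVertebralPlacements(m, c(60, 60, 60),
                                           c(63, 64, 90))$substitute)
  ## degenerate zero-SD model needs the configurable floor
  m0 <- structure(list(vessel = "L_VA", slope = 1, intercept = 0,
                       residualSd = 0, n = 10), class = "PlacementModel")
  expect_error(reconcileVertebralPlacements(m0, 60, 61, sdFloor = 0), "sdFloor")
  expect_true(reconcileVertebralPlacements(m0, 60, 90, sdFloor = 1)$substitute)
})

test_that("steady-state CBF averages placement-1 scans and honours substitutions", {
  acq <- data.frame(
    phase = c("BL", "BL", "BL", "HX", "HX"),
    placement = c(1L, 1L, 2L, 1L, 2L),
    flow_L_ICA = c(300, 302, 290, 310, 300),
    flow_R_ICA = c(295, 293, 280, 300, 295),
    flow_L_VA = c(90, 92, 120, 95, 130),
    flow_R_VA = c(93, 95, 96, 97, 98),
    petco2 = 41, peto2 = 110, ve = 9, spo2 = 98, hr = 65)
  ## two baseline totals 778 and 782 -> 780
  out <- steadyStateCbf(acq, mass = 1000)
  expect_equal(out$cbf[out$phase == "BL"], mean(c(778, 782)))
  expect_equal(out$ncbf, out$cbf / 1000 * 100)

  sub <- steadyStateCbf(acq, mass = 1000, c(L_VA = TRUE, R_VA = FALSE))
  ## L_VA replaced by the placement-2 value in every phase; ICAs untouched
  expect_equal(sub$flow_L_VA, c(120, 130))
  expect_equal(sub$cbf[1], mean(c(300, 302)) + mean(c(295, 293)) + 120 + 94)
  expect_equal(sub$cbf - sub$flow_L_VA - sub$flow_R_VA,
               out$cbf - out$flow_L_VA - out$flow_R_VA)

  one <- steadyStateCbf(acq[4:5, ], mass = 1000)   # single placement-1 scan
  expect_equal(one$cbf, 310 + 300 + 95 + 97)
})

test_that("CVR equations follow their sign conventions and units", {
  ## group-mean arithmetic: +14 over 63 per +5 mmHg -> 4.444 %/mmHg
  expect_equal(cvrHypercapnic(63, 77, 41.0, 46.0), 100 * 14 / 63 / 5)
  expect_equal(cvrHypercapnic(63, 63, 41.0, 46.0), 0)
  expect_error(cvrHypercapnic(63, 77, 41.0, 41.0), "undefined")

  expect_equal(cvrHypoxicPeto2(63, 67, 112.3, 61.6), 0.1252, tolerance = 1e-3)
  expect_equal(cvrHypoxicPeto2(63, 60, 112.3, 61.6), -0.0939, tolerance = 1e-3)
  expect_equal(cvrHypoxicPeto2(63, 63, 112.3, 61.6), 0)
  expect_error(cvrHypoxicPeto2(63, 67, 112.3, 112.3), "undefined")

  expect_equal(cvrHypoxicSpo2(63, 67, 98, 90), 0.7937, tolerance = 1e-3)
  expect_equal(cvrHypoxicSpo2(63, 63, 98, 90), 0)
  expect_error(cvrHypoxicSpo2(63, 67, 98, 98), "undefined")

  ## property: CBF rise under falling PETO2 gives positive CVR, and the
  ## metric is antisymmetric in the CBF change
  set.seed(31)
  for (i in 1:25) {
    bl <- runif(1, 50, 80); d <- runif(1, 1, 10)
    o2bl <- runif(1, 100, 120); o2hx <- runif(1, 50, 70)
    expect_gt(cvrHypoxicPeto2(bl, bl + d, o2bl, o2hx), 0)
    expect_equal(cvrHypoxicPeto2(bl, bl + d, o2bl, o2hx),
                 -cvrHypoxicPeto2(bl, bl - d, o2bl, o2hx))
  }
})

test_that("the PETCO2 correction removes the estimated CO2 contribution", {
  expect_equal(correctForPetco2(3, 63, 4.33, -0.4), 3 + 63 * 0.0433 * 0.4)
  expect_equal(correctForPetco2(3, 63, 4.33, -0.4), 4.0912, tolerance = 1e-4)
  expect_equal(correctForPetco2(3, 63, 4.33, 0), 3)        # identity at 0
  expect_equal(correctForPetco2(3, 63, 4, 1), 0.48, tolerance = 1e-10)
})

test_that("the meaningful-change threshold and classification behave as defined", {
  expect_equal(meaningfulChangeThreshold(c(1, -2, 3)), 2)
  expect_equal(meaningfulChangeThreshold(rep(0, 5)), 0)
  expect_error(meaningfulChangeThreshold(numeric(0)), "no back-to-back")
  expect_equal(classifyResponse(c(3, -1.5, -2.5), 2),
               c("increase", "minimal", "decrease"))
  expect_true(is.na(classifyResponse(NA_real_, 2)))
  expect_error(classifyResponse(1, 0), "threshold")
})

test_that("the pipeline recovers true CVR exactly on noise-free cohorts", {
  study <- zeroNoiseStudy()
  res <- analyzeCvr(study)
  m <- merge(res$cvr, trueParams(study), by = c("subject", "session"))
  expect_lt(max(abs(m$cvr_hc - m$cvr_hc_true)), 1e-9)
  expect_lt(max(abs(m$cvr_hx_peto2_corr - m$cvr_hx_true)), 1e-9)
  expect_lt(max(abs(m$cvr_hx_spo2_corr - m$cvr_hx_spo2_implied)), 1e-9)
  expect_lt(max(abs(m$ncbf_bl - m$ncbf_base_true)), 1e-9)
})

test_that("strong placement attenuation is detected and neutralised", {
  cfg <- cohortConfig(nSubjects = 12, nSessions = 3, seed = 9,
                      ncbfNoiseSd = 0, traceNoiseScale = 0,
                      placementAffectFraction = 0.1,
                      placementAlphaRange = c(0.70, 0.75))
  study <- generateCohort(cfg)
  res <- analyzeCvr(study)
  m <- merge(res$cvr, trueParams(study), by = c("subject", "session"))
  affected <- m$va_alpha_L < 1 | m$va_alpha_R < 1
  flagged <- m$sub_L_VA | m$sub_R_VA
  expect_gt(sum(affected), 0)
  expect_true(all(flagged[affected]))
  expect_lt(max(abs(m$cvr_hc - m$cvr_hc_true)), 1e-9)

  ## substitution never touches carotid flows: ICA components of the
  ## session table equal the placement-1 steady means regardless of flags
  study <- quantifyStudy(study)
  acq <- acquisitions(study)
  for (i in which(res$substitutions$sub_L_VA | res$substitutions$sub_R_VA)) {
    srow <- res$substitutions[i, ]
    sel <- acq$subject == srow$subject & acq$session == srow$session &
           acq$phase == "BL" & acq$placement == 1L
    ses <- res$sessions[res$sessions$subject == srow$subject &
                        res$sessions$session == srow$session &
                        res$sessions$phase == "BL", ]
    icaP1 <- mean(acq$flow_L_ICA[sel]) + mean(acq$flow_R_ICA[sel])
    expect_equal(ses$cbf - ses$flow_L_VA - ses$flow_R_VA, icaP1)
  }
})

test_that("CVR estimation error at default noise is noise-limited", {
  ## error propagation of acquisition noise (SD 2.1, two scans per phase)
  ## through the hypercapnic CVR ratio predicts MAE ~0.5 %/mmHg
  cfg <- cohortConfig(nSubjects = 34, nSessions = 3, seed = 6,
                      placementAffectFraction = 0)
  study <- generateCohort(cfg)
  m <- merge(analyzeCvr(study)$cvr, trueParams(study),
             by = c("subject", "session"))
  expect_gte(nrow(m), 100)
  expect_lt(mean(abs(m$cvr_hc - m$cvr_hc_true)), 0.65)
})
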