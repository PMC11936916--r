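test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohortConfig(nSubjects = 0), "nSubjects")
  expect_error(cohortConfig(vesselSplit = c(L_ICA = 0.5, R_ICA = 0.5,
                                            L_VA = 0.1, R_VA = 0.1)),
               "vesselSplit")
  expect_error(cohortConfig(cvrHcSdSubject = -1), "cvrHcSdSubject")
  expect_error(cohortConfig(paradoxFraction = 1.5), "paradoxFraction")
  expect_error(cohortConfig(hxPeto2TargetRange = c(55, 200)),
               "hxPeto2TargetRange")
  expect_error(cohortConfig(noSuchField = 1), "noSuchField")
})

test_that("the same configuration and seed give byte-identical studies", {
  cfg <- cohortConfig(nSubjects = 2, nSessions = 2, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudy(generateCohort(cfg), d1)
  writeStudy(generateCohort(cfg), d2)
  f <- sort(list.files(d1))
  expect_identical(f, sort(list.files(d2)))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})

test_that("cohort dimensions follow the protocol schedule", {
  study <- defaultCohort()                 # 21 x 3, no dropouts
  tr <- trueParams(study)
  expect_equal(nrow(tr), 63)               # one truth row per session
  acq <- acquisitions(study)
  expect_equal(nrow(acq), 63 * 14)         # 14 scans per session
  bySession <- table(acq$phase[acq$subject == "S01" & acq$session == 1])
  expect_equal(as.integer(bySession[c("BL", "HX", "HC")]), c(3L, 3L, 3L))
  expect_equal(as.integer(bySession["RBL"]), 1L)
  expect_equal(as.integer(bySession["transition"]), 4L)
  ## steady phases: two scans at placement 1, one at placement 2
  for (ph in c("BL", "HX", "HC")) {
    sel <- acq$phase == ph
    expect_equal(sum(acq$placement[sel] == 1L), 2 * 63)
    expect_equal(sum(acq$placement[sel] == 2L), 63)
  }
})

test_that("generated baseline nCBF is centred on the configured mean", {
  study <- generateCohort(cohortConfig(nSubjects = 1000, nSessions = 1,
                                       seed = 17))
  expect_lt(abs(mean(trueParams(study)$ncbf_base_true) - 63), 0.5)
})

test_that("physiological traces respect their invariants", {
  study <- smallFlowStudy()
  for (trace in physioTraces(study)) {
    df <- as.data.frame(trace)
    expect_true(all(diff(df$time_s) > 0))
    expect_true(all(df$spo2_pct > 0 & df$spo2_pct <= 100))
    expect_setequal(unique(df$phase), c("BL", "transition", "HX", "RBL", "HC"))
  }
})

test_that("subject sampling honours the paradox mixture and zero-variance limits", {
  cfg0 <- cohortConfig(paradoxFraction = 0)
  set.seed(1)
  draws <- replicate(200, sampleSubjectParams(cfg0)$cvrHxSubject)
  expect_true(all(draws >= 0))

  cfgZ <- cohortConfig(cvrHcSdSubject = 0, cvrHcSdSession = 0,
                       cvrHxSdSubject = 0, cvrHxSdSession = 0,
                       paradoxFraction = 0)
  set.seed(2)
  sp <- sampleSubjectParams(cfgZ)
  expect_equal(sp$cvrHc, rep(4.33, 3))
  expect_equal(sp$cvrHx, rep(0.10, 3))

  cfgP <- cohortConfig(paradoxFraction = 1)
  set.seed(3)
  sp <- sampleSubjectParams(cfgP)
  expect_lt(sp$cvrHxSubject, 0)
  expect_identical(sp$responderClass, "paradoxical")
})

test_that("per-session CVR variance decomposes into the configured components", {
  ## total SD of per-session values adds subject and session variances
  cfg <- cohortConfig(nSessions = 3)
  set.seed(8)
  vals <- replicate(4000, sampleSubjectParams(cfg)$cvrHc)  # 3 x 4000
  totalSd <- sd(as.vector(vals))
  expect_lt(abs(totalSd / sqrt(1.13^2 + 1.37^2) - 1), 0.02)

  ## and the components themselves are recoverable at n >= 500 subjects
  set.seed(9)
  draws <- replicate(500, sampleSubjectParams(cfg)$cvrHc)
  vc <- varianceComponents(rep(seq_len(500), each = 3), as.vector(draws))
  expect_lt(abs(vc$sdSubject / 1.13 - 1), 0.05)
  expect_lt(abs(vc$sdSession / 1.37 - 1), 0.05)
})

test_that("dropout specifications omit the named phases", {
  ds <- data.frame(subject = "S01", session = 1L, phase = "HC")
  study <- generateCohort(cohortConfig(nSubjects = 2, nSessions = 2, seed = 6,
                                       dropoutSpec = ds))
  acq <- acquisitions(study)
  expect_equal(sum(acq$subject == "S01" & acq$session == 1 & acq$phase == "HC"), 0)
  expect_gt(sum(acq$subject == "S01" & acq$session == 2 & acq$phase == "HC"), 0)
  res <- analyzeCvr(study)
  row <- res$cvr[res$cvr$subject == "S01" & res$cvr$session == 1, ]
  expect_true(is.na(row$cvr_hc))
  expect_true(is.na(row$cvr_hx_peto2_corr))   # correction needs CVR(HC)
  expect_false(is.na(row$cvr_hx_peto2))
})

test_that("hypoxia carries the configured concomitant PETCO2 perturbation", {
  study <- generateCohort(cohortConfig(nSubjects = 60, nSessions = 3, seed = 14))
  res <- analyzeCvr(study)
  d <- res$cvr$delta_petco2_hx
  expect_lt(abs(mean(d) - (-0.4)), 0.2)    # SE ~ 0.9/sqrt(180) = 0.07
  expect_lt(abs(sd(d) / 0.9 - 1), 0.2)
})
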