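test_that("rendered discs reproduce the requested flows within discretisation error", {
  ## vertebral disc diameter is 20 px at the default geometry; carotid 28 px
  flows <- c(L_ICA = 320, R_ICA = 300, L_VA = 95, R_VA = 85)
  cine <- synthVelocityCine(flows, defaultCineGeometry(),
                            noiseSd = 0, offset = 0, waveform = rep(1, 8))
  got <- quantifyCine(cine, correctBackground = FALSE)
  expect_lt(max(abs(got / flows - 1)), 0.02)
})

test_that("pulsatility modulates bins but not the cycle mean", {
  w <- pulsatilityWaveform(1.6)
  expect_equal(mean(w), 1)
  expect_equal(max(w) / mean(w), 1.6)
  flows <- c(L_ICA = 300, R_ICA = 300, L_VA = 90, R_VA = 90)
  cine <- synthVelocityCine(flows, waveform = w)
  f <- vesselFlow(cine, "L_ICA")
  expect_gt(sd(f$flow), 0)                       # bins differ
  expect_lt(abs(f$cycleMeanFlow / 300 - 1), 0.02)
})

test_that("zero flow renders zero velocity inside every ROI", {
  flows <- c(L_ICA = 0, R_ICA = 0, L_VA = 0, R_VA = 0)
  cine <- synthVelocityCine(flows)
  for (b in c(1L, 5L))
    expect_true(all(velocities(cine)[, , b][vesselMask(cine, "L_ICA", b)] == 0))
  expect_equal(quantifyCine(cine, correctBackground = FALSE),
               c(L_ICA = 0, R_ICA = 0, L_VA = 0, R_VA = 0))
})

test_that("a background offset appears in static tissue and is removed by correction", {
  flows <- c(L_ICA = 300, R_ICA = 300, L_VA = 90, R_VA = 90)
  cine <- synthVelocityCine(flows, offset = 1)
  for (b in 1:8)
    expect_equal(mean(velocities(cine)[, , b][staticMask(cine, b)]), 1)
  corr <- correctBackgroundPhase(cine)
  for (b in 1:8)
    expect_lt(abs(mean(velocities(corr)[, , b][staticMask(corr, b)])), 1e-9)
  expect_lt(max(abs(quantifyCine(cine) / flows - 1)), 0.02)

  ## uncorrected flows are biased by offset * area * 60 per vessel
  raw <- quantifyCine(cine, correctBackground = FALSE)
  cor2 <- quantifyCine(cine)
  area <- vesselFlow(corr, "L_ICA")$area[1]
  expect_equal(raw[["L_ICA"]] - cor2[["L_ICA"]], 1 * area * 60,
               tolerance = 1e-3)
})

test_that("background correction is idempotent and supports a planar fit", {
  flows <- c(L_ICA = 250, R_ICA = 250, L_VA = 80, R_VA = 80)
  cine <- synthVelocityCine(flows, offset = 0.7)
  once <- correctBackgroundPhase(cine)
  twice <- correctBackgroundPhase(once)
  expect_equal(velocities(once), velocities(twice))

  g <- defaultCineGeometry()$grid
  ramp <- outer(seq_len(g), seq_len(g), function(i, j) 0.002 * i - 0.001 * j)
  tilted <- synthVelocityCine(flows, offset = ramp)
  planar <- quantifyCine(tilted, method = "planar")
  expect_lt(max(abs(planar / flows - 1)), 0.02)
})

test_that("geometry violations and missing masks are rejected", {
  geom <- defaultCineGeometry()
  geom$centers["R_ICA", ] <- geom$centers["L_ICA", ] + c(2, 0)  # overlap
  flows <- c(L_ICA = 300, R_ICA = 300, L_VA = 90, R_VA = 90)
  expect_error(synthVelocityCine(flows, geom), "overlap")

  geom2 <- defaultCineGeometry()
  geom2$centers["L_ICA", ] <- c(5, 5)                           # off-grid
  expect_error(synthVelocityCine(flows, geom2), "does not fit")
  expect_error(synthVelocityCine(c(L_ICA = -1, R_ICA = 1, L_VA = 1, R_VA = 1)),
               ">= 0")

  cine <- synthVelocityCine(flows)
  m <- maskArray(cine)
  m[, , 3][m[, , 3] == 1L] <- 0L                                # drop a bin ROI
  broken <- new("VelocityCine", velocity = velocities(cine), mask = m,
                pixelArea = pixelArea(cine))
  expect_error(vesselFlow(broken, "L_ICA"), "bin 3")
  m2 <- maskArray(cine)
  m2[m2 == 9L] <- 0L
  noStatic <- new("VelocityCine", velocity = velocities(cine), mask = m2,
                  pixelArea = pixelArea(cine))
  expect_error(correctBackgroundPhase(noStatic), "static")
})

test_that("image-fidelity cohorts quantify to the flow-fidelity numbers", {
  ## twin cohorts share every flow-level draw; only rendering differs
  args <- list(nSubjects = 2, nSessions = 1, seed = 13, ncbfNoiseSd = 0,
               traceNoiseScale = 0, placementAffectFraction = 0)
  flowStudy <- generateCohort(do.call(cohortConfig, args))
  imgStudy <- generateCohort(do.call(cohortConfig, c(args, fidelity = "image")))
  imgStudy <- quantifyStudy(imgStudy)
  cols <- paste0("flow_", c("L_ICA", "R_ICA", "L_VA", "R_VA"))
  rel <- abs(as.matrix(acquisitions(imgStudy)[cols]) /
             as.matrix(acquisitions(flowStudy)[cols]) - 1)
  expect_lt(max(rel), 0.02)
})
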