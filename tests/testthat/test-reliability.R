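test_that("the one-way ICC matches hand ANOVA and its bounds", {
  expect_equal(iccOneway(rbind(c(1, 1), c(2, 2), c(3, 3))), 1)
  expect_equal(iccOneway(rbind(c(1, 2), c(2, 1), c(3, 3))), 7 / 11)
  expect_equal(iccOneway(rbind(c(1, 2), c(2, 1), c(3, 3))), 0.6364,
               tolerance = 1e-4)
  ## average-measures form consistent with the variance components
  expect_equal(iccOneway(rbind(c(1, 2), c(2, 1), c(3, 3)), "average"),
               (1.5 - 1 / 3) / 1.5)

  set.seed(12)
  for (i in 1:20) {
    mat <- matrix(rnorm(5 * 3, sd = runif(1, 0.5, 3)), 5, 3) +
           rnorm(5, sd = runif(1, 0, 2))
    icc <- iccOneway(mat)
    expect_gt(icc, -1 / (ncol(mat) - 1))
    expect_lte(icc, 1)
    expect_equal(icc, iccOneway(mat[sample(5), ]))       # row permutation
    expect_equal(icc, aovIccSingle(mat))                 # independent path
  }

  ## rows with missing sessions are excluded before computing
  m <- rbind(c(1, 2), c(2, 1), c(3, 3), c(9, NA))
  expect_equal(iccOneway(m), 7 / 11)
  expect_error(iccOneway(rbind(c(1, NA), c(2, 2), c(3, NA))), "complete")
  expect_error(iccOneway(cbind(1:5)), "columns")

  set.seed(13)
  null <- matrix(rnorm(600), 200, 3)                     # no subject variance
  expect_lt(abs(iccOneway(null)), 0.15)
})

test_that("variance components come from the one-way method of moments", {
  vc <- varianceComponents(rep(1:3, each = 2), c(1, 2, 2, 1, 3, 3))
  expect_equal(vc$sdSubject, sqrt((1.5 - 1 / 3) / 2))
  expect_equal(vc$sdSubject, 0.7638, tolerance = 1e-4)
  expect_equal(vc$sdSession, sqrt(1 / 3))
  expect_false(vc$truncated)

  z <- varianceComponents(rep(1:3, each = 2), rep(5, 6))
  expect_equal(c(z$sdSubject, z$sdSession), c(0, 0))

  ## negative moment estimates truncate with a warning
  expect_warning(
    neg <- varianceComponents(rep(1:2, each = 2), c(1, 4, 2, 3)),
    "truncated")
  expect_equal(neg$sdSubject, 0)
  expect_true(neg$truncated)

  ## unbalanced data use the harmonic-adjusted group size
  subj <- c(1, 1, 1, 2, 2, 3)
  expect_equal(suppressWarnings(varianceComponents(subj, rnorm(6))$k0),
               (6 - 14 / 6) / 2)

  set.seed(14)
  vals <- rnorm(500, 4.33, 1.13)[rep(1:500, each = 3)] + rnorm(1500, 0, 1.37)
  est <- varianceComponents(rep(1:500, each = 3), vals)
  expect_lt(abs(est$sdSubject / 1.13 - 1), 0.05)
  expect_lt(abs(est$sdSession / 1.37 - 1), 0.05)

  expect_error(varianceComponents(1:4, rnorm(4)), "repeated")
})

test_that("the exact Wilcoxon branch equals exhaustive enumeration", {
  expect_equal(wilcoxonSignedRank(c(1, 2, 3))$p.value, 0.25)
  expect_equal(wilcoxonSignedRank(c(-1, 1))$p.value, 1)
  expect_error(wilcoxonSignedRank(c(0, 0)), "zero")

  set.seed(15)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE) +
         round(rnorm(n), 1)                    # ties in |d| occur regularly
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxonSignedRank(d)$p.value, bruteWilcoxonP(d))
  }

  ## agreement with the reference implementation when it is exact (no ties)
  set.seed(16)
  for (i in 1:20) {
    d <- rnorm(sample(4:15, 1))
    if (any(duplicated(abs(d)))) next
    expect_equal(wilcoxonSignedRank(d)$p.value,
                 wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("the normal approximation agrees with the exact branch at n = 25", {
  set.seed(17)
  for (i in 1:10) {
    d <- rnorm(25, mean = runif(1, -0.3, 0.3))
    pe <- wilcoxonSignedRank(d, exactMax = 25)$p.value
    pa <- wilcoxonSignedRank(d, exactMax = 10)$p.value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("phase comparisons run 18 paired tests at the Bonferroni threshold", {
  pc <- phaseComparisons(defaultCohort())
  expect_equal(nrow(pc), 18)
  expect_equal(attr(pc, "threshold"), 0.05 / 18)
  g <- function(v, cmp) pc$significant[pc$variable == v & pc$comparison == cmp]
  expect_true(g("peto2", "HX vs BL"))       # the hypoxic stimulus
  expect_false(g("peto2", "HC vs BL"))      # oxygen untouched by hypercapnia
  expect_true(g("petco2", "HC vs BL"))
  expect_true(g("ncbf", "HC vs BL"))
  expect_true(g("spo2", "HX vs BL"))
})

test_that("pearson correlation matches the t-transform and rejects degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, x)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_equal(pearsonR(c(1, 1, -1, -1), c(1, -1, 1, -1))$r, 0)
  set.seed(18)
  a <- rnorm(20); b <- a + rnorm(20)
  expect_equal(pearsonR(a, b)$p.value, cor.test(a, b)$p.value)
  expect_error(pearsonR(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearsonR(1:2, 2:1), ">= 3")
})

test_that("the random-intercept R2 collapses to OLS and matches lme4", {
  set.seed(19)
  x <- rnorm(60); subj <- rep(1:20, 3)
  yFlat <- 1 + 0.8 * x + rnorm(60)           # no subject effect
  ## with singleton subjects the subject variance is structurally zero and
  ## the model collapses exactly onto ordinary least squares
  f <- rSquaredMixed(x, yFlat, seq_along(x))
  expect_lt(abs(f$r2 - summary(lm(yFlat ~ x))$r.squared), 1e-6)

  expect_equal(rSquaredMixed(x, 2 * x, subj)$r2, 1)
  expect_error(rSquaredMixed(rep(1, 60), yFlat, subj), "variance")
  expect_error(rSquaredMixed(x[1:4], yFlat[1:4], c(1, 1, 2, 2)), "subjects")

  ## known-parameter simulation: beta 2, sigma_b 1, sigma_e 0.8
  set.seed(20)
  b <- rnorm(20, 0, 1)[subj]
  y <- 1 + 2 * x + b + rnorm(60, 0, 0.8)
  fit <- rSquaredMixed(x, y, subj)
  analytic <- 4 * var(x) / (4 * var(x) + 1 + 0.64)
  expect_lt(abs(fit$r2 - analytic), 0.05)

  skip_if_not_installed("lme4")
  lfit <- lme4::lmer(y ~ x + (1 | subj), REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$beta, unname(lme4::fixef(lfit)[2]), tolerance = 1e-4)
  expect_equal(fit$sigma2Subject, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2Residual, vc$vcov[2], tolerance = 1e-3)
})

test_that("the reliability report assembles ICCs, components and correlations", {
  study <- generateCohort(cohortConfig(nSubjects = 12, nSessions = 3, seed = 23))
  res <- analyzeCvr(study)
  rep <- reliabilityReport(res)
  expect_named(rep$icc, c("cvr_hx_peto2", "cvr_hx_spo2", "cvr_hc",
                          "cvr_hx_peto2_corr", "cvr_hx_spo2_corr"))
  for (e in rep$icc) {
    expect_true(is.finite(e$iccSingle))
    expect_gte(e$iccAverage, e$iccSingle)   # k > 1 average-measures is larger
  }
  expect_gt(rep$iccBackToBack, 0.5)          # immediate repeatability is high
  expect_true(is.finite(rep$petco2Correlation$uncorrected$r))
  expect_true(all(vapply(rep$r2Mixed, is.finite, logical(1))))
  expect_gt(rep$threshold, 0)
})
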