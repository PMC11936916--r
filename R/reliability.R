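#' One-way random-effects intraclass correlation
#'
#' ICC from one-way ANOVA mean squares on rows (subjects) with complete data
#' across columns (sessions). The single-measures form is
#' `(MSB - MSW) / (MSB + (k - 1) * MSW)`; the average-measures form,
#' appropriate when the compared value is itself the mean of the k sessions'
#' measurements, is `(MSB - MSW) / MSB`.
#'
#' @param mat numeric matrix, subjects x sessions; rows with any `NA` are
#'   dropped before computing (complete-data requirement).
#' @param type `"single"` or `"average"`.
#' @return the ICC (a scalar in `(-1/(k-1), 1]` for single measures).
#' @examples
#' iccOneway(rbind(c(1, 2), c(2, 1), c(3, 3)))        # 0.6364
#' iccOneway(rbind(c(1, 1), c(2, 2), c(3, 3)))        # 1
#' @export
iccOneway <- function(mat, type = c("single", "average")) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need >= 2 sessions (columns)")
  if (n < 2L) stop("need >= 2 subjects with complete data; got ", n)
  grand <- mean(mat)
  rowMeansV <- rowMeans(mat)
  msb <- k * sum((rowMeansV - grand)^2) / (n - 1)
  msw <- sum((mat - rowMeansV)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) return(NaN)
  if (type == "single") (msb - msw) / (msb + (k - 1) * msw)
  else (msb - msw) / msb
}

#' Inter-subject and inter-session variance components
#'
#' Method-of-moments estimates from the one-way ANOVA decomposition of a
#' long table of repeated measurements: `sigma2_subject = (MSB - MSW) / k0`
#' with `k0` the harmonic-adjusted group size for unbalanced data
#' (`(N - sum(n_i^2) / N) / (g - 1)`), and the inter-session (residual) SD
#' `sqrt(MSW)`. A negative subject-variance moment estimate is truncated to
#' zero and flagged.
#'
#' @param subject subject identifier per observation.
#' @param value measurement per observation.
#' @return list: `sdSubject`, `sdSession`, `grandMean`, `nSubjects`,
#'   `nObs`, `k0`, `truncated`.
#' @examples
#' vc <- varianceComponents(rep(1:3, each = 2), c(1, 2, 2, 1, 3, 3))
#' c(vc$sdSubject, vc$sdSession)    # 0.7638, 0.5774
#' @export
varianceComponents <- function(subject, value) {
  ok <- is.finite(value)
  subject <- subject[ok]; value <- value[ok]
  ni <- table(subject)
  if (length(ni) < 2L || !any(ni >= 2L))
    stop("need >= 2 subjects and repeated observations for at least one subject")
  g <- length(ni); N <- length(value)
  means <- tapply(value, subject, mean)
  grand <- mean(value)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((value - means[as.character(subject)])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  k0 <- (N - sum(ni^2) / N) / (g - 1)
  s2b <- (msb - msw) / k0
  truncated <- s2b < 0
  if (truncated) {
    warning("negative subject variance moment estimate truncated to zero")
    s2b <- 0
  }
  list(sdSubject = sqrt(s2b), sdSession = sqrt(msw), grandMean = grand,
       nSubjects = g, nObs = N, k0 = k0, truncated = truncated)
}

## Distribution of the positive-rank sum over all sign assignments, by
## counting: counts[w] = number of assignments with statistic w. Ranks are
## doubled so midranks from ties become integers.
.signedRankCounts <- function(ranks2) {
  maxW <- sum(ranks2)
  counts <- numeric(maxW + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(maxW + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided test that paired differences are symmetric about zero. Zero
#' differences are dropped; absolute values are midranked. For `n <= exactMax`
#' (default 25) the p-value is exact, from the full distribution of the
#' positive-rank sum over all 2^n sign assignments (valid under ties, unlike
#' the classical no-tie tables); above that, a normal approximation with tie
#' and continuity corrections is used.
#'
#' @param diffs paired differences.
#' @param exactMax largest n for the exact branch.
#' @return list: `statistic` (positive-rank sum V), `p.value`, `n` (nonzero
#'   differences used), `exact`.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3))$p.value    # 0.25
#' wilcoxonSignedRank(c(-1, 1))$p.value      # 1
#' @export
wilcoxonSignedRank <- function(diffs, exactMax = 25L) {
  diffs <- diffs[is.finite(diffs) & diffs != 0]
  n <- length(diffs)
  if (!n) stop("all paired differences are zero; the test is undefined")
  ranks <- rank(abs(diffs))
  v <- sum(ranks[diffs > 0])
  if (n <= exactMax) {
    ranks2 <- as.integer(round(2 * ranks))
    counts <- .signedRankCounts(ranks2)
    total <- 2^n
    w2 <- as.integer(round(2 * v))
    pLow <- sum(counts[seq_len(w2 + 1L)]) / total
    pHigh <- sum(counts[seq.int(w2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(pLow, pHigh))
    list(statistic = v, p.value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(ranks)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
    list(statistic = v, p.value = min(1, 2 * stats::pnorm(-abs(z))),
         n = n, exact = FALSE)
  }
}

#' Paired phase comparisons with Bonferroni control
#'
#' For each physiological variable (PETCO2, PETO2, minute ventilation, SpO2,
#' heart rate, nCBF) the two stimulus phases are compared against the initial
#' baseline, and hypercapnia additionally against the recovery baseline,
#' pairing by session: 6 variables x 3 comparisons = 18 tests, flagged at a
#' family-wise 0.05 Bonferroni threshold (0.05/18 = 0.00278). Tests are
#' exact Wilcoxon signed-rank ([wilcoxonSignedRank()]).
#'
#' @param study a [SyntheticStudy-class].
#' @return data.frame: variable, comparison, n, statistic, p, significant,
#'   with the threshold as attribute `"threshold"`.
#' @export
phaseComparisons <- function(study) {
  tab <- .steadyP1Table(study)
  vars <- c("petco2", "peto2", "ve", "spo2", "hr", "ncbf")
  bySession <- stats::aggregate(tab[vars],
                                by = list(subject = tab$subject,
                                          session = tab$session,
                                          phase = tab$phase), FUN = mean)
  comparisons <- list(c("HX", "BL"), c("HC", "BL"), c("HC", "RBL"))
  thr <- 0.05 / (length(vars) * length(comparisons))
  out <- list()
  for (v in vars) {
    for (cmp in comparisons) {
      a <- bySession[bySession$phase == cmp[1], c("subject", "session", v)]
      b <- bySession[bySession$phase == cmp[2], c("subject", "session", v)]
      m <- merge(a, b, by = c("subject", "session"), suffixes = c(".a", ".b"))
      if (!nrow(m))
        stop("no paired sessions for comparison ", cmp[1], " vs ", cmp[2])
      d <- m[[paste0(v, ".a")]] - m[[paste0(v, ".b")]]
      w <- wilcoxonSignedRank(d)
      out[[paste(v, cmp[1], cmp[2])]] <- data.frame(
        variable = v, comparison = paste(cmp[1], "vs", cmp[2]),
        n = nrow(m), statistic = w$statistic, p = w$p.value,
        significant = w$p.value < thr, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, `n >= 3`, each with positive variance.
#' @return list: `r`, `p.value`, `n`.
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; the correlation is undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Marginal coefficient of determination from a random-intercept model
#'
#' Fits `y = alpha + beta * x + b_subject + e` by maximum likelihood,
#' profiling the variance ratio `lambda = sigma2_b / sigma2_e` (closed-form
#' generalised least squares at each lambda, one-dimensional likelihood
#' maximisation over log lambda), and returns the proportion of total
#' variance explained by the fixed slope:
#' `beta^2 Var(x) / (beta^2 Var(x) + sigma2_b + sigma2_e)`.
#'
#' @param x,y observations; `subject` groups repeated measures.
#' @param subject subject identifier per observation.
#' @return list: `r2`, `beta`, `alpha`, `sigma2Subject`, `sigma2Residual`,
#'   `lambda`.
#' @export
rSquaredMixed <- function(x, y, subject) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; subject <- as.character(subject[ok])
  n <- length(x)
  if (length(unique(subject)) < 3L) stop("need >= 3 subjects")
  if (n < 6L) stop("need >= 6 observations")
  if (stats::sd(x) == 0) stop("predictor has zero variance")

  groups <- split(seq_len(n), subject)
  X <- cbind(1, x)

  profile <- function(logLambda) {
    lam <- exp(logLambda)
    xtx <- matrix(0, 2, 2); xty <- numeric(2)
    ## accumulate X' V^-1 X and X' V^-1 y blockwise;
    ## V_i^-1 = I - lam/(1 + n_i lam) J
    for (idx in groups) {
      ni <- length(idx)
      w <- lam / (1 + ni * lam)
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      cx <- colSums(Xi); cy <- sum(yi)
      xtx <- xtx + crossprod(Xi) - w * tcrossprod(cx)
      xty <- xty + crossprod(Xi, yi) - w * cx * cy
    }
    beta <- solve(xtx, xty)
    rss <- 0; logdet <- 0
    for (idx in groups) {
      ni <- length(idx)
      w <- lam / (1 + ni * lam)
      ri <- y[idx] - X[idx, , drop = FALSE] %*% beta
      rss <- rss + sum(ri^2) - w * sum(ri)^2
      logdet <- logdet + log1p(ni * lam)
    }
    sigma2 <- rss / n
    ## guard the perfect-fit case (rss = 0) against log(0)
    ll <- -0.5 * (n * log(2 * pi * max(sigma2, 1e-300)) + logdet + n)
    list(ll = ll, beta = beta, sigma2 = sigma2, lambda = lam)
  }

  opt <- stats::optimize(function(l) profile(l)$ll,
                         lower = log(1e-8), upper = log(1e6), maximum = TRUE)
  fit <- profile(opt$maximum)
  ## boundary: a lambda at the lower search bound means no subject variance
  lam <- if (opt$maximum <= log(1e-8) + 1e-6) 0 else fit$lambda
  sigma2e <- fit$sigma2
  sigma2b <- lam * sigma2e
  beta <- fit$beta[2]
  ## population variance: keeps the sigma2_b = 0 case identical to OLS R^2
  varFixed <- beta^2 * mean((x - mean(x))^2)
  list(r2 = varFixed / (varFixed + sigma2b + sigma2e),
       beta = beta, alpha = fit$beta[1],
       sigma2Subject = sigma2b, sigma2Residual = sigma2e, lambda = lam)
}

#' Reliability and group statistics for a CVR analysis
#'
#' Builds subject x session matrices for each CVR metric and reports one-way
#' ICCs (single- and average-measures, overall and per session pair),
#' variance components, the immediate-repeatability ICC of back-to-back
#' baseline measurements, steady-state verification Wilcoxon tests (stimulus
#' back-to-back differences against baseline's), the correlation between
#' concomitant PETCO2 changes and hypoxic CBF changes before and after
#' correction, and random-intercept coefficients of determination between
#' hypercapnic and hypoxic CVR.
#'
#' @param analysis a `CVRAnalysis` from [analyzeCvr()].
#' @return a `ReliabilityReport` list; see element names.
#' @export
reliabilityReport <- function(analysis) {
  cvr <- analysis$cvr
  metrics <- c("cvr_hx_peto2", "cvr_hx_spo2", "cvr_hc",
               "cvr_hx_peto2_corr", "cvr_hx_spo2_corr")
  sessionsAll <- sort(unique(cvr$session))
  asMatrix <- function(metric) {
    m <- stats::reshape(cvr[, c("subject", "session", metric)],
                        direction = "wide", idvar = "subject",
                        timevar = "session")
    rn <- m$subject
    m <- as.matrix(m[, -1, drop = FALSE])
    rownames(m) <- rn
    m
  }
  iccTab <- list(); vcTab <- list()
  for (metric in metrics) {
    m <- asMatrix(metric)
    entry <- list(metric = metric)
    entry$iccSingle <- tryCatch(iccOneway(m, "single"), error = function(e) NA_real_)
    entry$iccAverage <- tryCatch(iccOneway(m, "average"), error = function(e) NA_real_)
    if (length(sessionsAll) > 2L) {
      for (j in 2:length(sessionsAll)) {
        pairMat <- m[, c(1, j), drop = FALSE]
        entry[[sprintf("iccSingle_s1_s%d", sessionsAll[j])]] <-
          tryCatch(iccOneway(pairMat, "single"), error = function(e) NA_real_)
      }
    }
    iccTab[[metric]] <- entry
    ok <- is.finite(cvr[[metric]])
    vcTab[[metric]] <- tryCatch(
      varianceComponents(cvr$subject[ok], cvr[[metric]][ok]),
      error = function(e) NULL)
  }

  b2b <- analysis$backToBack
  ## immediate repeatability: the two back-to-back baseline scans act as two
  ## "raters" of the same session's CBF
  blPairs <- b2b[b2b$phase == "BL", , drop = FALSE]
  iccBackToBack <- if (nrow(blPairs) >= 2L)
    tryCatch(iccOneway(cbind(blPairs$first, blPairs$second), "single"),
             error = function(e) NA_real_) else NA_real_
  steadyVerify <- list()
  for (ph in c("HX", "HC")) {
    dStim <- b2b$diff[b2b$phase == ph]
    dBl <- b2b$diff[b2b$phase == "BL"]
    nPair <- min(length(dStim), length(dBl))
    if (nPair >= 1L) {
      w <- tryCatch(wilcoxonSignedRank(abs(dStim[seq_len(nPair)]) -
                                       abs(dBl[seq_len(nPair)])),
                    error = function(e) NULL)
      if (!is.null(w))
        steadyVerify[[ph]] <- list(phase = ph, p.value = w$p.value, n = w$n)
    }
  }

  corUncorr <- tryCatch(
    pearsonR(cvr$delta_petco2_hx, cvr$delta_ncbf_hx),
    error = function(e) NULL)
  corCorr <- tryCatch(
    pearsonR(cvr$delta_petco2_hx, cvr$delta_ncbf_hx_corr),
    error = function(e) NULL)

  r2 <- list()
  for (metric in c("cvr_hx_peto2", "cvr_hx_spo2",
                   "cvr_hx_peto2_corr", "cvr_hx_spo2_corr")) {
    r2[[metric]] <- tryCatch(
      rSquaredMixed(cvr$cvr_hc, cvr[[metric]], cvr$subject)$r2,
      error = function(e) NA_real_)
  }

  counts <- list(
    decreaseHxBySession = tapply(cvr$response_hx == "decrease",
                                 cvr$session, sum, na.rm = TRUE),
    minimalHxTotal = sum(cvr$response_hx == "minimal", na.rm = TRUE),
    minimalHcTotal = sum(cvr$response_hc == "minimal", na.rm = TRUE))

  structure(list(icc = iccTab, varianceComponents = vcTab,
                 iccBackToBack = iccBackToBack,
                 threshold = analysis$threshold,
                 steadyStateVerification = steadyVerify,
                 petco2Correlation = list(uncorrected = corUncorr,
                                          corrected = corCorr),
                 r2Mixed = r2, responseCounts = counts),
            class = "ReliabilityReport")
}

#' @export
print.ReliabilityReport <- function(x, ...) {
  cat("ReliabilityReport\n")
  for (metric in names(x$icc)) {
    e <- x$icc[[metric]]
    cat(sprintf("  %-18s ICC(1) %.3f  ICC(1,k) %.3f\n", metric,
                e$iccSingle, e$iccAverage))
  }
  if (!is.null(x$petco2Correlation$uncorrected))
    cat(sprintf("  PETCO2-coupling r: %.3f uncorrected -> %.3f corrected\n",
                x$petco2Correlation$uncorrected$r,
                if (is.null(x$petco2Correlation$corrected)) NA_real_
                else x$petco2Correlation$corrected$r))
  cat(sprintf("  meaningful-change threshold %.2f mL/100 g/min\n", x$threshold))
  invisible(x)
}
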