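## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

smallFlowStudy <- function() fixture("smallFlow", function()
  generateCohort(cohortConfig(nSubjects = 4, nSessions = 2, seed = 11)))

defaultCohort <- function() fixture("defaultCohort", function()
  generateCohort(cohortConfig(seed = 4)))   # 21 subjects x 3 sessions

zeroNoiseStudy <- function() fixture("zeroNoise", function()
  generateCohort(zeroNoiseConfig(cohortConfig(nSubjects = 6, nSessions = 2,
                                              seed = 5))))

## Exhaustive signed-rank two-sided p over all 2^n sign patterns.
bruteWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- signs %*% r
  pLow <- mean(ws <= v + 1e-9)
  pHigh <- mean(ws >= v - 1e-9)
  min(1, 2 * min(pLow, pHigh))
}

## One-way ANOVA mean squares through stats::aov, as an independent ICC path.
aovIccSingle <- function(mat) {
  df <- data.frame(value = as.vector(mat),
                   subject = factor(rep(seq_len(nrow(mat)), ncol(mat))))
  ms <- summary(stats::aov(value ~ subject, data = df))[[1]][["Mean Sq"]]
  k <- ncol(mat)
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

## Render-and-quantify helper used by several cine tests.
uniformCine <- function(velocity, roiPixels, pixelArea) {
  g <- 32L
  interior <- which(matrix(TRUE, g, g) &
                    row(matrix(0, g, g)) > 1 & row(matrix(0, g, g)) < g)
  roi <- interior[seq_len(roiPixels)]
  vel <- array(0, dim = c(g, g, 8))
  mask <- array(0L, dim = c(g, g, 8))
  for (b in 1:8) {
    plane <- matrix(0, g, g)
    plane[roi] <- velocity
    m <- matrix(0L, g, g)
    m[g, ] <- 9L                      # static border
    m[roi] <- 1L                      # L_ICA code
    vel[, , b] <- plane
    mask[, , b] <- m
  }
  new("VelocityCine", velocity = vel, mask = mask, pixelArea = pixelArea)
}
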