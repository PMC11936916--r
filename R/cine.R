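#' Unit-mean pulsatility waveform over the cardiac cycle
#'
#' Raised cosine across the 8 cardiac bins with peak/mean ratio
#' `peakToMean`; only the cycle mean matters for cycle-averaged flow, so the
#' shape is a fixed modelling convention.
#'
#' @param peakToMean peak flow relative to cycle-mean flow (default 1.6).
#' @return numeric vector of length 8 with mean exactly 1.
#' @export
pulsatilityWaveform <- function(peakToMean = 1.6) {
  stopifnot(peakToMean >= 1)
  1 + (peakToMean - 1) * cos(2 * pi * (seq_len(.N_BINS) - 1) / .N_BINS)
}

#' Default vessel geometry for rendered cines
#'
#' Four circular vessel cross-sections on a square grid: internal carotids of
#' radius 0.28 cm and vertebrals of 0.20 cm (28- and 20-pixel diameters at
#' the default 0.02 cm pixel), one per quadrant, with a border ring of static
#' tissue used for background phase correction.
#'
#' @param config optional [CohortConfig-class] supplying grid size and pixel
#'   spacing.
#' @return list with `grid` (pixels per side), `pixelCm`, named `radiiCm`,
#'   `centers` (4 x 2 pixel coordinates, rows in canonical vessel order) and
#'   `staticBorder` (ring width in pixels).
#' @export
defaultCineGeometry <- function(config = NULL) {
  grid <- if (is.null(config)) 160L else config@cineGrid
  pixelCm <- if (is.null(config)) 0.02 else config@cinePixelCm
  q <- grid / 4
  list(grid = as.integer(grid), pixelCm = pixelCm,
       radiiCm = c(L_ICA = 0.28, R_ICA = 0.28, L_VA = 0.20, R_VA = 0.20),
       centers = matrix(c(q, q, 3 * q, q, q, 3 * q, 3 * q, 3 * q),
                        ncol = 2, byrow = TRUE,
                        dimnames = list(.VESSELS, c("x", "y"))),
       staticBorder = 8L)
}

#' Render a cine velocity map with known per-vessel flows
#'
#' Each vessel is drawn as a disc with a parabolic through-plane velocity
#' profile whose analytic integral over the disc equals the requested
#' per-bin flow (cycle-mean flow modulated by a unit-mean pulsatility
#' waveform). A background phase offset is added everywhere, and optional
#' white voxel noise on top. Static tissue occupies a border ring and carries
#' only offset and noise, so the offset is recoverable from it.
#'
#' @param flows named numeric, mL/min cycle-mean flow per vessel
#'   (`L_ICA`, `R_ICA`, `L_VA`, `R_VA`); all `>= 0`.
#' @param geometry as from [defaultCineGeometry()].
#' @param noiseSd voxel noise SD, cm/s.
#' @param offset background phase offset, cm/s: a scalar (constant field) or
#'   a `grid x grid` matrix (spatially varying field).
#' @param waveform per-bin flow modulation, unit mean, length 8.
#' @return a [VelocityCine-class].
#' @examples
#' cine <- synthVelocityCine(c(L_ICA = 300, R_ICA = 300, L_VA = 90, R_VA = 89),
#'                           defaultCineGeometry())
#' cine
#' @export
synthVelocityCine <- function(flows, geometry = defaultCineGeometry(),
                              noiseSd = 0, offset = 0,
                              waveform = pulsatilityWaveform()) {
  if (!all(.VESSELS %in% names(flows)))
    stop("'flows' must be named with all of: ", paste(.VESSELS, collapse = ", "))
  flows <- flows[.VESSELS]
  if (any(flows < 0)) stop("vessel flows must be >= 0")
  stopifnot(length(waveform) == .N_BINS)
  if (abs(mean(waveform) - 1) > 1e-9) stop("'waveform' must have unit mean")

  g <- geometry$grid
  px <- geometry$pixelCm
  radiiPx <- geometry$radiiCm / px
  ctr <- geometry$centers

  ## Discs must fit inside the static-free interior without touching.
  inner <- geometry$staticBorder + 1
  for (v in .VESSELS) {
    if (ctr[v, "x"] - radiiPx[[v]] < inner || ctr[v, "x"] + radiiPx[[v]] > g - inner ||
        ctr[v, "y"] - radiiPx[[v]] < inner || ctr[v, "y"] + radiiPx[[v]] > g - inner)
      stop("vessel disc '", v, "' does not fit inside the grid interior")
  }
  pairs <- utils::combn(.VESSELS, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- sqrt(sum((ctr[a, ] - ctr[b, ])^2))
    if (d <= radiiPx[[a]] + radiiPx[[b]])
      stop("vessel discs '", a, "' and '", b, "' overlap")
  }

  xs <- matrix(rep(seq_len(g), g), nrow = g)
  ys <- t(xs)
  mask2d <- matrix(0L, g, g)
  border <- xs <= geometry$staticBorder | xs > g - geometry$staticBorder |
            ys <= geometry$staticBorder | ys > g - geometry$staticBorder
  mask2d[border] <- .STATIC_CODE

  r2 <- vector("list", length(.VESSELS))
  names(r2) <- .VESSELS
  for (v in .VESSELS) {
    r2[[v]] <- (xs - ctr[v, "x"])^2 + (ys - ctr[v, "y"])^2
    inside <- r2[[v]] < radiiPx[[v]]^2
    mask2d[inside] <- .MASK_CODES[[v]]
  }

  vel <- array(0, dim = c(g, g, .N_BINS))
  mask <- array(0L, dim = c(g, g, .N_BINS))
  for (b in seq_len(.N_BINS)) {
    plane <- matrix(0, g, g)
    for (v in .VESSELS) {
      Rcm <- geometry$radiiCm[[v]]
      ## flow cm^3/s in this bin; parabolic profile integrates to
      ## vmax * pi R^2 / 2 over the disc.
      qBin <- flows[[v]] / 60 * waveform[b]
      vmax <- 2 * qBin / (pi * Rcm^2)
      inside <- r2[[v]] < radiiPx[[v]]^2
      plane[inside] <- vmax * (1 - r2[[v]][inside] / radiiPx[[v]]^2)
    }
    plane <- plane + offset
    if (noiseSd > 0) plane <- plane + stats::rnorm(g * g, 0, noiseSd)
    vel[, , b] <- plane
    mask[, , b] <- mask2d
  }
  methods::new("VelocityCine", velocity = vel, mask = mask, pixelArea = px^2)
}
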