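#' Remove background phase offsets using static tissue
#'
#' Velocity-encoded images carry a spatially slowly-varying velocity offset
#' from hardware imperfections. The default correction subtracts, per cardiac
#' bin, the mean velocity over the static-tissue mask from every voxel, after
#' which the static-mask mean is zero to machine precision. A planar fit
#' (least-squares plane over static voxels, evaluated and subtracted
#' everywhere) is available for spatially varying offsets. The operation is
#' idempotent.
#'
#' @param cine a [VelocityCine-class].
#' @param method `"constant"` (default) or `"planar"`.
#' @return the corrected [VelocityCine-class].
#' @export
correctBackgroundPhase <- function(cine, method = c("constant", "planar")) {
  method <- match.arg(method)
  vel <- cine@velocity
  g <- dim(vel)[1:2]
  for (b in seq_len(.N_BINS)) {
    stat <- cine@mask[, , b] == .STATIC_CODE
    if (!any(stat))
      stop("static-tissue mask is empty in cardiac bin ", b,
           "; background phase cannot be estimated")
    if (method == "constant") {
      vel[, , b] <- vel[, , b] - mean(vel[, , b][stat])
    } else {
      xs <- matrix(rep(seq_len(g[1]), g[2]), nrow = g[1])
      ys <- t(matrix(rep(seq_len(g[2]), g[1]), nrow = g[2]))
      fit <- stats::lm.fit(cbind(1, xs[stat], ys[stat]), vel[, , b][stat])
      plane <- fit$coefficients[1] + fit$coefficients[2] * xs +
               fit$coefficients[3] * ys
      vel[, , b] <- vel[, , b] - plane
    }
  }
  methods::initialize(cine, velocity = vel)
}

#' Quantify one vessel's flow from a cine
#'
#' Per cardiac bin, mean flow is the product of the mean velocity over the
#' vessel ROI and the ROI cross-sectional area (mask pixel count times pixel
#' area), converted to mL/min; the vessel's flow is the unweighted mean over
#' the 8 bins (retrospective gating yields equal-duration bins).
#'
#' @param cine a [VelocityCine-class] (background-corrected if appropriate).
#' @param vessel one of `"L_ICA"`, `"R_ICA"`, `"L_VA"`, `"R_VA"`.
#' @return a `VesselFlowMeasure`: list with `vessel`, per-bin `meanVelocity`
#'   (cm/s), `area` (cm^2) and `flow` (mL/min), and `cycleMeanFlow` (mL/min).
#' @examples
#' cine <- synthVelocityCine(c(L_ICA = 240, R_ICA = 240, L_VA = 80, R_VA = 80),
#'                           defaultCineGeometry())
#' vesselFlow(cine, "L_ICA")$cycleMeanFlow
#' @export
vesselFlow <- function(cine, vessel) {
  vessel <- match.arg(vessel, .VESSELS)
  code <- .MASK_CODES[[vessel]]
  mv <- area <- flow <- numeric(.N_BINS)
  for (b in seq_len(.N_BINS)) {
    roi <- cine@mask[, , b] == code
    if (!any(roi))
      stop("ROI mask for vessel '", vessel, "' is missing in cardiac bin ", b)
    mv[b] <- mean(cine@velocity[, , b][roi])
    area[b] <- sum(roi) * cine@pixelArea
    flow[b] <- mv[b] * area[b] * 60      # cm/s * cm^2 * 60 s/min = mL/min
  }
  structure(list(vessel = vessel, meanVelocity = mv, area = area,
                 flow = flow, cycleMeanFlow = mean(flow)),
            class = "VesselFlowMeasure")
}

#' @export
print.VesselFlowMeasure <- function(x, ...) {
  cat(sprintf("VesselFlowMeasure [%s]: cycle-mean flow %.1f mL/min (area %.3f cm^2)\n",
              x$vessel, x$cycleMeanFlow, mean(x$area)))
  invisible(x)
}

#' Total cerebral blood flow from the four neck vessels
#'
#' @param flows list of exactly four `VesselFlowMeasure` objects, one per
#'   vessel (any order; duplicates or omissions are errors).
#' @return total CBF, mL/min (sum of cycle-mean flows).
#' @export
totalCbf <- function(flows) {
  vessels <- vapply(flows, function(f) f$vessel, character(1))
  if (length(vessels) != 4L || !setequal(vessels, .VESSELS) ||
      anyDuplicated(vessels))
    stop("need exactly the four vessels ", paste(.VESSELS, collapse = ", "),
         "; got: ", paste(vessels, collapse = ", "))
  sum(vapply(flows, function(f) f$cycleMeanFlow, numeric(1)))
}

#' Brain mass from segmented tissue volumes
#'
#' Mass is (grey + white volume) times the brain tissue density of
#' 1.06 g/mL.
#'
#' @param gm,wm grey- and white-matter volumes, mL; both `>= 0`.
#' @return a `BrainMass`: list with `gm`, `wm`, `totalVolume` (mL), `mass`
#'   (g) and `density` (g/mL).
#' @examples
#' brainMass(600, 400)$mass   # 1060 g
#' @export
brainMass <- function(gm, wm) {
  if (gm < 0 || wm < 0) stop("tissue volumes must be >= 0")
  structure(list(gm = gm, wm = wm, totalVolume = gm + wm,
                 mass = (gm + wm) * .TISSUE_DENSITY,
                 density = .TISSUE_DENSITY),
            class = "BrainMass")
}

#' @export
print.BrainMass <- function(x, ...) {
  cat(sprintf("BrainMass: %.1f mL (GM %.1f + WM %.1f) x %.2f g/mL = %.1f g\n",
              x$totalVolume, x$gm, x$wm, x$density, x$mass))
  invisible(x)
}

#' Normalise total CBF by brain mass
#'
#' @param cbf total CBF, mL/min.
#' @param mass brain mass in g, or a `BrainMass`.
#' @return normalised CBF, mL/100 g/min.
#' @examples
#' normalizeCbf(779, 1236)    # ~63 mL/100 g/min
#' @export
normalizeCbf <- function(cbf, mass) {
  if (inherits(mass, "BrainMass")) mass <- mass$mass
  if (!is.numeric(mass) || mass <= 0) stop("brain mass must be > 0")
  cbf / mass * 100
}

#' Quantify all four vessels of a cine
#'
#' Convenience wrapper: optional background correction, then
#' [vesselFlow()] per vessel.
#'
#' @param cine a [VelocityCine-class].
#' @param correctBackground subtract the static-tissue phase offset first.
#' @param method correction model, see [correctBackgroundPhase()].
#' @return named numeric of cycle-mean flows (mL/min) in canonical vessel
#'   order.
#' @export
quantifyCine <- function(cine, correctBackground = TRUE,
                         method = c("constant", "planar")) {
  if (correctBackground) cine <- correctBackgroundPhase(cine, match.arg(method))
  vapply(.VESSELS, function(v) vesselFlow(cine, v)$cycleMeanFlow, numeric(1))
}

#' Fill per-vessel flows of an image-fidelity study
#'
#' Flow-fidelity studies pass through unchanged. For image-fidelity studies
#' every referenced cine is background-corrected and quantified, and the flow
#' columns of the acquisition table are populated.
#'
#' @param study a [SyntheticStudy-class].
#' @param method background correction model.
#' @return the study with flow columns filled.
#' @export
quantifyStudy <- function(study, method = c("constant", "planar")) {
  method <- match.arg(method)
  acq <- study@acquisitions
  todo <- which(!is.na(acq$cine_id))
  for (i in todo) {
    id <- acq$cine_id[i]
    cine <- study@cines[[id]]
    if (is.null(cine))
      stop("cine '", id, "' referenced by acquisition '", acq$acq_id[i],
           "' is missing from the study")
    acq[i, paste0("flow_", .VESSELS)] <-
      as.list(quantifyCine(cine, correctBackground = TRUE, method = method))
  }
  if (anyNA(acq$flow_L_ICA))
    stop("acquisitions without flows or cines present: ",
         paste(acq$acq_id[is.na(acq$flow_L_ICA)], collapse = ", "))
  methods::initialize(study, acquisitions = acq)
}
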