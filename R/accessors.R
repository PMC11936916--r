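#' @title Accessors for cvrflow S4 objects
#' @description Accessor generics and methods for [CohortConfig-class],
#'   [PhysioTrace-class], [VelocityCine-class] and [SyntheticStudy-class].
#'   Slots should be reached through these rather than `@`.
#' @param object,x an object of the documented class.
#' @param vessel one of `"L_ICA"`, `"R_ICA"`, `"L_VA"`, `"R_VA"`.
#' @param bin cardiac bin index, 1-8.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("nSessions", function(object) standardGeneric("nSessions"))
#' @rdname accessors
#' @export
setGeneric("cohortConfigOf", function(object) standardGeneric("cohortConfigOf"))
#' @rdname accessors
#' @export
setGeneric("physioTraces", function(object) standardGeneric("physioTraces"))
#' @rdname accessors
#' @export
setGeneric("acquisitions", function(object) standardGeneric("acquisitions"))
#' @rdname accessors
#' @export
setGeneric("anatomy", function(object) standardGeneric("anatomy"))
#' @rdname accessors
#' @export
setGeneric("trueParams", function(object) standardGeneric("trueParams"))
#' @rdname accessors
#' @export
setGeneric("cines", function(object) standardGeneric("cines"))
#' @rdname accessors
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("pixelArea", function(object) standardGeneric("pixelArea"))
#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object, vessel, bin) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setGeneric("staticMask", function(object, bin) standardGeneric("staticMask"))

#' @rdname accessors
#' @export
setMethod("nSubjects", "CohortConfig", function(object) object@nSubjects)
#' @rdname accessors
#' @export
setMethod("nSessions", "CohortConfig", function(object) object@nSessions)
#' @rdname accessors
#' @export
setMethod("nSubjects", "SyntheticStudy", function(object) object@config@nSubjects)
#' @rdname accessors
#' @export
setMethod("nSessions", "SyntheticStudy", function(object) object@config@nSessions)
#' @rdname accessors
#' @export
setMethod("cohortConfigOf", "SyntheticStudy", function(object) object@config)
#' @rdname accessors
#' @export
setMethod("physioTraces", "SyntheticStudy", function(object) object@traces)
#' @rdname accessors
#' @export
setMethod("acquisitions", "SyntheticStudy", function(object) object@acquisitions)
#' @rdname accessors
#' @export
setMethod("anatomy", "SyntheticStudy", function(object) object@anatomy)
#' @rdname accessors
#' @export
setMethod("trueParams", "SyntheticStudy", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("cines", "SyntheticStudy", function(object) object@cines)

#' @rdname accessors
#' @export
setMethod("velocities", "VelocityCine", function(object) object@velocity)
#' @rdname accessors
#' @export
setMethod("maskArray", "VelocityCine", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("pixelArea", "VelocityCine", function(object) object@pixelArea)

#' @rdname accessors
#' @export
setMethod("vesselMask", "VelocityCine", function(object, vessel, bin) {
  vessel <- match.arg(vessel, .VESSELS)
  stopifnot(bin >= 1L, bin <= .N_BINS)
  object@mask[, , bin] == .MASK_CODES[[vessel]]
})

#' @rdname accessors
#' @export
setMethod("staticMask", "VelocityCine", function(object, bin) {
  stopifnot(bin >= 1L, bin <= .N_BINS)
  object@mask[, , bin] == .STATIC_CODE
})

#' Convert a PhysioTrace to a data.frame
#'
#' @param x a [PhysioTrace-class].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return data.frame with columns time_s, petco2_mmHg, peto2_mmHg, spo2_pct,
#'   hr_bpm, ve_L_min, phase (the on-disk CSV layout).
#' @export
as.data.frame.PhysioTrace <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_s = x@time, petco2_mmHg = x@petco2, peto2_mmHg = x@peto2,
             spo2_pct = x@spo2, hr_bpm = x@heartRate,
             ve_L_min = x@minuteVentilation, phase = x@phase,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d subjects x %d sessions, fidelity '%s', seed %d\n",
              object@nSubjects, object@nSessions, object@fidelity, object@seed))
  cat(sprintf("  baseline nCBF %.1f +/- %.1f mL/100g/min; PETCO2 %.1f; PETO2 %.1f; SpO2 %.0f%%\n",
              object@baselineNcbfMean, object@baselineNcbfSd,
              object@baselinePetco2Mean, object@baselinePeto2Mean,
              object@baselineSpo2Mean))
  cat(sprintf("  CVR(HC) %.2f (subj SD %.2f, sess SD %.2f) %%/mmHg; CVR(HX) %.2f (%.2f, %.2f) %%/-mmHg\n",
              object@cvrHcMean, object@cvrHcSdSubject, object@cvrHcSdSession,
              object@cvrHxMean, object@cvrHxSdSubject, object@cvrHxSdSession))
  cat(sprintf("  paradoxical fraction %.2f; acquisition noise SD %.2f mL/100g/min\n",
              object@paradoxFraction, object@ncbfNoiseSd))
})

#' @rdname accessors
#' @export
setMethod("show", "PhysioTrace", function(object) {
  n <- length(object@time)
  cat(sprintf("PhysioTrace: %d samples, %.0f-%.0f s, phases: %s\n",
              n, min(object@time), max(object@time),
              paste(unique(object@phase), collapse = " ")))
})

#' @rdname accessors
#' @export
setMethod("show", "VelocityCine", function(object) {
  d <- dim(object@velocity)
  cat(sprintf("VelocityCine: %d x %d pixels, %d cardiac bins, pixel area %.4g cm^2\n",
              d[1], d[2], d[3], object@pixelArea))
  counts <- vapply(.VESSELS, function(v)
    sum(object@mask[, , 1] == .MASK_CODES[[v]]), integer(1))
  cat("  ROI pixels (bin 1): ",
      paste(sprintf("%s=%d", .VESSELS, counts), collapse = ", "),
      sprintf("; static=%d\n", sum(object@mask[, , 1] == .STATIC_CODE)), sep = "")
})

#' @rdname accessors
#' @export
setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d subjects x %d sessions (%s fidelity)\n",
              nSubjects(object), nSessions(object), object@config@fidelity))
  cat(sprintf("  %d acquisitions (%d steady-state), %d traces, %d cines\n",
              nrow(object@acquisitions),
              sum(object@acquisitions$phase != "transition"),
              length(object@traces), length(object@cines)))
})
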