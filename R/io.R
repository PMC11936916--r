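## CSV writer preserving full double precision (17 significant digits
## round-trips IEEE doubles exactly through text).
.writeCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.requireFile <- function(path, what) {
  if (!file.exists(path))
    stop("cannot read ", what, ": file '", path, "' is missing")
  path
}

.INT_SLOTS <- c("nSubjects", "nSessions", "seed", "cineGrid")

.configToList <- function(config) {
  sl <- methods::slotNames("CohortConfig")
  out <- lapply(sl, function(s) methods::slot(config, s))
  names(out) <- sl
  out$vesselSplit <- as.list(out$vesselSplit)  # keep names in JSON
  out
}

.configFromList <- function(lst) {
  for (s in .INT_SLOTS) lst[[s]] <- as.integer(lst[[s]])
  lst$vesselSplit <- unlist(lst$vesselSplit)[.VESSELS]
  for (s in c("hxPeto2TargetRange", "placementAlphaRange", "cineOffsetRange"))
    lst[[s]] <- as.numeric(unlist(lst[[s]]))
  ds <- lst$dropoutSpec
  if (is.null(ds) || (is.data.frame(ds) && !nrow(ds)) || !length(ds)) {
    lst$dropoutSpec <- data.frame(subject = character(0), session = integer(0),
                                  phase = character(0), stringsAsFactors = FALSE)
  } else {
    ds <- as.data.frame(ds, stringsAsFactors = FALSE)
    ds$session <- as.integer(ds$session)
    lst$dropoutSpec <- ds
  }
  do.call(methods::new, c(list(Class = "CohortConfig"), lst))
}

.writeCine <- function(cine, id, dir) {
  d <- dim(cine@velocity)
  pxMm <- sqrt(cine@pixelArea) * 10
  vel <- array(cine@velocity, dim = c(d[1], d[2], 1L, d[3]))
  attr(vel, "pixdim") <- c(pxMm, pxMm, 1, 1)
  img <- RNifti::asNifti(vel, datatype = "double", internal = FALSE)
  RNifti::writeNifti(img, file.path(dir, paste0(id, ".nii")))
  msk <- array(as.integer(cine@mask), dim = c(d[1], d[2], 1L, d[3]))
  attr(msk, "pixdim") <- c(pxMm, pxMm, 1, 1)
  mimg <- RNifti::asNifti(msk, datatype = "int16", internal = FALSE)
  RNifti::writeNifti(mimg, file.path(dir, paste0(id, "_mask.nii")))
}

.readCine <- function(id, dir) {
  vpath <- .requireFile(file.path(dir, paste0(id, ".nii")),
                        paste0("velocity cine '", id, "'"))
  mpath <- .requireFile(file.path(dir, paste0(id, "_mask.nii")),
                        paste0("ROI masks of cine '", id, "'"))
  img <- RNifti::readNifti(vpath)
  msk <- RNifti::readNifti(mpath)
  d <- dim(img)
  if (length(d) != 4L || d[3] != 1L)
    stop("cine '", id, "' must have dimensions (x, y, 1, bins)")
  pxCm <- RNifti::pixdim(img)[1] / 10
  methods::new("VelocityCine",
               velocity = array(as.numeric(img), dim = d[c(1, 2, 4)]),
               mask = array(as.integer(msk), dim = d[c(1, 2, 4)]),
               pixelArea = pxCm^2)
}

#' Write a synthetic study to a directory
#'
#' Serialises every component to plain, re-readable formats: one
#' `physio_<subject>_<session>.csv` per session (time_s, petco2_mmHg,
#' peto2_mmHg, spo2_pct, hr_bpm, ve_L_min, phase), `acquisitions.csv`,
#' `anatomy.csv`, the ground truth and generating configuration in
#' `truth.json`, and (image fidelity) per-acquisition NIfTI velocity cines
#' with companion integer-label mask volumes, dimensions (x, y, 1, 8).
#' Doubles are written at full precision, so [readStudy()] restores the
#' study exactly; output bytes depend only on the study content.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(study@traces))
    .writeCsv(as.data.frame(study@traces[[key]]),
              file.path(dir, sprintf("physio_%s.csv", key)))
  acq <- study@acquisitions
  acq$cine_path <- ifelse(is.na(acq$cine_id), "", paste0(acq$cine_id, ".nii"))
  .writeCsv(acq[, setdiff(names(acq), "cine_id")],
            file.path(dir, "acquisitions.csv"))
  .writeCsv(study@anatomy, file.path(dir, "anatomy.csv"))
  jsonlite::write_json(
    list(config = .configToList(study@config), truth = study@truth),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  for (id in names(study@cines)) .writeCine(study@cines[[id]], id, dir)
  invisible(dir)
}

#' Read a study directory written by [writeStudy()]
#'
#' @param dir the study directory.
#' @return a [SyntheticStudy-class] equal to the one written.
#' @export
readStudy <- function(dir) {
  tpath <- .requireFile(file.path(dir, "truth.json"),
                        "ground truth and configuration")
  tj <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  config <- .configFromList(tj$config)
  truth <- as.data.frame(tj$truth, stringsAsFactors = FALSE)
  truth$session <- as.integer(truth$session)

  apath <- .requireFile(file.path(dir, "acquisitions.csv"), "acquisition table")
  acq <- utils::read.csv(apath, stringsAsFactors = FALSE)
  acq$session <- as.integer(acq$session)
  acq$placement <- as.integer(acq$placement)
  for (col in paste0("flow_", .VESSELS))
    acq[[col]] <- as.numeric(acq[[col]])   # all-NA columns parse as logical
  acq$cine_id <- ifelse(is.na(acq$cine_path) | acq$cine_path == "",
                        NA_character_, sub("\\.nii$", "", acq$cine_path))
  acq$cine_path <- NULL

  anpath <- .requireFile(file.path(dir, "anatomy.csv"), "anatomy table")
  anat <- utils::read.csv(anpath, stringsAsFactors = FALSE)

  traces <- list()
  for (key in unique(paste(acq$subject, acq$session, sep = "_"))) {
    ppath <- .requireFile(file.path(dir, sprintf("physio_%s.csv", key)),
                          paste0("physiological trace for session '", key, "'"))
    df <- utils::read.csv(ppath, stringsAsFactors = FALSE)
    traces[[key]] <- methods::new(
      "PhysioTrace", time = df$time_s, petco2 = df$petco2_mmHg,
      peto2 = df$peto2_mmHg, spo2 = df$spo2_pct, heartRate = df$hr_bpm,
      minuteVentilation = df$ve_L_min, phase = df$phase)
  }

  cineIds <- unique(acq$cine_id[!is.na(acq$cine_id)])
  cineList <- list()
  for (id in cineIds) cineList[[id]] <- .readCine(id, dir)

  methods::new("SyntheticStudy", config = config, traces = traces,
               acquisitions = acq, anatomy = anat, truth = truth,
               cines = cineList)
}
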