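# On-disk forms: NIfTI image stacks with a JSON metadata sidecar, 0/1 NIfTI
# ROI masks, and CSV result tables.
#
# Layout written by saveDataset() under a dataset directory:
#   magnitude.nii.gz   2D magnitude image (FLOAT64)
#   phase.nii.gz       H x W x nOffsets phase stack, radians (FLOAT64)
#   meta.json          sidecar with the enumerated metadata keys
#
# FLOAT64 storage keeps the save -> load round trip bit-exact for R doubles.

.metaKeys <- c("frequency_hz", "n_offsets", "pixel_spacing_mm",
               "actuator_position", "side", "subject_id",
               "encoding_scale_rad_per_um")

.metaToList <- function(meta) {
  list(frequency_hz = meta@frequencyHz,
       n_offsets = meta@nOffsets,
       pixel_spacing_mm = meta@pixelSpacingMM,
       actuator_position = meta@actuatorPosition,
       side = meta@side,
       subject_id = meta@subjectId,
       encoding_scale_rad_per_um = meta@encodingScaleRadPerUm)
}

# readNifti() returns a niftiImage; strip header attributes down to a plain
# array so datasets compare identical() after a round trip.
.plainArray <- function(x) {
  a <- as.array(x)
  array(as.numeric(a), dim = dim(a))
}

#' Save an MRE dataset to a directory
#'
#' Writes the magnitude image and phase-offset stack as NIfTI-1 (.nii.gz,
#' FLOAT64) plus a JSON sidecar holding the acquisition metadata under the
#' documented keys (\code{frequency_hz}, \code{n_offsets},
#' \code{pixel_spacing_mm}, \code{actuator_position}, \code{side},
#' \code{subject_id}, \code{encoding_scale_rad_per_um}). The written form
#' round-trips bit-exactly through \code{\link{loadDataset}}.
#'
#' @param ds an \code{\link{MREDataset}}.
#' @param path directory to write into (created if missing).
#' @return Invisibly, the paths of the written files.
#' @export
saveDataset <- function(ds, path) {
  stopifnot(is(ds, "MREDataset"))
  validObject(ds)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create dataset directory: ", path)
  sp <- ds@meta@pixelSpacingMM
  magFile <- file.path(path, "magnitude.nii.gz")
  phaseFile <- file.path(path, "phase.nii.gz")
  metaFile <- file.path(path, "meta.json")
  RNifti::writeNifti(RNifti::asNifti(ds@magnitude, pixdim = c(sp, sp)),
                     magFile, datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(ds@phaseStack, pixdim = c(sp, sp, 1)),
                     phaseFile, datatype = "double")
  jsonlite::write_json(.metaToList(ds@meta), metaFile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(magnitude = magFile, phase = phaseFile, meta = metaFile))
}

#' Load an MRE dataset from a directory
#'
#' Reads the layout written by \code{\link{saveDataset}}, validates the
#' sidecar (every documented key must be present; invariants such as a
#' positive vibration frequency are enforced) and cross-checks image shapes.
#'
#' @param path dataset directory.
#' @return A validated \code{\link{MREDataset}}.
#' @export
loadDataset <- function(path) {
  metaFile <- file.path(path, "meta.json")
  for (f in c(file.path(path, "magnitude.nii.gz"),
              file.path(path, "phase.nii.gz"), metaFile))
    if (!file.exists(f)) stop("missing dataset file: ", f)
  raw <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  missing <- setdiff(.metaKeys, names(raw))
  if (length(missing))
    stop("sidecar is missing required key(s): ",
         paste(missing, collapse = ", "))
  m <- acquisitionMeta(frequencyHz = raw$frequency_hz,
                       nOffsets = raw$n_offsets,
                       pixelSpacingMM = raw$pixel_spacing_mm,
                       actuatorPosition = raw$actuator_position,
                       side = raw$side, subjectId = raw$subject_id,
                       encodingScaleRadPerUm = raw$encoding_scale_rad_per_um)
  mag <- .plainArray(RNifti::readNifti(file.path(path, "magnitude.nii.gz")))
  ph <- .plainArray(RNifti::readNifti(file.path(path, "phase.nii.gz")))
  if (length(dim(mag)) != 2L)
    stop("magnitude image must be 2D, got ", length(dim(mag)), "D")
  if (length(dim(ph)) != 3L)
    stop("phase stack must be 3D, got ", length(dim(ph)), "D")
  mreDataset(magnitude = mag, phaseStack = ph, meta = m)
}

#' Save / load an ROI mask as 0/1 NIfTI
#'
#' @param roi an \code{\link{ROIMask}}.
#' @param file output \code{.nii.gz} path.
#' @return \code{saveROIMask} invisibly returns \code{file};
#'   \code{loadROIMask} returns an \code{ROIMask}.
#' @export
saveROIMask <- function(roi, file) {
  stopifnot(is(roi, "ROIMask"))
  m <- roi@mask
  storage.mode(m) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(m), file, datatype = "uint8")
  invisible(file)
}

#' @rdname saveROIMask
#' @param label label to attach to the loaded mask.
#' @export
loadROIMask <- function(file, label = "ROI") {
  a <- as.array(RNifti::readNifti(file))
  roiMask(array(a != 0, dim = dim(a)), label = label)
}

#' Write a homogeneous list of result records as CSV
#'
#' Accepts a data.frame or a list of named lists/vectors with identical key
#' sets; writes RFC 4180 CSV (UTF-8, header row, stable column order taken
#' from the first record).
#'
#' @param records data.frame, or list of named records with homogeneous keys.
#' @param path output CSV file path.
#' @return Invisibly, the data.frame that was written.
#' @export
writeResultsCSV <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (!is.list(records))
      stop("records must be a data.frame or a list of named records")
    if (length(records) == 0L) {
      df <- data.frame()
    } else {
      keys <- names(records[[1L]])
      if (is.null(keys) || any(keys == ""))
        stop("records must have named fields")
      for (i in seq_along(records)) {
        ki <- names(records[[i]])
        if (!identical(sort(ki), sort(keys)))
          stop("record ", i, " has keys {", paste(ki, collapse = ", "),
               "} differing from the first record")
      }
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r[keys], stringsAsFactors = FALSE)))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' Read a results CSV written by \code{\link{writeResultsCSV}}
#' @param path CSV file path.
#' @return A data.frame.
#' @export
readResultsCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
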