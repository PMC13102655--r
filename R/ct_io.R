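#' Read a calibrated CT volume from NIfTI-1
#'
#' Reads a 3-D scalar NIfTI-1 file (`.nii` or `.nii.gz`), applies any header
#' scale slope/intercept so returned values are in Hounsfield Units, and
#' extracts voxel spacing from the header. NIfTI-1 is the only supported
#' on-disk format; DICOM series must be converted upstream.
#'
#' @param path path to a readable NIfTI-1 file.
#' @param id label for the volume; defaults to the file name.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (!is.character(path) || length(path) != 1)
    abort_usage("path must be a single file path")
  if (!file.exists(path))
    abort_data(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path, internal = FALSE)
  dims <- dim(img)
  if (is.null(dims) || length(dims) != 3)
    abort_data(sprintf(
      "expected 3-D scalar data, got %s-D in %s",
      length(dims) %||% 1, path
    ))
  sp <- RNifti::pixdim(img)
  if (length(sp) != 3 || anyNA(sp) || any(sp <= 0))
    abort_data(sprintf(
      "calibration error: invalid voxel spacing (%s) in %s",
      paste(sp, collapse = ", "), path
    ))
  hdr <- RNifti::niftiHeader(img)
  origin <- tryCatch(as.numeric(RNifti::origin(img)), error = function(e) c(0, 0, 0))
  if (length(origin) != 3 || anyNA(origin)) origin <- c(0, 0, 0)
  data <- as.array(img)
  attributes(data) <- list(dim = dims)
  if (!all(is.finite(data)))
    abort_data(sprintf("non-finite values in %s", path))
  ct_volume(data, voxel_geometry(sp, origin), id = id %||% basename(path))
}

#' Write a CT volume as NIfTI-1
#'
#' HU values are stored as 32-bit floats with slope 1 / intercept 0.
#'
#' @param vol a [ct_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  data <- vol$data
  attr(data, "pixdim") <- vol$geometry$spacing
  img <- RNifti::asNifti(data, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' Any strictly positive voxel is treated as inside the mask.
#'
#' @param path path to a NIfTI-1 mask (uint8 0/1 by convention).
#' @param reference optional [ct_volume()]; when given, grid shape and
#'   spacing are checked against it.
#' @return A [lung_mask()].
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  m <- lung_mask(array(vol$data > 0, dim = dim(vol$data)), vol$geometry)
  if (!is.null(reference)) check_same_grid(reference, m)
  m
}

#' Write a binary mask as NIfTI-1 (uint8 0/1)
#'
#' @param mask a [lung_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask"))
  data <- array(as.integer(mask$data), dim = dim(mask$data))
  attr(data, "pixdim") <- mask$geometry$spacing
  img <- RNifti::asNifti(data, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Heuristic HU calibration report
#'
#' Checks that a volume plausibly sits on the Hounsfield scale. A properly
#' calibrated thorax scan contains ambient/lumen air near -1000 HU, so a
#' volume with fewer than 0.1% of voxels in \[-1100, -900\] is flagged as
#' having no air reference. The check only reports; it never rescales data.
#'
#' @param vol a [ct_volume()].
#' @return A flat list (JSON-serialisable): voxel fractions below -1100 HU,
#'   above +3100 HU and in the air-reference window \[-1100, -900\], the value
#'   range, and logical `no_air_reference`.
#' @export
validate_hu_calibration <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- vol$data
  n <- length(d)
  air_frac <- sum(d >= -1100 & d <= -900) / n
  list(
    id = vol$id,
    n_voxels = n,
    frac_below_minus1100 = sum(d < -1100) / n,
    frac_above_3100 = sum(d > 3100) / n,
    frac_air_reference = air_frac,
    hu_min = min(d),
    hu_max = max(d),
    no_air_reference = air_frac < 0.001
  )
}
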