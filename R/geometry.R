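#' Voxel geometry of a CT grid
#'
#' Captures the physical sampling of a 3-D image grid: per-axis voxel spacing
#' in millimetres and the position of the first voxel. Axes are used exactly
#' as stored on disk (`axis_order = "xyz"`); no reorientation is performed
#' anywhere in the package, because the aeration analysis is histogram-based
#' and therefore orientation-invariant.
#'
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, coordinates of the first voxel in mm.
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry(c(0.072, 0.072, 0.072))
#' @export
voxel_geometry <- function(spacing, origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || anyNA(spacing) || any(spacing <= 0))
    abort_data("voxel spacing must be 3 positive lengths (mm)")
  if (length(origin) != 3 || anyNA(origin))
    abort_data("origin must be 3 finite coordinates (mm)")
  structure(
    list(spacing = spacing, origin = origin, axis_order = "xyz"),
    class = "voxel_geometry"
  )
}

#' Physical volume of one voxel
#'
#' @param x a `voxel_geometry`, or any object carrying one in `$geometry`
#'   (a [ct_volume()] or [lung_mask()]).
#' @return Voxel volume in mm^3 (product of the three spacings).
#' @examples
#' voxel_volume_mm3(voxel_geometry(c(0.072, 0.072, 0.072)))  # 3.73248e-4
#' @export
voxel_volume_mm3 <- function(x) {
  geom <- if (inherits(x, "voxel_geometry")) x else x$geometry
  if (!inherits(geom, "voxel_geometry"))
    abort_usage("no voxel geometry found on object")
  prod(geom$spacing)
}

#' Calibrated CT volume
#'
#' A 3-D grid of Hounsfield Unit values with its voxel geometry. Values are
#' held as doubles regardless of the on-disk storage type; any header
#' slope/intercept has already been applied by [read_volume()].
#'
#' @param data 3-D numeric array of finite HU values.
#' @param geometry a [voxel_geometry()].
#' @param id free-text label (defaults to `"volume"`).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, geometry, id = "volume") {
  if (!is.array(data) || length(dim(data)) != 3)
    abort_data("CT data must be a 3-D array")
  if (any(dim(data) < 1))
    abort_data("CT grid needs at least one voxel per axis")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    abort_data("CT volume contains non-finite HU values")
  if (!inherits(geometry, "voxel_geometry"))
    abort_usage("geometry must be a voxel_geometry")
  structure(
    list(data = data, geometry = geometry, id = as.character(id)[1]),
    class = "ct_volume"
  )
}

#' Binary mask aligned to a CT volume
#'
#' @param data 3-D logical array (coercible); `TRUE` marks included voxels.
#' @param geometry a [voxel_geometry()] matching the source volume.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(data, geometry) {
  if (!is.array(data) || length(dim(data)) != 3)
    abort_data("mask data must be a 3-D array")
  storage.mode(data) <- "logical"
  if (anyNA(data))
    abort_data("mask contains NA values")
  if (!inherits(geometry, "voxel_geometry"))
    abort_usage("geometry must be a voxel_geometry")
  structure(list(data = data, geometry = geometry), class = "lung_mask")
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    abort_data(sprintf(
      "grid shapes differ: %s vs %s",
      paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x")
    ))
  if (max(abs(a$geometry$spacing - b$geometry$spacing)) > 1e-6)
    abort_data("voxel spacings differ between volume and mask")
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume '%s'> %s voxels @ (%s) mm, HU range [%.1f, %.1f]\n",
    x$id, paste(dim(x$data), collapse = "x"),
    paste(format(x$geometry$spacing, digits = 4), collapse = ", "),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf(
    "<lung_mask> %s voxels, %d in mask (%.2f mm^3)\n",
    paste(dim(x$data), collapse = "x"), sum(x$data), mask_volume_mm3(x)
  ))
  invisible(x)
}
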