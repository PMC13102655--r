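#' Parameters of the thresholding segmentation pipeline
#'
#' All thresholds are in HU. Defaults reproduce the standard densitometric
#' conventions: parenchyma within \[-900, -100\], body/soft tissue above
#' -500, airway lumen and ambient air below -900.
#'
#' @param parenchyma_lo,parenchyma_hi HU limits of the parenchymal range.
#' @param body_threshold HU above which a voxel counts as body/soft tissue.
#' @param lumen_threshold HU below which lung-interior air is treated as
#'   airway lumen / trapped gas (excluded from parenchyma, kept in the lung
#'   mask for visualisation).
#' @param closing_radius_vox radius (voxels) of the per-slice morphological
#'   closing applied to the lung mask; 0 disables closing.
#' @param min_component_vox connected components of the lung candidate mask
#'   smaller than this are discarded as noise.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(parenchyma_lo = -900, parenchyma_hi = -100,
                                body_threshold = -500, lumen_threshold = -900,
                                closing_radius_vox = 2, min_component_vox = 100) {
  if (!(parenchyma_lo < parenchyma_hi))
    abort_usage("parenchyma_lo must be < parenchyma_hi")
  if (!(lumen_threshold <= parenchyma_lo))
    abort_usage("lumen_threshold must be <= parenchyma_lo")
  if (closing_radius_vox < 0 || closing_radius_vox != round(closing_radius_vox))
    abort_usage("closing_radius_vox must be a non-negative integer")
  if (min_component_vox < 1)
    abort_usage("min_component_vox must be a positive integer")
  structure(
    list(
      parenchyma_lo = parenchyma_lo, parenchyma_hi = parenchyma_hi,
      body_threshold = body_threshold, lumen_threshold = lumen_threshold,
      closing_radius_vox = as.integer(closing_radius_vox),
      min_component_vox = as.integer(min_component_vox)
    ),
    class = "segmentation_params"
  )
}

# 3-D connected-component labels (6-connectivity) via the voxel adjacency
# graph. Returns an integer array: 0 outside the mask, 1..n_components
# inside, components numbered in decreasing size order.
label_components_3d <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(lab)
  rank <- array(0L, dims)
  rank[idx] <- seq_along(idx)
  edge_pairs <- function(axis) {
    d <- dims
    a_idx <- slice.index(rank, axis) < d[axis]
    b_idx <- slice.index(rank, axis) > 1L
    a <- rank[a_idx]
    b <- rank[b_idx]
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, lapply(1:3, edge_pairs))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  lab[idx] <- relabel[comp$membership]
  lab
}

# 2-D hole filling applied independently to each axial (third-axis) slice.
fill_holes_slicewise <- function(mask) {
  filled <- EBImage::fillHull(array(as.numeric(mask), dim = dim(mask)))
  array(filled > 0.5, dim = dim(mask))
}

#' Extract the body (animal) mask from a thorax volume
#'
#' Largest 6-connected component of voxels at or above `body_threshold`,
#' hole-filled per axial slice so interior air (lungs, airways) is part of
#' the body. This separates lung air from ambient air before lung
#' extraction.
#'
#' @param vol a [ct_volume()].
#' @param params a [segmentation_params()].
#' @return A [lung_mask()] marking the body.
#' @export
extract_body_mask <- function(vol, params = segmentation_params()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(params, "segmentation_params"))
  cand <- vol$data >= params$body_threshold
  if (!any(cand))
    abort_data(sprintf(
      "no body found: no voxel >= %g HU (volume max %.1f HU)",
      params$body_threshold, max(vol$data)
    ))
  lab <- label_components_3d(cand)
  body <- fill_holes_slicewise(lab == 1L)
  lung_mask(body, vol$geometry)
}

#' Extract the lung mask inside the body
#'
#' Low-density voxels (below `body_threshold`) strictly inside the body
#' mask, with small connected components removed and an optional per-slice
#' morphological closing. Airway lumen remains included here; it is removed
#' only at the parenchyma step.
#'
#' @param vol a [ct_volume()].
#' @param body body mask from [extract_body_mask()].
#' @param params a [segmentation_params()].
#' @return A [lung_mask()]. The number of connected components retained
#'   before closing is attached as attribute `n_components`.
#' @export
extract_lung_mask <- function(vol, body, params = segmentation_params()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(body, "lung_mask"))
  check_same_grid(vol, body)
  if (!any(body$data)) abort_data("body mask is empty")
  cand <- (vol$data < params$body_threshold) & body$data
  lab <- label_components_3d(cand)
  if (max(lab) == 0L)
    abort_data("no lung candidate found: body has no low-density interior")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_component_vox)
  if (length(keep) == 0L)
    abort_data(sprintf(
      "no lung candidate found: all %d low-density components below %d voxels",
      length(sizes), params$min_component_vox
    ))
  m <- array(lab %in% keep, dim = dim(lab))
  if (params$closing_radius_vox > 0L) {
    brush <- EBImage::makeBrush(2L * params$closing_radius_vox + 1L, shape = "disc")
    closed <- EBImage::closing(array(as.numeric(m), dim = dim(m)), brush)
    m <- (closed > 0.5) & body$data  # closing must not leak outside the body
  }
  out <- lung_mask(m, vol$geometry)
  attr(out, "n_components") <- length(keep)
  out
}

#' Extract the parenchyma mask from the lung mask
#'
#' Keeps lung voxels whose HU lies in \[`parenchyma_lo`, `parenchyma_hi`\].
#' Voxels below the range (airway lumen, trapped air) and above it (vessels,
#' dense consolidation) are excluded from densitometry.
#'
#' @param vol a [ct_volume()].
#' @param lung lung mask from [extract_lung_mask()].
#' @param params a [segmentation_params()].
#' @return A [lung_mask()] marking parenchyma voxels.
#' @export
extract_parenchyma_mask <- function(vol, lung, params = segmentation_params()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lung, "lung_mask"))
  check_same_grid(vol, lung)
  if (!any(lung$data)) abort_data("lung mask is empty")
  hu <- vol$data[lung$data]
  inside <- hu >= params$parenchyma_lo & hu <= params$parenchyma_hi
  if (!any(inside))
    abort_data(sprintf(
      paste0("empty parenchyma: no lung voxel in [%g, %g] HU ",
             "(lung HU range [%.1f, %.1f], median %.1f)"),
      params$parenchyma_lo, params$parenchyma_hi,
      min(hu), max(hu), stats::median(hu)
    ))
  m <- lung$data & vol$data >= params$parenchyma_lo & vol$data <= params$parenchyma_hi
  lung_mask(m, vol$geometry)
}

#' Physical volume of a mask
#'
#' @param mask a [lung_mask()].
#' @return Volume in mm^3: voxel count times voxel volume.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "lung_mask"))
  sum(mask$data) * voxel_volume_mm3(mask)
}

#' Full segmentation pipeline: body, lung, parenchyma
#'
#' @param vol a [ct_volume()].
#' @param params a [segmentation_params()].
#' @return List with masks `body`, `lung`, `parenchyma`.
#' @export
segment_volume <- function(vol, params = segmentation_params()) {
  body <- extract_body_mask(vol, params)
  lung <- extract_lung_mask(vol, body, params)
  parenchyma <- extract_parenchyma_mask(vol, lung, params)
  list(body = body, lung = lung, parenchyma = parenchyma)
}
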