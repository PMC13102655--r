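#' Construct an equal-width HU bin scheme
#'
#' Bins are contiguous, non-overlapping and exactly cover \[`lo`, `hi`\].
#' Each bin is half-open `[lo, hi)` except the last, which is closed; on
#' integer HU data this is identical to the conventional integer boundary
#' listing (-900/-821, -820/-741, ...), while removing any ambiguity for
#' non-integer values.
#'
#' @param lo,hi HU limits of the binned range, `lo < hi`.
#' @param n_bins number of equal-width bins (>= 1).
#' @return An object of class `bin_scheme` with fields `edges` (length
#'   `n_bins + 1`) and `labels`.
#' @examples
#' make_bin_scheme(-900, -100, 10)  # ten bins of 80 HU
#' @export
make_bin_scheme <- function(lo, hi, n_bins) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    abort_usage("need finite lo < hi")
  if (n_bins < 1 || n_bins != round(n_bins))
    abort_usage("n_bins must be a positive integer")
  n_bins <- as.integer(n_bins)
  edges <- lo + (0:n_bins) * (hi - lo) / n_bins
  labels <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                    c(rep(")", n_bins - 1), "]"))
  bin_scheme(edges, labels)
}

bin_scheme <- function(edges, labels = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || anyNA(edges) || any(diff(edges) <= 0))
    abort_usage("bin edges must be strictly increasing, length >= 2")
  n <- length(edges) - 1L
  if (is.null(labels))
    labels <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                      c(rep(")", n - 1), "]"))
  if (length(labels) != n)
    abort_usage("need one label per bin")
  structure(list(edges = edges, labels = as.character(labels)),
            class = "bin_scheme")
}

n_bins <- function(scheme) length(scheme$edges) - 1L

#' The conventional two-compartment aeration scheme
#'
#' Well-aerated `[-900, -500)` and poorly-aerated `[-500, -100]`. A voxel at
#' exactly -500 HU is classified poorly-aerated.
#'
#' @return A `bin_scheme` with two bins.
#' @export
two_compartment_scheme <- function() {
  bin_scheme(c(-900, -500, -100), c("well-aerated", "poorly-aerated"))
}

#' The refined ten-bin aeration scheme
#'
#' Ten equal 80-HU bins over the 800-HU parenchymal range \[-900, -100\].
#'
#' @return A `bin_scheme` with ten bins.
#' @export
ten_bin_scheme <- function() make_bin_scheme(-900, -100, 10)

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d bins over [%g, %g] HU\n",
              n_bins(x), x$edges[1], x$edges[length(x$edges)]))
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

# Bin index per value under the half-open convention (last bin closed).
# Values outside [first, last] return 0 / n_bins + 1.
bin_index_of <- function(hu, scheme) {
  findInterval(hu, scheme$edges, rightmost.closed = TRUE)
}

#' Compute an aeration profile
#'
#' Counts parenchyma voxels per HU bin, converts counts to volumes via the
#' voxel volume, and expresses each bin as a percentage of total lung
#' volume. The denominator is the total segmented parenchyma volume (the sum
#' over bins), so fractions always sum to 100.
#'
#' @param vol a [ct_volume()].
#' @param parenchyma parenchyma mask from [extract_parenchyma_mask()].
#' @param scheme a `bin_scheme`; must span all parenchymal HU values.
#' @param subject_id,group,timepoint metadata labels carried into tables.
#' @return An object of class `aeration_profile` with per-bin integer voxel
#'   `counts`, `volumes_mm3`, `fractions_pct` and `total_volume_mm3`.
#' @export
compute_profile <- function(vol, parenchyma, scheme,
                            subject_id = NULL, group = NA_character_,
                            timepoint = NA_character_) {
  stopifnot(inherits(vol, "ct_volume"), inherits(parenchyma, "lung_mask"),
            inherits(scheme, "bin_scheme"))
  check_same_grid(vol, parenchyma)
  hu <- vol$data[parenchyma$data]
  if (length(hu) == 0L) abort_data("empty parenchyma mask")
  new_profile_from_counts(
    counts = count_in_bins(hu, scheme),
    scheme = scheme,
    voxel_mm3 = voxel_volume_mm3(vol),
    subject_id = subject_id %||% vol$id, group = group, timepoint = timepoint
  )
}

count_in_bins <- function(hu, scheme) {
  k <- n_bins(scheme)
  bi <- bin_index_of(hu, scheme)
  if (any(bi < 1L | bi > k))
    abort_data(sprintf(
      "internal consistency error: %d parenchyma voxels outside scheme range [%g, %g]",
      sum(bi < 1L | bi > k), scheme$edges[1], scheme$edges[k + 1]
    ))
  tabulate(bi, nbins = k)
}

new_profile_from_counts <- function(counts, scheme, voxel_mm3,
                                    subject_id, group, timepoint) {
  volumes <- counts * voxel_mm3
  total <- sum(volumes)
  structure(
    list(
      scheme = scheme,
      counts = as.integer(counts),
      volumes_mm3 = volumes,
      fractions_pct = if (total > 0) 100 * volumes / total else rep(0, length(volumes)),
      total_volume_mm3 = total,
      subject_id = as.character(subject_id),
      group = as.character(group),
      timepoint = as.character(timepoint)
    ),
    class = "aeration_profile"
  )
}

#' @export
print.aeration_profile <- function(x, ...) {
  cat(sprintf("<aeration_profile> '%s' (%s, %s), total %.3f mm^3\n",
              x$subject_id, x$group, x$timepoint, x$total_volume_mm3))
  print(data.frame(bin = x$scheme$labels,
                   volume_mm3 = round(x$volumes_mm3, 4),
                   fraction_pct = round(x$fractions_pct, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Aggregate a profile into a coarser nested scheme
#'
#' Every boundary of `target` must coincide with a boundary of the source
#' scheme; bin counts and volumes are summed, so aggregating the ten-bin
#' profile to the two-compartment scheme reproduces a directly computed
#' two-compartment profile exactly (bins 1-5 cover -900..-500, bins 6-10
#' cover -500..-100).
#'
#' @param p an `aeration_profile`.
#' @param target a `bin_scheme` nested in `p$scheme`.
#' @return An `aeration_profile` on `target`.
#' @export
aggregate_profile <- function(p, target) {
  stopifnot(inherits(p, "aeration_profile"), inherits(target, "bin_scheme"))
  src <- p$scheme$edges
  matched <- vapply(target$edges, function(e) {
    j <- which(abs(src - e) < 1e-9)
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
  if (anyNA(matched))
    abort_data("target scheme is not nested in the profile's scheme")
  if (matched[1] != 1L || matched[length(matched)] != length(src))
    abort_data("target scheme must span the full source range")
  dest <- findInterval(seq_len(n_bins(p$scheme)), matched)
  counts <- as.integer(rowsum(p$counts, dest))
  new_profile_from_counts(
    counts, target,
    voxel_mm3 = if (sum(p$counts) > 0) p$total_volume_mm3 / sum(p$counts) else 1,
    subject_id = p$subject_id, group = p$group, timepoint = p$timepoint
  )
}

#' Long-format table of aeration profiles
#'
#' @param profiles a single `aeration_profile` or a list of them; all must
#'   share one bin scheme.
#' @return A tibble with one row per profile and bin: `subject_id`, `group`,
#'   `timepoint`, `bin_index`, `bin_lo`, `bin_hi`, `bin_label`, `n_voxels`,
#'   `volume_mm3`, `fraction_pct`.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "aeration_profile")) profiles <- list(profiles)
  cols <- c("subject_id", "group", "timepoint", "bin_index", "bin_lo",
            "bin_hi", "bin_label", "n_voxels", "volume_mm3", "fraction_pct")
  if (length(profiles) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      c(rep(list(character()), 3), list(integer()), rep(list(numeric()), 2),
        list(character()), list(integer()), rep(list(numeric()), 2)),
      cols))
    return(out)
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "aeration_profile")))
  edges1 <- profiles[[1]]$scheme$edges
  same <- vapply(profiles, function(p)
    length(p$scheme$edges) == length(edges1) &&
      max(abs(p$scheme$edges - edges1)) < 1e-9, logical(1))
  if (!all(same)) abort_data("profiles mix different bin schemes")
  k <- n_bins(profiles[[1]]$scheme)
  dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(
      subject_id = p$subject_id, group = p$group, timepoint = p$timepoint,
      bin_index = seq_len(k),
      bin_lo = p$scheme$edges[-(k + 1)], bin_hi = p$scheme$edges[-1],
      bin_label = p$scheme$labels,
      n_voxels = p$counts, volume_mm3 = p$volumes_mm3,
      fraction_pct = p$fractions_pct
    )
  }))
}

#' Per-voxel bin label map for visualisation
#'
#' Assigns each parenchyma voxel the index of its HU bin (1..n, ordered from
#' most to least aerated) and 0 elsewhere, mirroring the green-to-red
#' gradient renderings of binned lung segmentations.
#'
#' @inheritParams compute_profile
#' @return Integer 3-D array of class `bin_labelmap` with attributes
#'   `geometry` and `scheme`; write with [write_labelmap()].
#' @export
render_bin_labelmap <- function(vol, parenchyma, scheme) {
  stopifnot(inherits(vol, "ct_volume"), inherits(parenchyma, "lung_mask"))
  check_same_grid(vol, parenchyma)
  hu <- vol$data[parenchyma$data]
  if (length(hu) == 0L) abort_data("empty parenchyma mask")
  bi <- bin_index_of(hu, scheme)
  k <- n_bins(scheme)
  if (any(bi < 1L | bi > k))
    abort_data("internal consistency error: parenchyma voxel outside scheme range")
  lab <- array(0L, dim = dim(vol$data))
  lab[parenchyma$data] <- as.integer(bi)
  structure(lab, geometry = vol$geometry, scheme = scheme,
            class = c("bin_labelmap", class(lab)))
}

#' Write a bin label map as NIfTI-1 (uint8)
#'
#' @param labelmap output of [render_bin_labelmap()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "bin_labelmap"))
  geom <- attr(labelmap, "geometry")
  data <- array(as.integer(labelmap), dim = dim(labelmap))
  attr(data, "pixdim") <- geom$spacing
  RNifti::writeNifti(RNifti::asNifti(data, datatype = "uint8"), path)
  invisible(path)
}

#' Write / read profile tables as CSV
#'
#' @param tbl a profile table from [profile_table()].
#' @param path CSV path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_profile_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = "c", group = "c", timepoint = "c"
                  ))
}
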