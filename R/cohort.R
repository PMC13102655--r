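#' One arm of a simulated cohort
#'
#' @param name group label.
#' @param n number of animals (>= 1).
#' @param f named numeric vector: densification severity per time point
#'   (names are the time point labels, values in \[0, 1\]).
#' @return A list describing the group.
#' @export
cohort_group <- function(name, n, f) {
  if (n < 1 || n != round(n)) abort_usage("n must be a positive integer")
  if (is.null(names(f)) || any(!nzchar(names(f))))
    abort_usage("f must be a named vector (time point labels)")
  if (any(f < 0 | f > 1)) abort_usage("severities must lie in [0, 1]")
  list(name = as.character(name), n = as.integer(n), f = f)
}

#' Specification of a simulated study cohort
#'
#' A multi-arm longitudinal design: each group follows a severity
#' trajectory `f(t)`; each animal carries a persistent severity offset
#' (sd `f_sd`, trajectory clipped to \[0, 1\]) and a persistent baseline
#' attenuation offset on `mu0` (sd `mu0_jitter_sd`, HU), representing
#' between-animal differences in inflation/baseline density. Default arms
#' mirror a low-dose chronic injury design: a 9-animal control, an
#' 11-animal treated arm developing moderate densification from day 14, and
#' a single-animal high-dose descriptive arm.
#'
#' @param groups list of [cohort_group()]s sharing identical time point
#'   names.
#' @param template a [phantom_spec()] shared by all animals.
#' @param f_sd sd of the per-animal severity offset.
#' @param mu0_jitter_sd sd (HU) of the per-animal baseline mean offset.
#' @param profile_voxels parenchyma voxels sampled per animal by the
#'   histogram-level generator [simulate_cohort_profiles()].
#' @param seed RNG seed; all generation is reproducible given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          cohort_group("Sham", 9, c(day0 = 0, day14 = 0, day21 = 0)),
                          cohort_group("BLM", 11, c(day0 = 0, day14 = 0.15, day21 = 0.15)),
                          cohort_group("BLM+", 1, c(day0 = 0, day14 = 0.30, day21 = 0.60))
                        ),
                        template = phantom_spec(),
                        f_sd = 0.03, mu0_jitter_sd = 20,
                        profile_voxels = 20000,
                        seed = 1L) {
  if (length(groups) < 1) abort_usage("need at least one group")
  tps <- names(groups[[1]]$f)
  ok <- vapply(groups, function(g) identical(names(g$f), tps), logical(1))
  if (!all(ok)) abort_usage("all groups must share the same time points")
  if (anyDuplicated(vapply(groups, `[[`, character(1), "name")))
    abort_usage("group names must be unique")
  if (f_sd < 0 || mu0_jitter_sd < 0) abort_usage("dispersions must be >= 0")
  if (profile_voxels < 10) abort_usage("profile_voxels too small")
  stopifnot(inherits(template, "phantom_spec"))
  structure(
    list(groups = groups, timepoints = tps, template = template,
         f_sd = f_sd, mu0_jitter_sd = mu0_jitter_sd,
         profile_voxels = as.integer(profile_voxels),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Per-animal draws shared by both generators: persistent severity offset and
# baseline-mean jitter for every animal, plus one sub-seed per
# animal-time point. Must be called right after set.seed(spec$seed) so both
# generation paths see identical animal-level parameters.
cohort_animal_table <- function(spec) {
  g_names <- vapply(spec$groups, `[[`, character(1), "name")
  n_per <- vapply(spec$groups, `[[`, integer(1), "n")
  animals <- do.call(rbind, lapply(seq_along(spec$groups), function(i) {
    data.frame(
      group = g_names[i],
      animal_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g_names[i]),
                          seq_len(n_per[i])),
      stringsAsFactors = FALSE
    )
  }))
  animals$f_offset <- stats::rnorm(nrow(animals), 0, spec$f_sd)
  animals$mu0_offset <- stats::rnorm(nrow(animals), 0, spec$mu0_jitter_sd)
  animals
}

cohort_design_long <- function(spec) {
  animals <- cohort_animal_table(spec)
  f_of <- function(g, tp) {
    grp <- spec$groups[[which(vapply(spec$groups, `[[`, character(1), "name") == g)]]
    unname(grp$f[[tp]])
  }
  long <- merge(animals, expand.grid(animal_id = animals$animal_id,
                                     timepoint = spec$timepoints,
                                     stringsAsFactors = FALSE),
                by = "animal_id")
  long$f_group <- mapply(f_of, long$group, long$timepoint)
  long$f_true <- pmin(1, pmax(0, long$f_group + long$f_offset))
  long <- long[order(long$group, long$animal_id, long$timepoint), ]
  rownames(long) <- NULL
  long$subseed <- sample.int(.Machine$integer.max - 1L, nrow(long))
  long
}

#' Generate a cohort of phantom volumes on disk
#'
#' Writes one NIfTI volume per animal and time point plus a metadata CSV
#' (`cohort.csv`: animal id, group, time point, true severity, file path).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return The metadata tibble, invisibly written to `cohort.csv`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  long <- cohort_design_long(spec)
  paths <- character(nrow(long))
  for (i in seq_len(nrow(long))) {
    pspec <- spec$template
    pspec$mu0 <- pspec$mu0 + long$mu0_offset[i]
    pspec$f <- long$f_true[i]
    pspec$seed <- long$subseed[i]
    ph <- generate_phantom(pspec)
    paths[i] <- file.path(out_dir, sprintf("%s_%s.nii.gz",
                                           long$animal_id[i], long$timepoint[i]))
    write_volume(ph$volume, paths[i])
  }
  meta <- tibble::tibble(
    animal_id = long$animal_id, group = long$group,
    timepoint = long$timepoint, f_true = long$f_true,
    path = paths
  )
  readr::write_csv(meta, file.path(out_dir, "cohort.csv"))
  meta
}

#' Histogram-level cohort profiles (no spatial rendering)
#'
#' Samples each animal's parenchymal HU values directly from its mixture
#' law (`profile_voxels` draws, noiseless) and bins them, skipping image
#' synthesis and segmentation. The distributional ground truth is identical
#' to profiling a noise-free spatial phantom's true parenchyma mask; this
#' path exists so replicated power and calibration experiments run at
#' simulation speed.
#'
#' @param spec a [cohort_spec()].
#' @param scheme bin scheme for the profiles (default ten-bin).
#' @param timepoints subset of time points to simulate (default all).
#' @return A profile table ([profile_table()] layout).
#' @export
simulate_cohort_profiles <- function(spec, scheme = ten_bin_scheme(),
                                     timepoints = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  long <- cohort_design_long(spec)
  if (!is.null(timepoints)) {
    bad <- setdiff(timepoints, spec$timepoints)
    if (length(bad))
      abort_usage(sprintf("unknown time points: %s", paste(bad, collapse = ", ")))
    long <- long[long$timepoint %in% timepoints, , drop = FALSE]
  }
  tmpl <- spec$template
  vox_mm3 <- prod(tmpl$spacing)
  nv <- spec$profile_voxels
  profiles <- lapply(seq_len(nrow(long)), function(i) {
    set.seed(long$subseed[i])
    hu <- rtrunc_mixture(nv, long$f_true[i],
                         tmpl$mu0 + long$mu0_offset[i], tmpl$sigma0,
                         tmpl$mu1, tmpl$sigma1,
                         tmpl$hu_range[1], tmpl$hu_range[2])
    new_profile_from_counts(count_in_bins(hu, scheme), scheme, vox_mm3,
                            subject_id = long$animal_id[i],
                            group = long$group[i],
                            timepoint = long$timepoint[i])
  })
  profile_table(profiles)
}
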