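#' Plot aeration curves (mean fraction per bin, by group)
#'
#' One line per group: mean fraction (%) per HU bin with SEM error bars,
#' bins on the abscissa ordered from most aerated (lowest HU) to least
#' aerated. Groups with a single animal are drawn without error bars.
#'
#' @param tbl a profile table ([profile_table()]); one shared scheme.
#' @param timepoint time point to plot (may be omitted when unique).
#' @param groups optional subset/order of groups.
#' @return A ggplot object.
#' @export
plot_aeration_curves <- function(tbl, timepoint = NULL, groups = NULL) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0) abort_data("empty profile table")
  tps <- unique(tbl$timepoint)
  if (is.null(timepoint)) {
    if (length(tps) != 1) abort_usage("multiple time points; specify `timepoint`")
    timepoint <- tps
  }
  d <- tbl[tbl$timepoint == timepoint, , drop = FALSE]
  if (nrow(d) == 0) abort_data(sprintf("no profiles at time point '%s'", timepoint))
  if (!is.null(groups)) d <- d[d$group %in% groups, , drop = FALSE]
  lvls <- unique(d$bin_label[order(d$bin_lo)])
  summ <- d |>
    dplyr::group_by(.data$group, .data$bin_index, .data$bin_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct = mean(.data$fraction_pct),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$fraction_pct) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin_label = factor(.data$bin_label, levels = lvls))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin_label, y = .data$mean_pct,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      data = dplyr::filter(summ, !is.na(.data$sem)),
      ggplot2::aes(ymin = .data$mean_pct - .data$sem,
                   ymax = .data$mean_pct + .data$sem),
      width = 0.2
    ) +
    ggplot2::labs(
      x = "HU bin (most to least aerated)",
      y = "Fraction of total lung volume (%)",
      colour = "Group",
      title = sprintf("Aeration profile, %s", timepoint)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

save_plot <- function(p, path, width = 7, height = 4.5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" && !capabilities("png"))
    abort_data("PNG device unavailable; use .pdf or .svg")
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_spec()] to simulate, or `NULL` when analysing
#'   existing volumes listed in `metadata_csv`.
#' @param metadata_csv CSV with columns `animal_id, group, timepoint, path`
#'   pointing at NIfTI volumes (ignored when `cohort` is given).
#' @param params a [segmentation_params()].
#' @param n_bins,hu_lo,hu_hi bin scheme of the profile step.
#' @param control control group for the comparison step.
#' @param design `"anova_dunnett"` or `"per_bin_t"`.
#' @param alpha significance level.
#' @param seed seed for the simulation and the Dunnett Monte Carlo.
#' @param plot_format `"pdf"` or `"png"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = cohort_spec(), metadata_csv = NULL,
                       params = segmentation_params(),
                       n_bins = 10, hu_lo = -900, hu_hi = -100,
                       control = "Sham", design = "anova_dunnett",
                       alpha = 0.05, seed = 1L, plot_format = "pdf") {
  if (alpha <= 0 || alpha >= 1) abort_usage("alpha must be in (0, 1)")
  if (is.null(cohort) && is.null(metadata_csv))
    abort_usage("provide either a cohort to simulate or a metadata CSV")
  structure(
    list(out_dir = out_dir, cohort = cohort, metadata_csv = metadata_csv,
         params = params, n_bins = n_bins, hu_lo = hu_lo, hu_hi = hu_hi,
         control = control, design = design, alpha = alpha,
         seed = as.integer(seed), plot_format = plot_format),
    class = "run_config"
  )
}

#' Run the full pipeline: simulate/segment/profile/compare/plot
#'
#' Executes every stage, writes all artifacts under `config$out_dir`
#' (masks, `profiles.csv`, `comparison_<timepoint>.csv`, one aeration-curve
#' plot per time point) and a JSON manifest (`manifest.json`) capturing the
#' package version, full configuration and produced files, sufficient to
#' reproduce the run.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the profile table, comparison tables and
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(out, "masks")
  dir.create(mask_dir, showWarnings = FALSE)

  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    cohort$seed <- config$seed
    meta <- generate_cohort(cohort, file.path(out, "volumes"))
  } else {
    if (!file.exists(config$metadata_csv))
      abort_data(sprintf("metadata CSV not found: %s", config$metadata_csv))
    meta <- readr::read_csv(config$metadata_csv, show_col_types = FALSE)
    need <- c("animal_id", "group", "timepoint", "path")
    if (!all(need %in% names(meta)))
      abort_data(sprintf("metadata CSV must contain columns: %s",
                         paste(need, collapse = ", ")))
    missing <- !file.exists(meta$path)
    if (any(missing))
      abort_data(sprintf("missing input volumes: %s",
                         paste(utils::head(meta$path[missing], 5), collapse = ", ")))
  }

  scheme <- make_bin_scheme(config$hu_lo, config$hu_hi, config$n_bins)
  profiles <- vector("list", nrow(meta))
  mask_paths <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    vol <- read_volume(meta$path[i], id = meta$animal_id[i])
    seg <- segment_volume(vol, config$params)
    mask_paths[i] <- file.path(
      mask_dir, sprintf("%s_%s_parenchyma.nii.gz",
                        meta$animal_id[i], meta$timepoint[i]))
    write_mask(seg$parenchyma, mask_paths[i])
    profiles[[i]] <- compute_profile(vol, seg$parenchyma, scheme,
                                     subject_id = meta$animal_id[i],
                                     group = meta$group[i],
                                     timepoint = meta$timepoint[i])
  }
  tbl <- profile_table(profiles)
  profile_path <- file.path(out, "profiles.csv")
  write_profile_csv(tbl, profile_path)

  comparisons <- list()
  comparison_paths <- character(0)
  plot_paths <- character(0)
  for (tp in unique(tbl$timepoint)) {
    res <- compare_groups(tbl, config$control, timepoint = tp,
                          design = config$design, alpha = config$alpha,
                          seed = config$seed)
    cp <- file.path(out, sprintf("comparison_%s.csv", tp))
    readr::write_csv(res, cp)
    comparisons[[tp]] <- res
    comparison_paths <- c(comparison_paths, cp)
    pp <- file.path(out, sprintf("aeration_%s.%s", tp, config$plot_format))
    save_plot(plot_aeration_curves(tbl, timepoint = tp), pp)
    plot_paths <- c(plot_paths, pp)
  }

  manifest <- list(
    package = "aerateCT",
    version = as.character(utils::packageVersion("aerateCT")),
    seed = config$seed,
    config = serialize_config(config),
    outputs = list(
      profiles = profile_path,
      comparisons = comparison_paths,
      plots = plot_paths,
      masks = mask_paths
    ),
    status = "complete"
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(profiles = tbl, comparisons = comparisons,
                 manifest = manifest_path))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  if (!is.null(cfg$cohort)) {
    cfg$cohort <- unclass(cfg$cohort)
    cfg$cohort$template <- unclass(cfg$cohort$template)
    cfg$cohort$groups <- lapply(cfg$cohort$groups, function(g) {
      g$f <- as.list(g$f); g
    })
  }
  cfg
}

#' Rebuild a run configuration from a manifest
#'
#' Re-running the returned configuration reproduces the original outputs
#' exactly (same seed, same parameters).
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir output directory for the re-run (defaults to the one in
#'   the manifest).
#' @return A [run_config()].
#' @export
config_from_manifest <- function(manifest_path, out_dir = NULL) {
  if (!file.exists(manifest_path))
    abort_data(sprintf("manifest not found: %s", manifest_path))
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  cohort <- NULL
  if (!is.null(cfg$cohort)) {
    f_df <- cfg$cohort$groups$f
    groups <- lapply(seq_len(nrow(cfg$cohort$groups)), function(i) {
      g <- cfg$cohort$groups[i, ]
      cohort_group(g$name, g$n,
                   stats::setNames(as.numeric(f_df[i, ]), names(f_df)))
    })
    tmpl <- cfg$cohort$template
    cohort <- cohort_spec(
      groups = groups,
      template = phantom_spec(
        shape = tmpl$shape, spacing = tmpl$spacing,
        body_semiaxes = tmpl$body_semiaxes, body_center = tmpl$body_center,
        lung_semiaxes = tmpl$lung_semiaxes, lung_offset = tmpl$lung_offset,
        airway_radius = tmpl$airway_radius, airway_length = tmpl$airway_length,
        mu0 = tmpl$mu0, sigma0 = tmpl$sigma0, f = tmpl$f,
        mu1 = tmpl$mu1, sigma1 = tmpl$sigma1,
        soft_tissue_hu = tmpl$soft_tissue_hu, air_hu = tmpl$air_hu,
        noise_sd = tmpl$noise_sd, hu_range = tmpl$hu_range,
        integer_hu = tmpl$integer_hu, seed = tmpl$seed
      ),
      f_sd = cfg$cohort$f_sd, mu0_jitter_sd = cfg$cohort$mu0_jitter_sd,
      profile_voxels = cfg$cohort$profile_voxels, seed = cfg$cohort$seed
    )
  }
  run_config(
    out_dir = out_dir %||% cfg$out_dir,
    cohort = cohort,
    metadata_csv = cfg$metadata_csv,
    params = do.call(segmentation_params, cfg$params),
    n_bins = cfg$n_bins, hu_lo = cfg$hu_lo, hu_hi = cfg$hu_hi,
    control = cfg$control, design = cfg$design, alpha = cfg$alpha,
    seed = cfg$seed, plot_format = cfg$plot_format
  )
}
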