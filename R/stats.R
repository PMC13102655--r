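#' Two-sample t-tests on aeration fractions
#'
#' `student_t_test()` is the unpaired two-tailed pooled-variance test
#' (df = n_a + n_b - 2); `welch_t_test()` uses the Welch-Satterthwaite
#' degrees of freedom and does not assume equal variances. Both tests are
#' two-sided. The degenerate case of two constant samples with equal means
#' is defined as t = 0, p = 1.
#'
#' @param a,b numeric vectors of per-animal fractions (%), each of length
#'   >= 2.
#' @return An object of class `aeration_test`: `statistic`, `df`,
#'   `p_value`, `adjusted_p` (NA here), `method`, `mean_diff` (mean(a) -
#'   mean(b)) and its standard error `se`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_t_test <- function(a, b) two_sample_t(a, b, pooled = FALSE)

#' @rdname welch_t_test
#' @export
student_t_test <- function(a, b) two_sample_t(a, b, pooled = TRUE)

two_sample_t <- function(a, b, pooled) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    abort_data("each sample needs n >= 2 for a t-test")
  if (anyNA(a) || anyNA(b) || !all(is.finite(c(a, b))))
    abort_data("samples must be finite")
  method <- if (pooled) "student" else "welch"
  md <- mean(a) - mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    df <- length(a) + length(b) - 2
    if (md == 0)
      return(new_test(0, df, 1, method, md, 0))
    return(new_test(sign(md) * Inf, df, 0, method, md, 0))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  new_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
           method, md, unname(ht$stderr))
}

new_test <- function(statistic, df, p, method, mean_diff, se,
                     adjusted_p = NA_real_) {
  structure(
    list(statistic = statistic, df = df, p_value = p,
         adjusted_p = adjusted_p, method = method,
         mean_diff = mean_diff, se = se),
    class = "aeration_test"
  )
}

#' @export
print.aeration_test <- function(x, ...) {
  cat(sprintf("<%s t-test> t = %.4f, df = %.2f, p = %.4g (diff %.3f +/- %.3f)\n",
              x$method, x$statistic, x$df, x$p_value, x$mean_diff, x$se))
  invisible(x)
}

#' F-ratio check for variance heterogeneity
#'
#' Drives the automatic Welch fallback: when the two-sided F test of the
#' sample variances rejects at `alpha`, group comparisons switch from the
#' pooled Student test to Welch. Symmetric in its arguments.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param alpha rejection level of the F test (default 0.05).
#' @return Logical: `TRUE` when variances are heterogeneous.
#' @export
variance_heterogeneity_check <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    abort_data("each sample needs n >= 2 for the variance check")
  if (stats::var(a) == 0 && stats::var(b) == 0) return(FALSE)
  if (xor(stats::var(a) == 0, stats::var(b) == 0)) return(TRUE)
  stats::var.test(a, b)$p.value < alpha
}

# Student unless the F check detects heterogeneity, then Welch.
t_test_auto <- function(a, b, alpha = 0.05) {
  if (variance_heterogeneity_check(a, b, alpha)) welch_t_test(a, b)
  else student_t_test(a, b)
}

#' Two-way fixed-effects ANOVA on a profile table
#'
#' Fits `fraction_pct ~ group * bin` (or without interaction) on the
#' profiles of a single time point, with the HU bin as a categorical
#' factor. Each animal contributes one fraction per bin.
#'
#' @param tbl profile table rows for one time point (see [profile_table()]).
#' @param include_interaction include the group x bin interaction (default
#'   TRUE; the interaction is precisely a shift of the aeration curve's
#'   shape between groups).
#' @param response name of the response column.
#' @return An object of class `anova_table`: a data frame with one row per
#'   effect (and residuals) holding df, sum of squares, mean square, F and
#'   p, plus attributes `residual_df` and `residual_ms`.
#' @export
two_way_anova <- function(tbl, include_interaction = TRUE,
                          response = "fraction_pct") {
  need <- c(response, "group", "bin_index")
  if (!all(need %in% names(tbl)))
    abort_usage(sprintf("profile table must contain: %s",
                        paste(need, collapse = ", ")))
  if ("timepoint" %in% names(tbl) &&
      length(unique(tbl$timepoint)) > 1)
    abort_usage("two_way_anova expects a single time point; filter first")
  d <- data.frame(
    y = tbl[[response]],
    group = factor(tbl$group),
    bin = factor(tbl$bin_index)
  )
  if (nlevels(d$group) < 2 || nlevels(d$bin) < 2)
    abort_data("need >= 2 levels for both treatment group and HU bin")
  if (any(table(d$group, d$bin) == 0))
    abort_data("empty group x bin cells")
  form <- if (include_interaction) y ~ group * bin else y ~ group + bin
  fit <- stats::aov(form, data = d)
  s <- summary(fit)[[1]]
  out <- data.frame(
    term = trimws(rownames(s)),
    df = s$Df,
    sum_sq = s[["Sum Sq"]],
    mean_sq = s[["Mean Sq"]],
    statistic = s[["F value"]],
    p_value = s[["Pr(>F)"]],
    row.names = NULL
  )
  rdf <- out$df[out$term == "Residuals"]
  if (length(rdf) != 1 || rdf < 1)
    abort_data("zero residual degrees of freedom")
  structure(out, class = c("anova_table", "data.frame"),
            residual_df = rdf,
            residual_ms = out$mean_sq[out$term == "Residuals"])
}

# --- Monte-Carlo Dunnett many-to-one adjustment -----------------------------

.dunnett_cache <- new.env(parent = emptyenv())

# Seeded sample of the null max-|t| statistic over k equicorrelated
# contrasts (pairwise correlation `correlation` >= 0) sharing one residual
# chi-square. correlation = 1/2 is the classical many-to-one structure of k
# treatments against one control with equal n; correlation = 0 gives
# independent contrasts. The RNG state of the caller is left untouched.
dunnett_null_max_t <- function(k, df, nsim = 1e5, seed = 1L,
                               correlation = 0.5) {
  if (correlation < 0 || correlation >= 1)
    abort_usage("correlation must be in [0, 1)")
  key <- paste(k, df, nsim, seed, correlation, sep = "|")
  if (!is.null(.dunnett_cache[[key]])) return(.dunnett_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  x0 <- stats::rnorm(nsim)
  z <- sqrt(correlation) * x0 +
    sqrt(1 - correlation) * matrix(stats::rnorm(nsim * k), nrow = nsim)
  denom <- sqrt(stats::rchisq(nsim, df) / df)
  maxt <- Reduce(pmax, asplit(abs(z), 2)) / denom
  .dunnett_cache[[key]] <- maxt
  maxt
}

#' Dunnett many-to-one adjusted p values by Monte Carlo
#'
#' Familywise-adjusted two-sided p values for `k` t statistics sharing one
#' residual degrees of freedom. The null distribution of the maximum |t|
#' over the k contrasts is sampled by seeded Monte Carlo under an
#' equicorrelation model; each adjusted p is the null probability that the
#' maximum exceeds the observed |t|, floored at the unadjusted p.
#'
#' The default `correlation = 0.5` is the classical many-to-one structure
#' (k treatment arms compared with one shared control sample of equal
#' size). For a family of per-bin contrasts - one treatment-vs-control
#' difference per HU bin - the contrasts do not share a control sample;
#' they are close to independent (mildly negatively correlated through the
#' closure of fractions to 100%), and `correlation = 0` is the
#' accurate-to-conservative choice used by [compare_groups()].
#'
#' @param t_stats numeric vector of observed t statistics (k >= 1).
#' @param df shared residual degrees of freedom (>= 1).
#' @param nsim Monte-Carlo sample size (default 1e5).
#' @param seed RNG seed for the null sample (results cached per
#'   (k, df, nsim, seed, correlation)).
#' @param correlation pairwise correlation of the contrasts in `[0, 1)`.
#' @return Numeric vector of adjusted p values, same length as `t_stats`.
#' @export
dunnett_adjust <- function(t_stats, df, nsim = 1e5, seed = 1L,
                           correlation = 0.5) {
  k <- length(t_stats)
  if (k < 1) abort_usage("need at least one comparison")
  if (df < 1) abort_usage("df must be >= 1")
  maxt <- dunnett_null_max_t(k, df, nsim, seed, correlation)
  p_un <- 2 * stats::pt(-abs(t_stats), df)
  p_mc <- vapply(abs(t_stats), function(t0) mean(maxt >= t0), numeric(1))
  pmin(1, pmax(p_mc, p_un))
}

#' Monte-Carlo Dunnett critical value
#'
#' @inheritParams dunnett_adjust
#' @param k number of comparisons against the control.
#' @param alpha familywise error level.
#' @return The two-sided critical |t| value.
#' @export
dunnett_critical <- function(k, df, alpha = 0.05, nsim = 1e5, seed = 1L,
                             correlation = 0.5) {
  unname(stats::quantile(dunnett_null_max_t(k, df, nsim, seed, correlation),
                         1 - alpha))
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Per-bin group comparisons against a control
#'
#' Compares each treatment group with the control group bin by bin at one
#' time point, reproducing the two analysis designs used for aeration
#' profiles:
#'
#' * `"per_bin_t"`: independent two-sample t-test per bin, Student pooled
#'   variance with automatic Welch fallback when the F-ratio check detects
#'   variance heterogeneity; p values unadjusted (the conventional
#'   two-compartment analysis).
#' * `"anova_dunnett"`: two-way ANOVA (group x bin, with interaction) on all
#'   inferential groups, then per-bin treatment-vs-control contrasts using
#'   the pooled residual mean square, jointly adjusted by the Monte-Carlo
#'   Dunnett procedure (the refined ten-bin analysis).
#'
#' Groups with a single animal are reported descriptively (means only, no
#' inference), matching the treatment of single-animal reference arms.
#'
#' @param profiles a profile table ([profile_table()]) or list of profiles.
#' @param control name of the control group.
#' @param timepoint time point to analyse; may be omitted when the table
#'   contains exactly one.
#' @param design `"anova_dunnett"` or `"per_bin_t"`.
#' @param alpha significance level used for the stars annotation.
#' @param seed,nsim_dunnett Monte-Carlo settings for the Dunnett null.
#' @param dunnett_correlation pairwise contrast correlation assumed by the
#'   Monte-Carlo Dunnett null. The per-bin contrasts of this family do not
#'   share a control sample across bins; they are near-independent (weakly
#'   negatively correlated through the closure of fractions to 100), so the
#'   default is 0. The classical many-to-one value 0.5 would understate the
#'   familywise error here.
#' @param include_interaction passed to [two_way_anova()].
#' @return A tibble with one row per treatment group and bin: group means,
#'   difference, t, df, `p_value`, `p_adj` (Dunnett design only), `stars`
#'   (on the adjusted p when present) and `method`.
#' @export
compare_groups <- function(profiles, control,
                           timepoint = NULL,
                           design = c("anova_dunnett", "per_bin_t"),
                           alpha = 0.05, seed = 1L, nsim_dunnett = 1e5,
                           dunnett_correlation = 0,
                           include_interaction = TRUE) {
  design <- match.arg(design)
  tbl <- if (inherits(profiles, "aeration_profile") || is.list(profiles) &&
             !is.data.frame(profiles)) profile_table(profiles) else profiles
  if (!is.data.frame(tbl) || nrow(tbl) == 0)
    abort_data("empty profile table")
  tps <- unique(tbl$timepoint)
  if (is.null(timepoint)) {
    if (length(tps) != 1)
      abort_usage("multiple time points present; specify `timepoint`")
    timepoint <- tps
  }
  tbl <- tbl[tbl$timepoint == timepoint, , drop = FALSE]
  if (nrow(tbl) == 0)
    abort_data(sprintf("no profiles at time point '%s'", timepoint))
  if (!control %in% tbl$group)
    abort_data(sprintf("control group '%s' not found", control))

  n_by_group <- tapply(tbl$subject_id, tbl$group,
                       function(s) length(unique(s)))
  if (n_by_group[[control]] < 2)
    abort_data("control group needs >= 2 animals for inference")
  treatments <- setdiff(names(n_by_group), control)
  inferential <- treatments[n_by_group[treatments] >= 2]
  descriptive <- treatments[n_by_group[treatments] < 2]

  bins <- sort(unique(tbl$bin_index))
  bin_meta <- unique(tbl[, c("bin_index", "bin_lo", "bin_hi", "bin_label")])
  bin_meta <- bin_meta[order(bin_meta$bin_index), ]
  values_of <- function(g, b) tbl$fraction_pct[tbl$group == g & tbl$bin_index == b]

  rows <- list()
  add_row <- function(g, b, mt, stat = NA_real_, df = NA_real_,
                      p = NA_real_, p_adj = NA_real_, se = NA_real_,
                      method = "descriptive") {
    mc <- mean(values_of(control, b))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      timepoint = timepoint, group = g, bin_index = b,
      n_control = unname(n_by_group[[control]]), n_treatment = unname(n_by_group[[g]]),
      mean_control = mc, mean_treatment = mt, diff = mt - mc, se = se,
      statistic = stat, df = df, p_value = p, p_adj = p_adj,
      stars = significance_stars(if (is.na(p_adj)) p else p_adj),
      method = method
    )
  }

  if (design == "per_bin_t") {
    for (g in inferential) for (b in bins) {
      a <- values_of(g, b); cc <- values_of(control, b)
      ht <- t_test_auto(cc, a, alpha = alpha)
      add_row(g, b, mean(a), stat = -ht$statistic, df = ht$df,
              p = ht$p_value, se = ht$se,
              method = paste0("per_bin_", ht$method))
    }
  } else if (length(inferential) > 0) {
    sub <- tbl[tbl$group %in% c(control, inferential), , drop = FALSE]
    av <- two_way_anova(sub, include_interaction = include_interaction)
    mse <- attr(av, "residual_ms")
    rdf <- attr(av, "residual_df")
    contrasts <- expand.grid(group = inferential, bin = bins,
                             stringsAsFactors = FALSE)
    tstat <- mapply(function(g, b) {
      mt <- mean(values_of(g, b)); mc <- mean(values_of(control, b))
      (mt - mc) / sqrt(mse * (1 / n_by_group[[g]] + 1 / n_by_group[[control]]))
    }, contrasts$group, contrasts$bin)
    p_adj <- dunnett_adjust(tstat, rdf, nsim = nsim_dunnett, seed = seed,
                            correlation = dunnett_correlation)
    for (i in seq_len(nrow(contrasts))) {
      g <- contrasts$group[i]; b <- contrasts$bin[i]
      se <- sqrt(mse * (1 / n_by_group[[g]] + 1 / n_by_group[[control]]))
      add_row(g, b, mean(values_of(g, b)), stat = tstat[i], df = rdf,
              p = 2 * stats::pt(-abs(tstat[i]), rdf), p_adj = p_adj[i],
              se = se, method = "anova_dunnett")
    }
  }
  for (g in descriptive) for (b in bins)
    add_row(g, b, mean(values_of(g, b)))

  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, bin_meta, by = "bin_index")
  dplyr::arrange(
    dplyr::select(out, "timepoint", "group", "bin_index", "bin_lo", "bin_hi",
                  dplyr::everything(), -"bin_label"),
    .data$group, .data$bin_index
  )
}
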