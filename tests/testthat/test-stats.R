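# Hand-coded two-sample t formulas: the independent oracle for the wrappers.
oracle_t <- function(a, b, pooled) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

test_that("t-tests match hand-evaluated formulas", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  for (fn in list(welch_t_test, student_t_test)) {
    r <- fn(a, b)
    expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-6)  # -1.224745
    expect_equal(r$df, 4, tolerance = 1e-6)
    expect_equal(r$p_value, oracle_t(a, b, TRUE)$p, tolerance = 1e-6)
    expect_equal(r$mean_diff, -1)
  }
  # unequal n and variance: each wrapper against its own formula
  set.seed(2)
  x <- rnorm(7, 0, 1); y <- rnorm(12, 0.5, 3)
  w <- welch_t_test(x, y); ow <- oracle_t(x, y, FALSE)
  expect_equal(w$statistic, ow$t, tolerance = 1e-10)
  expect_equal(w$df, ow$df, tolerance = 1e-10)
  expect_equal(w$p_value, ow$p, tolerance = 1e-10)
  s <- student_t_test(x, y); os <- oracle_t(x, y, TRUE)
  expect_equal(s$statistic, os$t, tolerance = 1e-10)
  expect_equal(s$p_value, os$p, tolerance = 1e-10)
})

test_that("t-test edge cases and invariances", {
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
  same <- c(4, 5, 6)
  r <- welch_t_test(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # two constant samples
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t_test(c(3, 3), c(2, 2))$p_value, 0)
  # scaling both samples leaves t and p unchanged; shifting moves the diff
  set.seed(3)
  a <- rnorm(6); b <- rnorm(8, 1)
  r1 <- welch_t_test(a, b); r2 <- welch_t_test(10 * a, 10 * b)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(student_t_test(a + 3, b)$mean_diff, r1$mean_diff + 3,
               tolerance = 1e-12)
  # equal n and equal variances: Welch equals Student exactly
  x <- c(1, 2, 6); y <- c(3, 4, 8)
  expect_equal(welch_t_test(x, y)$statistic, student_t_test(x, y)$statistic)
  expect_equal(welch_t_test(x, y)$df, student_t_test(x, y)$df)
})

test_that("variance heterogeneity check is an F test at alpha 0.05", {
  same <- c(1, 2, 3, 4)
  expect_false(variance_heterogeneity_check(same, same))
  set.seed(4)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 0, 10)  # variance ratio ~100
  expect_true(variance_heterogeneity_check(a, b))
  expect_identical(variance_heterogeneity_check(a, b),
                   variance_heterogeneity_check(b, a))
  # oracle: two-sided F probability computed from pf directly
  f <- var(a) / var(b)
  p_oracle <- 2 * min(pf(f, 9, 9), 1 - pf(f, 9, 9))
  expect_identical(variance_heterogeneity_check(a, b), p_oracle < 0.05)
})

test_that("two-way ANOVA matches brute-force sums of squares", {
  # balanced 2 groups x 2 bins x 3 animals with known cell means
  d <- expand.grid(animal = 1:3, group = c("g1", "g2"), bin_index = 1:2)
  cell_mean <- c(10, 14, 20, 18)  # g1b1, g2b1, g1b2, g2b2
  d$fraction_pct <- cell_mean[as.integer(interaction(d$group, d$bin_index))] +
    c(-1, 0, 1)[d$animal]
  d$subject_id <- paste0(d$group, d$animal)
  d$timepoint <- "day14"
  av <- two_way_anova(d)

  y <- d$fraction_pct
  gm <- mean(y)
  m_g <- tapply(y, d$group, mean); m_b <- tapply(y, d$bin_index, mean)
  m_gb <- tapply(y, interaction(d$group, d$bin_index), mean)
  ss_g <- 6 * sum((m_g - gm)^2)
  ss_b <- 6 * sum((m_b - gm)^2)
  ss_cells <- 3 * sum((m_gb - gm)^2)
  ss_int <- ss_cells - ss_g - ss_b
  ss_res <- sum((y - m_gb[interaction(d$group, d$bin_index)])^2)

  expect_equal(av$sum_sq[av$term == "group"], ss_g, tolerance = 1e-10)
  expect_equal(av$sum_sq[av$term == "bin"], ss_b, tolerance = 1e-10)
  expect_equal(av$sum_sq[av$term == "group:bin"], ss_int, tolerance = 1e-10)
  expect_equal(av$sum_sq[av$term == "Residuals"], ss_res, tolerance = 1e-10)
  expect_equal(sum(av$df), nrow(d) - 1)
})

test_that("ANOVA invariances on balanced data", {
  set.seed(6)
  d <- expand.grid(animal = 1:4, group = c("a", "b", "c"), bin_index = 1:5)
  d$subject_id <- paste0(d$group, d$animal)
  d$timepoint <- "t"
  d$fraction_pct <- rnorm(nrow(d), 10, 2)
  av <- two_way_anova(d)
  # full decomposition of the total sum of squares
  ss_total <- sum((d$fraction_pct - mean(d$fraction_pct))^2)
  expect_equal(sum(av$sum_sq), ss_total, tolerance = 1e-8 * ss_total)
  # translation invariance of all F statistics
  d2 <- d; d2$fraction_pct <- d$fraction_pct + 7
  av2 <- two_way_anova(d2)
  expect_equal(av$statistic[av$term != "Residuals"],
               av2$statistic[av2$term != "Residuals"], tolerance = 1e-8)
  # constant response: all effect F are 0
  d3 <- d; d3$fraction_pct <- 5
  av3 <- suppressWarnings(two_way_anova(d3))
  expect_true(all(av3$sum_sq < 1e-20))
})

test_that("Monte-Carlo Dunnett adjustment is calibrated against mvtnorm", {
  t_obs <- c(0.8, -1.7, 2.4, 3.2, -0.3)
  for (df in c(10, 30)) {
    p_adj <- dunnett_adjust(t_obs, df = df, nsim = 2e5, seed = 5)
    p_un <- 2 * pt(-abs(t_obs), df)
    expect_true(all(p_adj >= p_un))                 # monotone in the family
    expect_true(all(p_adj <= pmin(1, 5 * p_un) + 0.01))  # Bonferroni + MC slack
    corr <- matrix(0.5, 5, 5); diag(corr) <- 1
    p_exact <- vapply(abs(t_obs), function(t0)
      1 - mvtnorm::pmvt(lower = rep(-t0, 5), upper = rep(t0, 5),
                        df = df, corr = corr,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-4)),
      numeric(1))
    expect_equal(p_adj, pmax(p_exact, p_un), tolerance = 0.01)
  }
  # independent contrasts: the adjustment is Sidak up to Monte-Carlo error
  t_obs5 <- c(0.8, -1.7, 2.4, 3.2, -0.3)
  p0 <- dunnett_adjust(t_obs5, df = 30, nsim = 2e5, seed = 5, correlation = 0)
  p_un5 <- 2 * pt(-abs(t_obs5), 30)
  expect_equal(p0, 1 - (1 - p_un5)^5, tolerance = 0.01)
  # independence is more conservative than the shared-control structure
  expect_true(all(p0 >= dunnett_adjust(t_obs5, df = 30, nsim = 2e5, seed = 5,
                                       correlation = 0.5) - 0.01))
  # single comparison: adjustment is a no-op up to Monte-Carlo error
  p1 <- dunnett_adjust(2.1, df = 18, nsim = 2e5, seed = 2)
  expect_equal(p1, 2 * pt(-2.1, 18), tolerance = 0.005)
  expect_error(dunnett_adjust(numeric(0), df = 5), "at least one")
})

test_that("group comparison designs behave per design", {
  sp <- two_group_cohort(0.3, seed = 21)
  tbl <- simulate_cohort_profiles(sp)
  res <- compare_groups(tbl, "Sham", design = "anova_dunnett", seed = 1)
  expect_equal(nrow(res), 10)
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
  # strong densification must flag aerated-range bins (1-5) after adjustment
  expect_true(any(res$p_adj[res$bin_index <= 5] < 0.05))

  res_t <- compare_groups(tbl, "Sham", design = "per_bin_t")
  expect_true(all(is.na(res_t$p_adj)))
  expect_true(all(res_t$method %in% c("per_bin_student", "per_bin_welch")))

  # single-animal arms are descriptive only
  sp3 <- cohort_spec(
    groups = list(
      cohort_group("Sham", 5, c(day14 = 0)),
      cohort_group("BLM", 5, c(day14 = 0.2)),
      cohort_group("BLM+", 1, c(day14 = 0.6))
    ),
    seed = 3
  )
  tbl3 <- simulate_cohort_profiles(sp3)
  res3 <- compare_groups(tbl3, "Sham", design = "anova_dunnett")
  blmp <- res3[res3$group == "BLM+", ]
  expect_equal(nrow(blmp), 10)
  expect_true(all(is.na(blmp$p_value)))
  expect_true(all(blmp$method == "descriptive"))
  expect_true(all(is.finite(blmp$mean_treatment)))
  expect_error(compare_groups(tbl3, "NoSuchGroup"), "not found")
})
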