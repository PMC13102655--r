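test_that("equal-width bin schemes have exact edges", {
  s <- make_bin_scheme(-900, -100, 10)
  expect_identical(s$edges, seq(-900, -100, by = 80))
  expect_true(all(diff(s$edges) == 80))
  expect_identical(make_bin_scheme(-900, -100, 1)$edges, c(-900, -100))
  expect_identical(make_bin_scheme(0, 10, 5)$edges, c(0, 2, 4, 6, 8, 10))
  expect_error(make_bin_scheme(-100, -900, 10), "lo < hi")
  expect_error(make_bin_scheme(-900, -100, 0), "positive")
})

test_that("the two-compartment scheme splits the range at -500", {
  s <- two_compartment_scheme()
  expect_length(s$labels, 2)
  expect_identical(s$edges, c(-900, -500, -100))
  # a voxel at exactly -500 HU is poorly-aerated
  hv <- hu_as_volume(c(-600, -500, -499.5))
  p <- compute_profile(hv$vol, hv$mask, s)
  expect_identical(p$counts, c(1L, 2L))
})

test_that("profiles recover known HU distributions", {
  # uniform over the range: each of ten bins near 10%
  set.seed(42)
  hv <- hu_as_volume(runif(1e6, -900, -100))
  p <- compute_profile(hv$vol, hv$mask, ten_bin_scheme())
  expect_true(all(abs(p$fractions_pct - 10) < 0.3))

  # degenerate distribution lands in one bin
  hv1 <- hu_as_volume(rep(-850, 100))
  p1 <- compute_profile(hv1$vol, hv1$mask, ten_bin_scheme())
  expect_identical(p1$fractions_pct, c(100, rep(0, 9)))

  # truncated Gaussian matches the analytic normal-CDF bin masses
  spec <- tiny_phantom_spec(seed = 8, mu0 = -700, sigma0 = 60, f = 0)
  set.seed(7)
  n <- 2e5
  u <- runif(n, pnorm((-900 + 700) / 60), pnorm((-100 + 700) / 60))
  hv2 <- hu_as_volume(-700 + 60 * qnorm(u))
  p2 <- compute_profile(hv2$vol, hv2$mask, ten_bin_scheme())
  expect_true(all(abs(p2$fractions_pct - analytic_bin_fractions(spec)) < 0.35))
})

test_that("aggregation to a nested scheme is exact and identity-stable", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 11, f = 0.3, noise_sd = 6))
  par <- extract_parenchyma_mask(ph$volume, ph$lung_mask)
  p10 <- compute_profile(ph$volume, par, ten_bin_scheme())
  p2 <- aggregate_profile(p10, two_compartment_scheme())
  direct <- compute_profile(ph$volume, par, two_compartment_scheme())
  expect_identical(p2$counts, direct$counts)
  expect_equal(p2$total_volume_mm3, p10$total_volume_mm3)

  same <- aggregate_profile(p10, ten_bin_scheme())
  expect_identical(same$counts, p10$counts)

  shifted <- bin_scheme(c(-900, -490, -100))
  expect_error(aggregate_profile(p10, shifted), "not nested")
})

test_that("profile tables are long-format and round-trip through CSV", {
  profs <- lapply(1:3, function(i) {
    ph <- generate_phantom(tiny_phantom_spec(seed = 20 + i))
    par <- extract_parenchyma_mask(ph$volume, ph$lung_mask)
    compute_profile(ph$volume, par, ten_bin_scheme(),
                    subject_id = paste0("m", i), group = "Sham",
                    timepoint = "day0")
  })
  tbl <- profile_table(profs)
  expect_equal(nrow(tbl), 30)
  expect_equal(unique(table(tbl$subject_id)), 10L)

  empty <- profile_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("subject_id", "bin_index", "fraction_pct") %in% names(empty)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(tbl, path)
  back <- read_profile_csv(path)
  expect_equal(back$fraction_pct, tbl$fraction_pct, tolerance = 1e-12)

  mixed <- c(profs[1:2], list(aggregate_profile(profs[[3]], two_compartment_scheme())))
  expect_error(profile_table(mixed), "mix")
})

test_that("bin label maps agree voxelwise with profile counts", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 31, f = 0.4, noise_sd = 6))
  par <- extract_parenchyma_mask(ph$volume, ph$lung_mask)
  scheme <- ten_bin_scheme()
  lm <- render_bin_labelmap(ph$volume, par, scheme)
  p <- compute_profile(ph$volume, par, scheme)
  expect_true(all(lm %in% 0:10))
  expect_identical(tabulate(lm[lm > 0], 10), p$counts)
  expect_identical(sum(lm > 0), sum(par$data))

  hv <- hu_as_volume(rep(-850, 20))
  lm1 <- render_bin_labelmap(hv$vol, hv$mask, scheme)
  expect_true(all(lm1 == 1L))
})

test_that("profiles conserve mass and ignore voxel order", {
  for (i in 1:25) {
    spec <- random_tiny_spec(i)
    ph <- generate_phantom(spec)
    par <- extract_parenchyma_mask(ph$volume, ph$lung_mask)
    p <- compute_profile(ph$volume, par, ten_bin_scheme())
    expect_lt(abs(sum(p$fractions_pct) - 100), 1e-6)
    expect_lt(abs(sum(p$volumes_mm3) - mask_volume_mm3(par)), 1e-6)
  }
  # permutation invariance of the underlying binning
  set.seed(5)
  hu <- runif(5000, -900, -100)
  p_a <- compute_profile(hu_as_volume(hu)$vol, hu_as_volume(hu)$mask, ten_bin_scheme())
  hu_s <- sample(hu)
  p_b <- compute_profile(hu_as_volume(hu_s)$vol, hu_as_volume(hu_s)$mask, ten_bin_scheme())
  expect_identical(p_a$counts, p_b$counts)
})

test_that("a rightward HU shift never raises cumulative aeration fractions", {
  set.seed(13)
  hu <- pmin(-100, pmax(-900, rnorm(20000, -650, 120)))
  scheme <- ten_bin_scheme()
  base <- compute_profile(hu_as_volume(hu)$vol, hu_as_volume(hu)$mask, scheme)
  for (shift in c(10, 40, 120, 400)) {
    hu2 <- pmin(-100, hu + shift)
    p2 <- compute_profile(hu_as_volume(hu2)$vol, hu_as_volume(hu2)$mask, scheme)
    expect_true(all(cumsum(p2$fractions_pct) <= cumsum(base$fractions_pct) + 1e-9))
  }
})
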