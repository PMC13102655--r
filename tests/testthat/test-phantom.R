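test_that("phantom generation is seed-deterministic", {
  a <- generate_phantom(tiny_phantom_spec(seed = 12, noise_sd = 10))
  b <- generate_phantom(tiny_phantom_spec(seed = 12, noise_sd = 10))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$lung_mask$data, b$lung_mask$data)
  c <- generate_phantom(tiny_phantom_spec(seed = 13, noise_sd = 10))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("baseline lung HU follow the truncated normal law", {
  spec <- tiny_phantom_spec(seed = 14, f = 0, mu0 = -700, sigma0 = 100)
  ph <- generate_phantom(spec)
  hu <- ph$volume$data[ph$lung_mask$data]
  ptrunc <- function(q) {
    lo <- pnorm((-900 + 700) / 100); hi <- pnorm((-100 + 700) / 100)
    pmin(1, pmax(0, (pnorm((q + 700) / 100) - lo) / (hi - lo)))
  }
  ks <- suppressWarnings(ks.test(hu, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("analytic bin fractions integrate the mixture correctly", {
  spec <- tiny_phantom_spec(seed = 1, mu0 = -700, sigma0 = 60, f = 0)
  fr <- analytic_bin_fractions(spec)
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  # oracle: numerical integration of the truncated normal density per bin
  dens <- function(x) dnorm(x, -700, 60) /
    (pnorm((-100 + 700) / 60) - pnorm((-900 + 700) / 60))
  edges <- ten_bin_scheme()$edges
  fr_num <- vapply(1:10, function(i)
    100 * integrate(dens, edges[i], edges[i + 1], rel.tol = 1e-10)$value,
    numeric(1))
  expect_equal(fr, fr_num, tolerance = 1e-6)

  # symmetric mixture about the range midpoint gives symmetric fractions
  sym <- tiny_phantom_spec(seed = 1, mu0 = -500, sigma0 = 250, mu1 = -300, f = 0)
  fs <- analytic_bin_fractions(sym)
  expect_equal(fs, rev(fs), tolerance = 1e-9)

  # a single bin spanning the range holds everything
  expect_equal(analytic_bin_fractions(spec, make_bin_scheme(-900, -100, 1)), 100)
  expect_error(analytic_bin_fractions(spec, make_bin_scheme(-1000, -100, 9)),
               "outside")
})

test_that("full densification concentrates mass in poorly-aerated bins", {
  spec <- tiny_phantom_spec(seed = 15, f = 1, mu1 = -300, sigma1 = 60,
                            noise_sd = 0)
  ph <- generate_phantom(spec)
  par <- extract_parenchyma_mask(ph$volume, ph$lung_mask)
  p <- compute_profile(ph$volume, par, ten_bin_scheme())
  fr <- analytic_bin_fractions(spec)
  expect_gt(sum(p$fractions_pct[6:10]), 95)
  # only ~900 parenchyma voxels here; binomial noise allows a few points
  expect_true(all(abs(p$fractions_pct - fr) < 5))
})

test_that("measured fractions recover analytic ground truth at scale", {
  spec <- big_phantom_spec(seed = 16, f = 0.25)
  ph <- generate_phantom(spec)
  par <- extract_parenchyma_mask(ph$volume, ph$lung_mask)
  expect_gte(sum(par$data), 1e5)
  p <- compute_profile(ph$volume, par, ten_bin_scheme())
  expect_true(all(abs(p$fractions_pct - analytic_bin_fractions(spec)) < 1))
})

test_that("densification strictly erodes the well-aerated compartment", {
  fs <- seq(0, 1, by = 0.05)
  well <- vapply(fs, function(f)
    analytic_well_aerated_pct(tiny_phantom_spec(seed = 1, f = f)), numeric(1))
  expect_true(all(diff(well) < 0))
})

test_that("cohort generation writes one volume per animal and time point", {
  sp <- cohort_spec(
    groups = list(
      cohort_group("Sham", 3, c(day0 = 0, day14 = 0)),
      cohort_group("BLM", 2, c(day0 = 0, day14 = 0.3))
    ),
    template = tiny_phantom_spec(noise_sd = 5),
    seed = 8
  )
  out <- withr::local_tempdir()
  meta <- generate_cohort(sp, out)
  expect_equal(nrow(meta), 10)
  expect_true(all(file.exists(meta$path)))
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_equal(sum(meta$group == "Sham"), 6)
  # severity honors trajectory + clipping
  expect_true(all(meta$f_true >= 0 & meta$f_true <= 1))
  expect_true(all(meta$f_true[meta$group == "BLM" & meta$timepoint == "day14"] > 0.1))
  # volumes are readable and calibrated
  v <- read_volume(meta$path[1])
  expect_false(validate_hu_calibration(v)$no_air_reference)
})

test_that("histogram-level profiles are deterministic and conservative", {
  sp <- two_group_cohort(0.1, n_control = 4, n_treated = 4,
                         timepoints = c("day0", "day14"), seed = 31,
                         profile_voxels = 5000)
  t1 <- simulate_cohort_profiles(sp)
  t2 <- simulate_cohort_profiles(sp)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 8 * 2 * 10)
  sums <- tapply(t1$fraction_pct, paste(t1$subject_id, t1$timepoint), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # null group is exchangeable across time points: bin means stay close
  m_by_tp <- tapply(t1$fraction_pct[t1$group == "Sham"],
                    list(t1$bin_index[t1$group == "Sham"],
                         t1$timepoint[t1$group == "Sham"]), mean)
  expect_true(all(abs(m_by_tp[, 1] - m_by_tp[, 2]) < 3))
})

test_that("invalid phantom and cohort specs are rejected", {
  expect_error(phantom_spec(f = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(mu0 = -300, mu1 = -500), "mu1")
  expect_error(phantom_spec(lung_offset = 3), "inside the body")
  expect_error(cohort_spec(groups = list(
    cohort_group("A", 2, c(day0 = 0)),
    cohort_group("B", 2, c(day1 = 0))
  )), "same time points")
  expect_error(cohort_group("A", 2, c(day0 = 1.4)), "\\[0, 1\\]")
})
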