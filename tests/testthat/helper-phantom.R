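# Small phantom specs sized for fast tests.

tiny_phantom_spec <- function(seed = 1L, ...) {
  defaults <- list(
    shape = c(24, 24, 28),
    body_semiaxes = c(0.80, 0.75, 0.95),
    lung_semiaxes = c(0.26, 0.30, 0.50),
    lung_offset = 0.40,
    airway_radius = 0,
    noise_sd = 0,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# A spatial phantom spec with >= 1e5 parenchyma voxels, used for oracle
# recovery; noiseless so parenchyma equals the true lung mask.
big_phantom_spec <- function(seed = 1L, ...) {
  defaults <- list(
    shape = c(116, 116, 120),
    body_semiaxes = c(2.9, 3.0, 4.1),
    lung_semiaxes = c(1.3, 1.5, 2.6),
    lung_offset = 1.45,
    airway_radius = 0,
    noise_sd = 0,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# Randomised mixture parameters for property-style loops; deterministic in i.
random_tiny_spec <- function(i) {
  set.seed(1000 + i)
  mu0 <- runif(1, -780, -550)
  tiny_phantom_spec(
    seed = i,
    mu0 = mu0, sigma0 = runif(1, 40, 180),
    f = runif(1),
    mu1 = mu0 + runif(1, 50, 350), sigma1 = runif(1, 30, 120),
    noise_sd = runif(1, 0, 12)
  )
}

# Wrap a numeric vector as a one-voxel-thick ct_volume + full mask, for
# tests that exercise binning on explicit HU values.
hu_as_volume <- function(hu, spacing = c(1, 1, 1)) {
  geom <- voxel_geometry(spacing)
  vol <- ct_volume(array(hu, dim = c(length(hu), 1, 1)), geom)
  mask <- lung_mask(array(TRUE, dim = c(length(hu), 1, 1)), geom)
  list(vol = vol, mask = mask)
}

two_group_cohort <- function(f_treated, n_control = 9, n_treated = 11,
                             timepoints = "day14", seed = 1L, ...) {
  f_ctl <- stats::setNames(rep(0, length(timepoints)), timepoints)
  f_trt <- stats::setNames(rep(f_treated, length.out = length(timepoints)),
                           timepoints)
  cohort_spec(
    groups = list(
      cohort_group("Sham", n_control, f_ctl),
      cohort_group("BLM", n_treated, f_trt)
    ),
    seed = seed, ...
  )
}
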