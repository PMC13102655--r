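#' Specification of a synthetic thorax phantom
#'
#' Describes a rodent-thorax stand-in with analytically known ground truth:
#' a soft-tissue body ellipsoid in ambient air, two lung ellipsoids inside
#' the body, and an airway tube between them. Lung voxels draw HU from a
#' two-component mixture of truncated normals on `hu_range`:
#' `(1 - f) * N(mu0, sigma0) + f * N(mu1, sigma1)`, where `f` is the
#' densification fraction - the portion of parenchyma shifted toward the
#' denser component, emulating bleomycin-like early fibro-inflammatory
#' change. Densification is distributional, not spatially structured,
#' because the downstream analysis is histogram-based.
#'
#' @param shape integer length-3 grid size (voxels).
#' @param spacing voxel spacing in mm (default 0.072 isotropic).
#' @param body_semiaxes,body_center body ellipsoid semi-axes / centre, mm
#'   (centre relative to the grid centre).
#' @param lung_semiaxes semi-axes of each lung ellipsoid, mm.
#' @param lung_offset lateral displacement of each lung centre from the
#'   grid centre along x, mm (lungs sit at +/- this offset).
#' @param airway_radius,airway_length radius and length (mm) of the airway
#'   tube descending along z at the midline; 0 radius disables it.
#' @param mu0,sigma0 baseline (aerated) component mean / sd, HU.
#' @param f densification fraction in \[0, 1\].
#' @param mu1,sigma1 densified component mean / sd, HU; `mu1 > mu0`.
#' @param soft_tissue_hu,air_hu HU of body tissue and air.
#' @param noise_sd additive Gaussian noise sd, HU (applied to every voxel).
#' @param hu_range truncation range of the parenchymal mixture.
#' @param integer_hu round all HU to integers, mimicking integer exports.
#' @param seed RNG seed used by [generate_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(72, 72, 72),
                         spacing = rep(0.072, 3),
                         body_semiaxes = c(2.30, 2.20, 2.50),
                         body_center = c(0, 0, 0),
                         lung_semiaxes = c(0.75, 0.95, 1.60),
                         lung_offset = 1.15,
                         airway_radius = 0.22,
                         airway_length = 2.2,
                         mu0 = -700, sigma0 = 100,
                         f = 0,
                         mu1 = -560, sigma1 = 50,
                         soft_tissue_hu = 40, air_hu = -1000,
                         noise_sd = 10,
                         hu_range = c(-900, -100),
                         integer_hu = FALSE,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 4))
    abort_usage("shape must be 3 integers >= 4")
  if (f < 0 || f > 1) abort_usage("densification fraction f must be in [0, 1]")
  if (!(mu0 < mu1)) abort_usage("mu1 must exceed mu0 (densified component is denser)")
  if (sigma0 <= 0 || sigma1 <= 0 || noise_sd < 0)
    abort_usage("sigma0, sigma1 must be > 0 and noise_sd >= 0")
  if (length(hu_range) != 2 || hu_range[1] >= hu_range[2])
    abort_usage("hu_range must be an increasing pair")
  extent <- shape * spacing
  if (any(lung_offset + lung_semiaxes[1] > body_semiaxes[1],
          lung_semiaxes[2:3] > body_semiaxes[2:3]))
    abort_usage("lungs are not strictly inside the body ellipsoid")
  if (any(2 * body_semiaxes > extent))
    abort_usage("body ellipsoid does not fit inside the grid")
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         body_semiaxes = body_semiaxes, body_center = body_center,
         lung_semiaxes = lung_semiaxes, lung_offset = lung_offset,
         airway_radius = airway_radius, airway_length = airway_length,
         mu0 = mu0, sigma0 = sigma0, f = f, mu1 = mu1, sigma1 = sigma1,
         soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
         noise_sd = noise_sd, hu_range = as.numeric(hu_range),
         integer_hu = isTRUE(integer_hu), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# n draws from the truncated-normal mixture on [lo, hi].
rtrunc_mixture <- function(n, f, mu0, sigma0, mu1, sigma1, lo, hi) {
  comp <- stats::runif(n) < f
  mu <- ifelse(comp, mu1, mu0)
  sigma <- ifelse(comp, sigma1, sigma0)
  plo <- stats::pnorm((lo - mu) / sigma)
  phi <- stats::pnorm((hi - mu) / sigma)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, mu + sigma * stats::qnorm(u)))
}

#' Generate a synthetic thorax phantom
#'
#' Deterministic for a given `spec$seed`. The caller's RNG state is saved
#' and restored.
#'
#' @param spec a [phantom_spec()].
#' @return A list:
#'   \describe{
#'     \item{volume}{the [ct_volume()] (HU, with noise).}
#'     \item{body_mask,lung_mask}{ground-truth [lung_mask()]s.}
#'     \item{truth}{voxel counts per region, the mixture parameters and the
#'       spec itself.}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  dims <- spec$shape
  sp <- spec$spacing
  cx <- (dims - 1) / 2 * sp  # grid centre in mm
  x <- (seq_len(dims[1]) - 1) * sp[1] - cx[1] - spec$body_center[1]
  y <- (seq_len(dims[2]) - 1) * sp[2] - cx[2] - spec$body_center[2]
  z <- (seq_len(dims[3]) - 1) * sp[3] - cx[3] - spec$body_center[3]

  ell2 <- function(xc, semi) {
    # squared normalised distance field for an ellipsoid centred at xc (mm)
    q1 <- ((x - xc[1]) / semi[1])^2
    q2 <- ((y - xc[2]) / semi[2])^2
    q3 <- ((z - xc[3]) / semi[3])^2
    outer(outer(q1, q2, "+"), q3, "+")
  }
  body <- ell2(c(0, 0, 0), spec$body_semiaxes) <= 1
  lungL <- ell2(c(-spec$lung_offset, 0, 0), spec$lung_semiaxes) <= 1
  lungR <- ell2(c(+spec$lung_offset, 0, 0), spec$lung_semiaxes) <= 1
  lungs <- lungL | lungR
  if (!all(body[lungs]))
    abort_data("degenerate geometry: lung voxels fall outside the body")

  airway <- array(FALSE, dims)
  if (spec$airway_radius > 0) {
    r2 <- outer(x^2, y^2, "+")
    disc <- r2 <= spec$airway_radius^2
    zin <- z >= -spec$airway_length / 2 & z <= spec$airway_length / 2
    airway <- outer(disc, zin, "&") & body & !lungs
  }

  hu <- array(spec$air_hu, dims)
  hu[body] <- spec$soft_tissue_hu
  n_lung <- sum(lungs)
  hu[lungs] <- rtrunc_mixture(n_lung, spec$f, spec$mu0, spec$sigma0,
                              spec$mu1, spec$sigma1,
                              spec$hu_range[1], spec$hu_range[2])
  hu[airway] <- spec$air_hu
  if (spec$noise_sd > 0)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  if (spec$integer_hu) hu <- round(hu)

  geom <- voxel_geometry(sp)
  list(
    volume = ct_volume(hu, geom, id = sprintf("phantom_seed%d", spec$seed)),
    body_mask = lung_mask(body, geom),
    lung_mask = lung_mask(lungs, geom),
    truth = list(
      n_body = sum(body), n_lung = n_lung, n_airway = sum(airway),
      lung_volume_mm3 = n_lung * prod(sp),
      body_volume_mm3 = sum(body) * prod(sp),
      spec = spec
    )
  )
}

#' Analytic expected bin fractions of a phantom's parenchyma
#'
#' Expected percentage of parenchyma volume per bin under the phantom's
#' truncated-normal mixture, ignoring voxel noise: per component, normal CDF
#' differences at the bin edges renormalised by the truncation mass, mixed
#' with weights `(1 - f, f)`. Sums to 100.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a `bin_scheme` lying within `spec$hu_range`.
#' @return Numeric vector of expected fractions (%), one per bin.
#' @export
analytic_bin_fractions <- function(spec, scheme = ten_bin_scheme()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "bin_scheme"))
  lo <- spec$hu_range[1]; hi <- spec$hu_range[2]
  e <- scheme$edges
  if (e[1] < lo - 1e-9 || e[length(e)] > hi + 1e-9)
    abort_usage("scheme extends outside the phantom's HU range")
  comp_mass <- function(mu, sigma) {
    z <- stats::pnorm((e - mu) / sigma)
    trunc_mass <- stats::pnorm((hi - mu) / sigma) - stats::pnorm((lo - mu) / sigma)
    diff(z) / trunc_mass
  }
  m <- (1 - spec$f) * comp_mass(spec$mu0, spec$sigma0) +
    spec$f * comp_mass(spec$mu1, spec$sigma1)
  100 * m
}

#' Expected well-aerated fraction (%) under a phantom spec
#'
#' Convenience wrapper: the analytic mass below -500 HU.
#' @param spec a [phantom_spec()].
#' @return Scalar percentage.
#' @export
analytic_well_aerated_pct <- function(spec) {
  analytic_bin_fractions(spec, two_compartment_scheme())[1]
}
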