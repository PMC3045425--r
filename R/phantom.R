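#' Phantom and acquisition specification
#'
#' Geometry, resolution model and noise calibration for the digital head
#' phantom. The point spread function is the two-Gaussian mixture
#' \deqn{K = (1-\rho) G(\sigma_1) + \rho G(\sigma_2)}
#' with defaults \eqn{\sigma_1 = 0.9} mm, \eqn{\sigma_2 = 2.5} mm and
#' \eqn{\rho = 0.07} (an HRRT-class resolution model). Noise variance per
#' voxel is `noise_alpha * activity / (decay * duration)`, mimicking count
#' statistics in decay-corrected units (11C half-life 20.364 min).
#'
#' @param grid_shape voxel counts per axis (default 96^3 for desk-scale runs).
#' @param voxel_size isotropic voxel edge in mm (default 2; 1.22 mm optional).
#' @param carotid_diameters carotid diameters in mm, one pair each (default
#'   `c(8, 5)`).
#' @param psf list with `sigma1`, `sigma2` (mm) and mixture weight `rho` on
#'   the wide component.
#' @param noise_alpha unitless variance calibration (0 = noiseless).
#' @param isotope_half_life minutes.
#' @param frame_averaging `FALSE` = punctual sampling at frame midpoints
#'   (ideal temporal sampling); `TRUE` = average the curve over each frame
#'   (clinical-like peak flattening).
#' @param seed integer noise seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_size = 2,
                         carotid_diameters = c(8, 5),
                         psf = list(sigma1 = 0.9, sigma2 = 2.5, rho = 0.07),
                         noise_alpha = 0.02, isotope_half_life = 20.364,
                         frame_averaging = FALSE, seed = 1L) {
  assert_that(psf$sigma1 < psf$sigma2, "sigma1 must be < sigma2")
  assert_that(psf$rho >= 0 && psf$rho <= 1, "rho must lie in [0, 1]")
  assert_that(noise_alpha >= 0, "noise_alpha must be >= 0")
  assert_that(all(carotid_diameters > 0), "carotid diameters must be positive")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 carotid_diameters = carotid_diameters, psf = psf,
                 noise_alpha = noise_alpha, isotope_half_life = isotope_half_life,
                 frame_averaging = isTRUE(frame_averaging), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Discretized PSF kernel
#'
#' The two-Gaussian mixture kernel evaluated on the voxel grid out to a
#' radius of `4 * sigma2` and renormalized to sum exactly 1. With `rho = 0`
#' this is a single Gaussian of FWHM `2.355 * sigma1`.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_size kernel grid spacing in mm (defaults to the spec's).
#' @return a 3D array summing to 1.
#' @export
psf_kernel <- function(spec, voxel_size = spec$voxel_size) {
  p <- spec$psf
  assert_that(p$sigma1 > 0 && p$sigma2 > 0, "PSF sigmas must be positive")
  n <- ceiling(4 * p$sigma2 / voxel_size)
  x <- seq(-n, n) * voxel_size
  g3 <- function(sigma) {
    g <- exp(-x^2 / (2 * sigma^2))
    k <- outer(outer(g, g), g)
    k / sum(k)
  }
  k <- (1 - p$rho) * g3(p$sigma1) + p$rho * g3(p$sigma2)
  k / sum(k)
}

# apply the mixture PSF to one 3D frame; separable per Gaussian component,
# exactly equivalent to convolution with psf_kernel() (outer-product identity)
apply_psf <- function(vol, spec) {
  p <- spec$psf
  if (p$sigma1 <= 0 && (p$rho == 0 || p$sigma2 <= 0)) return(vol)
  radius <- 4 * p$sigma2
  narrow <- gauss_blur_3d(vol, p$sigma1, spec$voxel_size, radius)
  if (p$rho == 0) return(narrow)
  wide <- gauss_blur_3d(vol, p$sigma2, spec$voxel_size, radius)
  (1 - p$rho) * narrow + p$rho * wide
}

#' Procedural digital head phantom
#'
#' Builds a label volume containing a brain ellipsoid split into frontal,
#' temporal, parietal and occipital grey sectors around a white-matter core,
#' basal ganglia, a cerebellum, a scalp shell, neck soft tissue, air, and two
#' pairs of vertical carotid cylinders (defaults 8 mm and 5 mm diameter)
#' entering below the brain near the temporal sectors.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_map()]; region names follow [tracer_template()] regions
#'   plus `carotid_8mm` / `carotid_5mm` (suffix = diameter).
#' @export
build_head_phantom <- function(spec) {
  d <- spec$grid_shape
  vx <- spec$voxel_size
  ext <- d * vx
  # voxel-center coordinates in mm, x/y centered, z from 0
  cx <- (seq_len(d[1]) - 0.5) * vx - ext[1] / 2
  cy <- (seq_len(d[2]) - 0.5) * vx - ext[2] / 2
  cz <- (seq_len(d[3]) - 0.5) * vx
  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)

  zc <- 0.62 * ext[3]                      # brain centre height
  br <- c(0.34, 0.42, 0.28) * min(ext)     # brain ellipsoid radii (mm)
  inside <- function(ctr, radii) {
    ((X - ctr[1]) / radii[1])^2 + ((Y - ctr[2]) / radii[2])^2 +
      ((Z - ctr[3]) / radii[3])^2 <= 1
  }
  brain <- inside(c(0, 0, zc), br)
  white <- inside(c(0, 0, zc), br * 0.62)
  bg    <- inside(c(0, 8, zc - 5), c(20, 24, 16))
  cereb <- inside(c(0, -0.30 * ext[2], zc - 0.24 * ext[3]), c(34, 26, 20))
  scalp <- inside(c(0, 0, zc), br * 1.16) & !inside(c(0, 0, zc), br * 1.08)

  labels <- array(0L, dim = d)
  grey <- brain & !white & !bg
  frontal  <- grey & (Y >= abs(X))
  occip    <- grey & (Y <= -abs(X))
  lateral  <- grey & !frontal & !occip
  temporal <- lateral & (Z < zc)
  parietal <- lateral & (Z >= zc)

  ids <- c(frontal_grey = 1L, temporal_grey = 2L, parietal_grey = 3L,
           occipital_grey = 4L, white_matter = 5L, basal_ganglia = 6L,
           cerebellum = 7L, scalp = 8L, soft_tissue = 9L)
  labels[frontal] <- ids[["frontal_grey"]]
  labels[temporal] <- ids[["temporal_grey"]]
  labels[parietal] <- ids[["parietal_grey"]]
  labels[occip] <- ids[["occipital_grey"]]
  labels[white & brain] <- ids[["white_matter"]]
  labels[bg & brain] <- ids[["basal_ganglia"]]
  labels[cereb] <- ids[["cerebellum"]]
  labels[scalp & labels == 0L] <- ids[["scalp"]]

  # neck soft tissue below the brain
  neck <- (Z < zc - 0.5 * br[3]) & (X^2 / (0.30 * ext[1])^2 +
                                      Y^2 / (0.30 * ext[2])^2 <= 1) & labels == 0L
  labels[neck] <- ids[["soft_tissue"]]

  # carotid cylinders: vertical, below/entering the brain near the temporal
  # sectors; one left/right pair per requested diameter
  nm <- stats::setNames(names(ids), as.character(ids))
  next_id <- max(ids) + 1L
  z_top <- zc - 0.35 * br[3]
  y_off <- c(6, -14, 22, -30)              # anterior/posterior separation
  for (i in seq_along(spec$carotid_diameters)) {
    dia <- spec$carotid_diameters[i]
    r <- dia / 2
    assert_that(r + 20 < ext[1] / 2, "carotid does not fit in the grid")
    cyl <- ((abs(X) - 18)^2 + (Y - y_off[i])^2 <= r^2) & (Z <= z_top)
    assert_that(any(cyl), "carotid does not fit in the grid")
    labels[cyl] <- next_id
    nm[as.character(next_id)] <- sprintf("carotid_%gmm", dia)
    next_id <- next_id + 1L
  }
  label_map(labels, nm)
}
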