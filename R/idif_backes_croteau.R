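#' Backes' model-inversion IDIF
#'
#' Models the measured carotid-ROI signal as
#' \deqn{C_{carotid}(t) = a_v C_{wb}(t) + (1-a_v)\,k \int_0^t C_{wb}(\tau)\,d\tau}
#' where `a_v` is the fractional vessel volume in the ROI and `k` the
#' vessel-to-tissue transport constant, and inverts it for the whole-blood
#' curve by forward substitution on the trapezoid-discretized Volterra
#' equation.
#'
#' @param image a [dynamic_image()].
#' @param square_mask logical 3D mask from [square_carotid_rois()].
#' @param params named vector/list with `a_v` in (0, 1] and `k` (min^-1).
#' @return list with `input` (provenance `backes`) and `params`
#'   (a `backes_params` object).
#' @export
backes_idif <- function(image, square_mask, params) {
  a_v <- params[["a_v"]]; k <- params[["k"]]
  assert_that(!is.null(a_v) && a_v > 0 && a_v <= 1, "a_v must lie in (0, 1]")
  assert_that(!is.null(k) && k >= 0, "k must be >= 0")
  tac_t <- image$schedule$mid
  c_car <- mask_tac(image, square_mask)
  wb <- invert_backes(tac_t, c_car, a_v, k)
  list(input = input_function(tac_t, pmax(wb, 0), provenance = "backes"),
       params = structure(list(a_v = a_v, k = k), class = "backes_params"))
}

# forward substitution on C(t_i) = a_v w_i + (1-a_v) k I_i with trapezoid I;
# the curve is taken to start from w(0) = 0 at t = 0
invert_backes <- function(times, c_meas, a_v, k) {
  tt <- c(0, times)
  cc <- c(0, c_meas)
  n <- length(tt)
  w <- numeric(n)
  I <- 0
  b <- (1 - a_v) * k
  for (i in 2:n) {
    dt <- tt[i] - tt[i - 1]
    w[i] <- (cc[i] - b * (I + dt / 2 * w[i - 1])) / (a_v + b * dt / 2)
    I <- I + dt / 2 * (w[i - 1] + w[i])
  }
  w[-1]
}

# forward model used for calibration tests and the grid search oracle
forward_backes <- function(times, wb, a_v, k) {
  tt <- c(0, times)
  ww <- c(0, wb)
  a_v * ww[-1] + (1 - a_v) * k * cum_trapz(tt, ww)[-1]
}

#' Recovery-coefficient table for cylindrical vessels
#'
#' For each diameter from 3 to 8 mm in 0.1 mm steps, rasterizes a uniform
#' unit-activity cylinder on the voxel grid (fractional-occupancy
#' anti-aliasing), convolves it with the two-Gaussian PSF, and records the
#' mean of the four hottest pixels in the central plane as the recovery
#' coefficient rc(d). rc is non-decreasing in diameter and approaches 1 for
#' diameters far above the PSF FWHM.
#'
#' @param spec a [phantom_spec()] (PSF and voxel size are used).
#' @param diameters mm (default `seq(3, 8, by = 0.1)`).
#' @param n_hottest pixels averaged (default 4).
#' @return a `recovery_table` tibble with `diameter` and `rc`.
#' @export
build_recovery_table <- function(spec, diameters = seq(3, 8, by = 0.1),
                                 n_hottest = 4) {
  rc <- vapply(diameters, function(d) cylinder_rc(spec, d, n_hottest), numeric(1))
  out <- tibble(diameter = diameters, rc = rc)
  class(out) <- c("recovery_table", class(out))
  out
}

cylinder_rc <- function(spec, diameter, n_hottest = 4, subsample = 5) {
  vx <- spec$voxel_size
  r <- diameter / 2
  margin <- 4 * spec$psf$sigma2 + vx
  nxy <- 2 * ceiling((r + margin) / vx) + 1
  nz <- 2 * ceiling(margin / vx) + 3
  off <- seq(-(subsample - 1) / 2, (subsample - 1) / 2) / subsample * vx
  centers <- (seq_len(nxy) - (nxy + 1) / 2) * vx
  # fractional in-circle occupancy of each xy cell
  occ <- matrix(0, nxy, nxy)
  for (dx in off) for (dy in off) {
    occ <- occ + outer(centers + dx, centers + dy,
                       function(x, y) as.numeric(x^2 + y^2 <= r^2))
  }
  occ <- occ / subsample^2
  vol <- array(rep(occ, nz), dim = c(nxy, nxy, nz))
  blurred <- apply_psf(vol, modifyList(spec, list(voxel_size = vx)))
  mid <- blurred[, , (nz + 1) / 2]
  mean(sort(as.vector(mid), decreasing = TRUE)[seq_len(n_hottest)])
}

#' Croteau's recovery-coefficient IDIF
#'
#' Averages the four hottest carotid pixels over three adjacent planes
#' (the hottest run of planes in the early summed image), fits the curve
#' with [fit_triexponential()], and divides the fitted curve by the recovery
#' coefficient interpolated from `recovery_table` at the known carotid
#' diameter. Partial volume only — no spill-in correction.
#'
#' @inheritParams chen_idif
#' @param carotid_diameter_mm measured carotid diameter (3-8 mm).
#' @param recovery_table a [build_recovery_table()] result.
#' @param n_planes adjacent planes used (default 3).
#' @return list with `input` (provenance `croteau`), `rc`, and the
#'   `triexp_fit`.
#' @export
croteau_idif <- function(image, rois, carotid_diameter_mm, recovery_table,
                         n_planes = 3) {
  assert_that(carotid_diameter_mm >= min(recovery_table$diameter) &&
                carotid_diameter_mm <= max(recovery_table$diameter),
              "carotid diameter outside the recovery table range",
              "petidif_range_error")
  summed <- early_summed(image)
  planes <- sort(unique(which(rois$carotid_mask, arr.ind = TRUE)[, 3]))
  # hottest run of n_planes adjacent planes within the carotid mask
  plane_heat <- vapply(planes, function(z) {
    m <- rois$carotid_mask[, , z]
    sum(summed[, , z][m])
  }, numeric(1))
  runs <- which(diff(planes, lag = n_planes - 1) == n_planes - 1)
  assert_that(length(runs) > 0, "fewer than n_planes adjacent carotid planes",
              "petidif_detection_error")
  run_heat <- vapply(runs, function(i) sum(plane_heat[i:(i + n_planes - 1)]),
                     numeric(1))
  best <- runs[which.max(run_heat)]
  use_planes <- planes[best:(best + n_planes - 1)]
  tac_t <- image$schedule$mid
  raw <- hottest_pixels_curve(image, rois$carotid_mask, 4, planes = use_planes)
  fit <- fit_triexponential(tac_t, raw)
  rc <- approx(recovery_table$diameter, recovery_table$rc,
               xout = carotid_diameter_mm)$y
  list(input = input_function(tac_t, pmax(fit$fitted / rc, 0),
                              provenance = "croteau"),
       rc = rc, triexp = fit, planes = use_planes)
}

#' Grid calibration of a method parameter against the arterial AUC
#'
#' Runs an IDIF method once per candidate parameter set, computes the
#' image/arterial whole-blood AUC ratio over 0-90 min, and returns the
#' candidate whose ratio is closest to 1 (ties resolved toward the earlier
#' candidate). Default grids: Su truncations 10..90 min by 10; Backes
#' `a_v` in {0.3, 0.4, 0.5} crossed with `k` in {5e-1, 5e-2, 5e-3, 5e-4}.
#'
#' @param candidates list of candidate parameter values (a scalar truncation
#'   for `su`; a named list/vector with `a_v`, `k` for `backes`).
#' @param image a [dynamic_image()].
#' @param rois a `carotid_roi_set` (for `su`) or square mask (for `backes`).
#' @param reference_input arterial truth [input_function()] (whole blood).
#' @param method `"su"` or `"backes"`.
#' @param t_end AUC horizon in minutes (default 90).
#' @return list: `candidate` (chosen), `index`, `ratios` (all AUC ratios).
#' @export
calibrate_parameter_grid <- function(candidates, image, rois, reference_input,
                                     method = c("su", "backes"), t_end = 90) {
  method <- match.arg(method)
  assert_that(length(candidates) > 0, "no candidates")
  ratios <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    res <- tryCatch({
      out <- switch(method,
        su = su_idif(image, rois, truncation_min = candidates[[i]]),
        backes = backes_idif(image, rois, candidates[[i]]))
      auc_ratio(out$input, reference_input, t_end)
    }, error = function(e) NA_real_)
    ratios[i] <- res
  }
  assert_that(any(is.finite(ratios)), "all candidates failed",
              "petidif_calibration_error")
  idx <- which.min(abs(ratios - 1))
  list(candidate = candidates[[idx]], index = idx, ratios = ratios)
}

#' Default Backes calibration grid
#' @return list of `c(a_v, k)` pairs in the printed order.
#' @export
backes_grid <- function() {
  g <- expand.grid(k = c(5e-1, 5e-2, 5e-3, 5e-4), a_v = c(0.3, 0.4, 0.5))
  purrr::map(seq_len(nrow(g)), function(i) c(a_v = g$a_v[i], k = g$k[i]))
}
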