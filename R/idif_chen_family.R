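# Shared least-squares machinery for the carotid signal model
#   C_carotid(t) = RC * C_blood(t) + SP * C_surround(t)
# fit over a set of calibration points; used by the Chen, Su and Parker
# methods (the latter two substitute pseudo-blood curves for sampled blood).
fit_rc_sp <- function(c_carotid, c_blood, c_surround) {
  X <- cbind(RC = c_blood, SP = c_surround)
  qrx <- qr(X)
  assert_that(qrx$rank == 2,
              "singular calibration design (blood and surround proportional)",
              "petidif_calibration_error")
  # SP is a spill-in percentage and cannot be negative; the constrained
  # solution also keeps the fit off the collinear ridge that an unconstrained
  # solve can wander onto when the surround curve nearly parallels the tail
  beta <- nnls_small(X, c_carotid)
  assert_that(is.finite(beta[1]) && beta[1] > 0,
              "calibration produced a non-positive recovery coefficient",
              "petidif_calibration_error")
  list(RC = unname(beta[1]), SP = unname(beta[2]))
}

chen_fit_obj <- function(RC, SP, calibration_times) {
  structure(list(RC = RC, SP = SP, calibration_times = calibration_times),
            class = "chen_fit")
}

#' Chen's blood-calibrated IDIF
#'
#' Models the carotid ROI signal as `RC * C_wb + SP * C_surround`, estimates
#' the recovery coefficient RC and spill-in fraction SP by linear least
#' squares at four late calibration times against sampled arterial whole
#' blood, and recovers the whole-blood curve as
#' `(C_carotid - SP * C_surround) / RC` on the frame grid.
#'
#' @param image a [dynamic_image()].
#' @param rois a `carotid_roi_set` from [auto_carotid_rois()].
#' @param blood a [blood_series()] covering the calibration times.
#' @param mode tracer class selecting the calibration times: 6/20/60/90 min
#'   for `rolipram_like`, 4/20/60/90 min for `pbr28_like`; or pass
#'   `calibration_times` directly.
#' @param calibration_times optional explicit times (minutes).
#' @return list with `input` (an [input_function()], provenance `chen`) and
#'   `fit` (a `chen_fit` with `RC`, `SP`).
#' @export
chen_idif <- function(image, rois, blood,
                      mode = c("rolipram_like", "pbr28_like"),
                      calibration_times = NULL) {
  if (is.null(calibration_times)) {
    mode <- match.arg(mode)
    calibration_times <- if (mode == "rolipram_like") c(6, 20, 60, 90) else c(4, 20, 60, 90)
  }
  tac_t <- image$schedule$mid
  c_car <- mask_tac(image, rois$carotid_mask)
  c_sur <- mask_tac(image, rois$background_mask)
  # the frame is the measurement: snap each calibration time to the frame
  # containing it and compare frame values with blood interpolated at the
  # frame midpoint, rather than interpolating the coarse image TAC
  cal_fr <- vapply(calibration_times, function(tc) {
    inside <- which(image$schedule$start <= tc + 1e-9 &
                      tc < image$schedule$end + 1e-9)
    if (length(inside) > 0) inside[1] else which.min(abs(tac_t - tc))
  }, integer(1))
  fit <- fit_rc_sp(c_car[cal_fr],
                   interpolate_curve(blood$time, blood$whole_blood, tac_t[cal_fr]),
                   c_sur[cal_fr])
  recovered <- pmax((c_car - fit$SP * c_sur) / fit$RC, 0)
  list(input = input_function(tac_t, recovered, provenance = "chen"),
       fit = chen_fit_obj(fit$RC, fit$SP, calibration_times))
}

#' Su's pseudo-blood IDIF
#'
#' Blood-free variant of the Chen model: the sampled whole blood is replaced
#' by the frame-wise hottest carotid voxel (re-selected every frame), and
#' RC/SP are fit over all frames whose midpoints fall within the truncation
#' window (default 20 min for the low-metabolite mode, 40 min for the
#' high-metabolite mode).
#'
#' @inheritParams chen_idif
#' @param truncation_min use frames with midpoints up to this time.
#' @return list with `input` (provenance `su`), `fit` (`chen_fit`), and
#'   `pseudo_blood` (the hottest-voxel curve).
#' @export
su_idif <- function(image, rois, truncation_min = NULL,
                    mode = c("rolipram_like", "pbr28_like")) {
  if (is.null(truncation_min)) {
    mode <- match.arg(mode)
    truncation_min <- if (mode == "rolipram_like") 20 else 40
  }
  tac_t <- image$schedule$mid
  assert_that(truncation_min <= max(image$schedule$end) + 1e-9,
              "truncation beyond the scan span")
  idx <- which(rois$carotid_mask)
  nvox <- prod(dim(image$voxels)[1:3])
  h <- vapply(seq_along(tac_t), function(fr) {
    max(image$voxels[idx + (fr - 1) * nvox])
  }, numeric(1))
  c_car <- mask_tac(image, rois$carotid_mask)
  c_sur <- mask_tac(image, rois$background_mask)
  use <- tac_t <= truncation_min + 1e-9
  fit <- fit_rc_sp(c_car[use], h[use], c_sur[use])
  recovered <- pmax((c_car - fit$SP * c_sur) / fit$RC, 0)
  list(input = input_function(tac_t, recovered, provenance = "su"),
       fit = chen_fit_obj(fit$RC, fit$SP, tac_t[use]), pseudo_blood = h)
}

#' Parker's hottest-5% IDIF
#'
#' Pseudo-blood curve `I_max` = per-frame mean of the hottest 5 percent of
#' carotid-ROI voxels. For frames where the background mean `T_mean` exceeds
#' the carotid mean `I_mean`, `I_max` is corrected to
#' `I_max * I_mean / T_mean`. The corrected curve then substitutes blood in
#' the Chen least squares over the same early-frame window as Su's method.
#'
#' @inheritParams su_idif
#' @param hottest_fraction fraction of carotid voxels averaged (default 0.05).
#' @return list with `input` (provenance `parker`), `fit`, and a
#'   `parker_fit` element with `imax_curve`, `imean_curve`, `tmean_curve`,
#'   `corrected_frames`.
#' @export
parker_idif <- function(image, rois, truncation_min = NULL,
                        mode = c("rolipram_like", "pbr28_like"),
                        hottest_fraction = 0.05) {
  if (is.null(truncation_min)) {
    mode <- match.arg(mode)
    truncation_min <- if (mode == "rolipram_like") 20 else 40
  }
  tac_t <- image$schedule$mid
  idx <- which(rois$carotid_mask)
  nvox <- prod(dim(image$voxels)[1:3])
  n_top <- max(1L, ceiling(hottest_fraction * length(idx)))
  imax <- vapply(seq_along(tac_t), function(fr) {
    v <- image$voxels[idx + (fr - 1) * nvox]
    mean(sort(v, decreasing = TRUE)[seq_len(n_top)])
  }, numeric(1))
  imean <- mask_tac(image, rois$carotid_mask)
  tmean <- mask_tac(image, rois$background_mask)
  corrected <- which(tmean > imean)
  imax_corr <- imax
  imax_corr[corrected] <- imax[corrected] * imean[corrected] / tmean[corrected]
  use <- tac_t <= truncation_min + 1e-9
  fit <- fit_rc_sp(imean[use], imax_corr[use], tmean[use])
  recovered <- pmax((imean - fit$SP * tmean) / fit$RC, 0)
  list(input = input_function(tac_t, recovered, provenance = "parker"),
       fit = chen_fit_obj(fit$RC, fit$SP, tac_t[use]),
       parker_fit = structure(list(imax_curve = imax_corr, imean_curve = imean,
                                   tmean_curve = tmean,
                                   corrected_frames = corrected),
                              class = "parker_fit"))
}
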