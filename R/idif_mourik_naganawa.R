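#' Mourik's hottest-pixels IDIF
#'
#' Averages the four hottest carotid pixels per plane (cluster fixed on the
#' early summed image), fits the curve with [fit_triexponential()], and
#' scales the fitted curve by the mean ratio of arterial whole-blood samples
#' at 20, 60 and 90 minutes to the fitted values at those times.
#'
#' @inheritParams chen_idif
#' @param scaling_times minutes (default `c(20, 60, 90)`).
#' @param n_per_plane hottest pixels per plane (default 4).
#' @return list with `input` (provenance `mourik`), `scale`, and the
#'   `triexp_fit`.
#' @export
mourik_idif <- function(image, rois, blood, scaling_times = c(20, 60, 90),
                        n_per_plane = 4) {
  tac_t <- image$schedule$mid
  raw <- hottest_pixels_curve(image, rois$carotid_mask, n_per_plane)
  fit <- fit_triexponential(tac_t, raw)
  at_scale <- fit$predict(scaling_times)
  assert_that(all(at_scale > 0),
              "fitted curve non-positive at a scaling time",
              "petidif_scaling_error")
  wb <- interpolate_curve(blood$time, blood$whole_blood, scaling_times)
  scale <- mean(wb / at_scale)
  list(input = input_function(tac_t, pmax(scale * fit$fitted, 0),
                              provenance = "mourik"),
       scale = scale, triexp = fit)
}

# Symmetric FastICA on pre-whitened data Z (comp x samples) with the
# kurtosis (cubic) contrast, which favors the spiky super-Gaussian bolus
# component over smoother tissue courses on the short frame axis.
# Returns the unmixing matrix W (rows orthonormal).
fastica_symmetric <- function(Z, seed, max_iter = 500, tol = 1e-9) {
  p <- nrow(Z); n <- ncol(Z)
  set.seed(seed)
  W <- matrix(rnorm(p * p), p, p)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    W_new <- sym_decorrelate((WX^3 %*% t(Z)) / n - 3 * W)
    done <- max(abs(abs(rowSums(W_new * W)) - 1)) < tol
    W <- W_new
    if (done) break
  }
  W
}

#' Naganawa's ICA-based IDIF
#'
#' Crops the image to a head bounding box, smooths every frame with a 6 mm
#' FWHM Gaussian, reduces the voxel-by-frame matrix to `n_components`
#' principal components, and unmixes them with a seeded symmetric FastICA.
#' The blood component is the one peaking earliest (within the first 5 min)
#' with the most positive skewness, sign-rectified. Its spatial weights
#' (positive part) define a weighted-average curve in activity units, which
#' is then scaled with the Mourik three-sample rule.
#'
#' @param image a [dynamic_image()].
#' @param blood a [blood_series()] (for the 20/60/90-min scaling).
#' @param n_components number of independent components (default 3).
#' @param seed integer seed for the ICA initialization.
#' @param scaling_times minutes (default `c(20, 60, 90)`).
#' @return list with `input` (provenance `naganawa`), `components` (frames x
#'   n_components matrix of temporal courses), `selected` (index).
#' @export
naganawa_idif <- function(image, blood, n_components = 3, seed = 1L,
                          scaling_times = c(20, 60, 90)) {
  tac_t <- image$schedule$mid
  nf <- length(tac_t)
  n_components <- min(n_components, nf - 1L)
  # head bounding box from the time-summed image
  total <- array(0, dim = dim(image$voxels)[1:3])
  for (fr in seq_len(nf)) total <- total + image$voxels[, , , fr]
  thr <- 0.05 * max(total)
  inbox <- which(total > thr, arr.ind = TRUE)
  rng <- apply(inbox, 2, range)
  fwhm_sigma <- 6 / (2 * sqrt(2 * log(2)))
  sub <- lapply(seq_len(nf), function(fr) {
    v <- gauss_blur_3d(image$voxels[, , , fr], fwhm_sigma, image$voxel_size[1])
    v[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3]]
  })
  X <- vapply(sub, as.vector, numeric(length(sub[[1]])))  # voxels x frames
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = n_components)
  keep <- seq_len(n_components)
  Z <- t(sv$v[, keep, drop = FALSE]) * sqrt(nrow(X))      # comp x frames, white
  W <- fastica_symmetric(Z, seed = seed)
  S <- W %*% Z                                            # temporal sources
  comps <- t(S)                                           # frames x comp
  # rectify sign so each component's extreme excursion is positive
  for (j in seq_len(ncol(comps))) {
    if (abs(min(comps[, j])) > abs(max(comps[, j]))) comps[, j] <- -comps[, j]
  }
  peak_t <- tac_t[apply(comps, 2, which.max)]
  cand <- which(peak_t <= 5)
  assert_that(length(cand) > 0, "no component peaking within the first 5 min",
              "petidif_extraction_error")
  # among early-peaking components, the blood curve is the most positively
  # skewed (sharp bolus peak over a low tail)
  skews <- apply(comps[, cand, drop = FALSE], 2, skewness)
  sel <- cand[which.max(skews)]
  # back-project: positive spatial weights of the selected source give a
  # weighted-average curve in activity units
  s <- comps[, sel]
  # spatial map of the selected source: M = Xc S^T (S S^T)^-1, and
  # S S^T = n I after whitening, so the map is Xc s / n
  wmap <- pmax(as.vector(Xc %*% s) / length(s), 0)
  wmap[wmap < 0.5 * max(wmap)] <- 0      # keep strongly blood-weighted voxels
  assert_that(sum(wmap) > 0, "degenerate blood component",
              "petidif_extraction_error")
  curve <- as.vector(t(X) %*% wmap) / sum(wmap)
  at_scale <- interpolate_curve(tac_t, curve, scaling_times)
  assert_that(all(at_scale > 0), "component non-positive at a scaling time",
              "petidif_extraction_error")
  wb <- interpolate_curve(blood$time, blood$whole_blood, scaling_times)
  scale <- mean(wb / at_scale)
  list(input = input_function(tac_t, pmax(scale * curve, 0),
                              provenance = "naganawa"),
       components = comps, selected = sel)
}
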