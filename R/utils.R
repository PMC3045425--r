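#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup bind_rows left_join
#' @importFrom purrr map map_dbl map2 pmap imap keep
#' @importFrom stats approx optim nlminb rnorm runif sd median coef lm setNames
#' @importFrom utils head tail modifyList
NULL

stop_petidif <- function(msg, class) {
  abort(msg, class = c(class, "petidif_error"))
}

assert_that <- function(ok, msg, class = "petidif_validation_error") {
  if (!isTRUE(ok)) stop_petidif(msg, class)
  invisible(TRUE)
}

is_strictly_increasing <- function(x) all(diff(x) > 0)

#' Trapezoidal integration
#'
#' Cumulative and total trapezoid integrals of a sampled curve. Used for all
#' AUC computations and for the Logan integrals.
#'
#' @param times sample times (strictly increasing).
#' @param values sampled values.
#' @return `trapz()` the total integral; `cum_trapz()` a vector of cumulative
#'   integrals from `times[1]` to each sample time.
#' @export
trapz <- function(times, values) {
  assert_that(length(times) == length(values) && length(times) >= 2,
              "trapz() needs two equal-length samples or more")
  sum(diff(times) * (head(values, -1) + tail(values, -1)) / 2)
}

#' @rdname trapz
#' @export
cum_trapz <- function(times, values) {
  c(0, cumsum(diff(times) * (head(values, -1) + tail(values, -1)) / 2))
}

#' Interpolate a sampled curve
#'
#' Linear interpolation with the package-wide extrapolation contract: queries
#' before the first sample are interpolated linearly from zero at `t = 0`
#' (input functions start at zero at injection); queries after the last sample
#' hold the last value.
#'
#' @param times sample times in minutes, strictly increasing.
#' @param values sampled values.
#' @param query_times times at which to evaluate, or a [frame_schedule()] when
#'   `mode = "frame_start"`.
#' @param mode `"linear"` evaluates at `query_times` directly;
#'   `"frame_start"` treats `query_times` as a frame schedule and evaluates at
#'   the frame start times (the convention used for metabolite correction).
#' @return interpolated values at the query points.
#' @export
interpolate_curve <- function(times, values, query_times,
                              mode = c("linear", "frame_start")) {
  mode <- match.arg(mode)
  assert_that(length(times) > 0 && length(times) == length(values),
              "empty or mismatched curve")
  assert_that(is_strictly_increasing(times), "times must be strictly increasing")
  if (mode == "frame_start") {
    assert_that(inherits(query_times, "frame_schedule"),
                "mode = 'frame_start' needs a frame_schedule")
    query_times <- query_times$start
  }
  # prepend the implicit (0, 0) origin unless the curve already starts at t <= 0
  if (times[1] > 0) {
    times <- c(0, times)
    values <- c(0, values[])
  }
  out <- approx(times, values, xout = query_times, rule = 2)$y
  out
}

gaussian_kernel_1d <- function(sigma_mm, voxel_mm, radius_mm) {
  n <- max(1L, ceiling(radius_mm / voxel_mm))
  x <- seq(-n, n) * voxel_mm
  k <- exp(-x^2 / (2 * sigma_mm^2))
  k / sum(k)
}

# 1D convolution along one axis of a 3D array via banded matrix product.
conv_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  # dense n x n convolution matrix with zero padding outside the grid
  cm <- matrix(0, n, n)
  for (j in seq_len(length(kernel))) {
    off <- j - 1L - half
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    cm[cbind(idx[ok], src[ok])] <- cm[cbind(idx[ok], src[ok])] + kernel[j]
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- cm %*% matrix(v, nrow = dv[1])
  dim(v) <- dv
  aperm(v, order(perm))
}

# separable isotropic Gaussian blur of a 3D volume (zero padding at edges)
gauss_blur_3d <- function(vol, sigma_mm, voxel_mm, radius_mm = 4 * sigma_mm) {
  if (sigma_mm <= 0) return(vol)
  k <- gaussian_kernel_1d(sigma_mm, voxel_mm, radius_mm)
  for (ax in 1:3) vol <- conv_axis(vol, k, ax)
  vol
}

skewness <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
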