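#' Tri-exponential (Feng-type) whole-blood model
#'
#' Whole-blood activity after a bolus: zero until the appearance delay `tau`,
#' then
#' \deqn{C_{wb}(t) = A_1 (t-\tau) e^{-\lambda_1 (t-\tau)}
#'   + A_2 (e^{-\lambda_2 (t-\tau)} - e^{-\lambda_1 (t-\tau)})
#'   + A_3 (e^{-\lambda_3 (t-\tau)} - e^{-\lambda_1 (t-\tau)})}
#' The default templates place the peak at about 90 s post-injection.
#'
#' @param template a [tracer_template()].
#' @param time_grid minutes, increasing, starting at 0.
#' @return whole-blood activity (kBq/mL) on the grid.
#' @export
feng_whole_blood <- function(template, time_grid) {
  f <- template$feng
  assert_that(all(c(f$lam1, f$lam2, f$lam3) > 0), "Feng rates must be positive")
  assert_that(time_grid[1] >= 0 && !is.unsorted(time_grid),
              "time grid must be increasing and start at 0")
  u <- pmax(time_grid - f$tau, 0)
  v <- f$A1 * u * exp(-f$lam1 * u) +
    f$A2 * (exp(-f$lam2 * u) - exp(-f$lam1 * u)) +
    f$A3 * (exp(-f$lam3 * u) - exp(-f$lam1 * u))
  v[time_grid <= f$tau] <- 0
  pmax(v, 0)
}

# analytic integral of the Feng model from 0 to each t (used by tests as the
# closed-form AUC; exported for reuse)
#' @rdname feng_whole_blood
#' @export
feng_auc <- function(template, t_end) {
  f <- template$feng
  u <- max(t_end - f$tau, 0)
  int_texp <- function(lam, u) (1 - (1 + lam * u) * exp(-lam * u)) / lam^2
  int_exp <- function(lam, u) (1 - exp(-lam * u)) / lam
  f$A1 * int_texp(f$lam1, u) +
    f$A2 * (int_exp(f$lam2, u) - int_exp(f$lam1, u)) +
    f$A3 * (int_exp(f$lam3, u) - int_exp(f$lam1, u))
}

# fit (a, t50) of r(t) = 1 - a * t^h / (t^h + t50^h) through the anchors,
# with 0 < a <= 1 so the curve stays in [0, 1] and is non-increasing
fit_hill_ratio <- function(anchors, h) {
  tt <- vapply(anchors, `[`, numeric(1), 1)
  rr <- vapply(anchors, `[`, numeric(1), 2)
  assert_that(!is.unsorted(tt, strictly = TRUE), "anchor times must increase")
  assert_that(all(diff(rr) <= 1e-9), "anchor ratios must be non-increasing")
  if (all(abs(rr - rr[1]) < 1e-12) && abs(rr[1] - 1) < 1e-12) {
    return(list(a = 0, t50 = Inf, h = h))
  }
  obj <- function(p) {
    a <- stats::plogis(p[1])
    t50 <- exp(p[2])
    pred <- 1 - a * tt^h / (tt^h + t50^h)
    sum((pred - rr)^2)
  }
  best <- NULL
  for (t50_0 in c(5, 20, 60, 150)) {
    fit <- nlminb(c(stats::qlogis(0.9), log(t50_0)), obj)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  assert_that(best$objective < 1e-4,
              "metabolite anchors cannot be fit by a monotone Hill curve")
  list(a = stats::plogis(best$par[1]), t50 = exp(best$par[2]), h = h)
}

#' Parent/whole-blood ratio curve
#'
#' Monotone non-increasing Hill-type curve
#' \deqn{r(t) = 1 - a\, t^h / (t^h + t_{50}^h)}
#' with \eqn{r(0) = 1}, fit through the template's metabolite anchors at the
#' template's Hill slope. For the high-metabolite mode the ratio falls from
#' about 0.96 at 4 min to about 0.07 at 90 min; for the low-metabolite mode it
#' stays near 1 (0.80 at 90 min).
#'
#' @inheritParams feng_whole_blood
#' @return ratio values in `[0, 1]` on the grid.
#' @export
parent_fraction_curve <- function(template, time_grid) {
  m <- template$metabolite
  fit <- fit_hill_ratio(m$anchors, m$hill_slope)
  if (!is.finite(fit$t50)) return(rep(1, length(time_grid)))
  r <- 1 - fit$a * time_grid^fit$h / (time_grid^fit$h + fit$t50^fit$h)
  r[time_grid == 0] <- 1
  pmax(r, 0)
}

#' Build the arterial input function of a template
#'
#' Combines the Feng whole-blood model with the metabolite ratio curve:
#' `parent_plasma(t) = whole_blood(t) * r(t)`, where `r` is the
#' parent-plasma/whole-blood ratio curve. Tagged `arterial`.
#'
#' @inheritParams feng_whole_blood
#' @return an [input_function()] with `whole_blood` and `parent_plasma`.
#' @export
make_input_function <- function(template, time_grid) {
  wb <- feng_whole_blood(template, time_grid)
  r <- parent_fraction_curve(template, time_grid)
  input_function(time_grid, wb, parent_plasma = wb * r, provenance = "arterial")
}

#' Sample arterial blood at a discrete schedule
#'
#' Emulates discrete arterial sampling of a continuous input function at the
#' clinical schedule (default: every 15 s to 150 s, then sparser to 90 min),
#' with optional multiplicative Gaussian noise.
#'
#' @param input an [input_function()] with `parent_plasma`.
#' @param template the [tracer_template()] that generated it (for the
#'   plasma/whole-blood scalar).
#' @param sampling_times minutes; default [default_blood_sampling_times()].
#' @param noise_cv coefficient of variation of multiplicative noise (0 = exact).
#' @param seed integer seed used when `noise_cv > 0`.
#' @return a [blood_series()].
#' @export
sample_arterial_blood <- function(input, template,
                                  sampling_times = default_blood_sampling_times(),
                                  noise_cv = 0, seed = 1L) {
  assert_that(max(sampling_times) <= max(input$time) + 1e-9,
              "sampling times must lie within the curve span")
  wb <- interpolate_curve(input$time, input$whole_blood, sampling_times)
  pp <- interpolate_curve(input$time, input$parent_plasma, sampling_times)
  rho <- template$plasma_over_wholeblood
  plasma <- wb * rho
  # parent fraction (in plasma) from the noiseless curves; it is a ratio
  # measurement and far less noisy than the activity assays
  pf <- ifelse(plasma > 0, pmin(pmax(pp / pmax(plasma, 1e-12), 0), 1), 0)
  if (noise_cv > 0) {
    set.seed(seed)
    wb <- pmax(wb * (1 + rnorm(length(wb), 0, noise_cv)), 0)
    plasma <- pmax(plasma * (1 + rnorm(length(plasma), 0, noise_cv)), 0)
  }
  blood_series(sampling_times, wb, plasma, pf)
}
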