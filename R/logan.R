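#' Logan graphical analysis
#'
#' Regresses the normalized tissue integral
#' \eqn{y_i = \int_0^{t_i} C_T / C_T(t_i)} on the normalized input integral
#' \eqn{x_i = \int_0^{t_i} C_p / C_T(t_i)} over the frames whose midpoints
#' fall at or after `t_star`; the slope of the late-time linear segment
#' estimates the total distribution volume VT. Integrals are trapezoidal;
#' the input is integrated on its own grid and the cumulative integral
#' interpolated to the frame midpoints.
#'
#' @param tissue_tac tissue activity at the frame midpoints (kBq/mL).
#' @param input an [input_function()] with a `parent_plasma` column
#'   (metabolite-corrected).
#' @param schedule the [frame_schedule()] of the TAC.
#' @param t_star start of the linear segment in minutes (default 30).
#' @return a `logan_fit` with `vt`, `intercept`, `t_star`, `n_points`,
#'   `r_squared`.
#' @export
logan_vt <- function(tissue_tac, input, schedule, t_star = 30) {
  assert_that(!is.null(input[["parent_plasma"]]),
              "input must be metabolite-corrected (parent_plasma missing)")
  assert_that(t_star < max(schedule$end), "t_star beyond the scan end")
  t_i <- schedule$mid
  assert_that(length(tissue_tac) == length(t_i), "TAC/schedule length mismatch")
  # input integral on its own grid (implicit zero at t = 0)
  it <- input$time; iv <- input[["parent_plasma"]]
  if (it[1] > 0) { it <- c(0, it); iv <- c(0, iv) }
  cum_cp <- cum_trapz(it, iv)
  int_cp <- approx(it, cum_cp, xout = t_i, rule = 2)$y
  tt <- c(0, t_i); cv <- c(0, tissue_tac)
  int_ct <- cum_trapz(tt, cv)[-1]
  use <- t_i >= t_star - 1e-9
  drop <- use & tissue_tac <= 0
  if (any(drop)) {
    warn(sprintf("dropping %d frame(s) with non-positive tissue activity", sum(drop)))
    use <- use & !drop
  }
  assert_that(sum(use) >= 3, "fewer than 3 usable frames after t_star",
              "petidif_fit_error")
  x <- int_cp[use] / tissue_tac[use]
  y <- int_ct[use] / tissue_tac[use]
  fit <- lm(y ~ x)
  structure(list(vt = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 t_star = t_star, n_points = sum(use),
                 r_squared = summary(fit)$r.squared),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("<logan_fit> VT = %.4g mL/cm^3 (intercept %.3g min, t* = %g, n = %d, R^2 = %.4f)\n",
              x$vt, x$intercept, x$t_star, x$n_points, x$r_squared))
  invisible(x)
}
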