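# Independent oracles and small fixtures used across the suite.

# Fine-step RK4 integration of the 2TCM ODE system; independent of the
# package's analytic convolution solver.
rk4_two_tissue <- function(params, cp_fun, t_end, dt = 1e-3) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  deriv <- function(t, y) {
    cp <- cp_fun(t)
    c(K1 * cp - (k2 + k3) * y[1] + k4 * y[2],
      k3 * y[1] - k4 * y[2])
  }
  n <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  out <- matrix(0, n + 1, 2)
  y <- c(0, 0)
  for (i in seq_len(n)) {
    t <- times[i]
    k1v <- deriv(t, y)
    k2v <- deriv(t + dt / 2, y + dt / 2 * k1v)
    k3v <- deriv(t + dt / 2, y + dt / 2 * k2v)
    k4v <- deriv(t + dt, y + dt * k3v)
    y <- y + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    out[i + 1, ] <- y
  }
  list(time = times, ct = out[, 1] + out[, 2])
}

# small synthetic dynamic image with known voxel TACs
toy_image <- function(dims = c(10, 10, 4), n_frames = 6, seed = 1) {
  set.seed(seed)
  sched <- frame_schedule(seq(0, by = 0.5, length.out = n_frames),
                          rep(0.5, n_frames))
  vox <- array(runif(prod(dims) * n_frames), dim = c(dims, n_frames))
  dynamic_image(vox, c(2, 2, 2), sched)
}

# image whose every voxel carries value * a fixed curve (plus optional second
# source), for constructed-algebra tests
curve_image <- function(curve, mask_value = 1, dims = c(8, 8, 4),
                        background_curve = NULL) {
  nf <- length(curve)
  sched <- frame_schedule(seq(0, by = 0.5, length.out = nf), rep(0.5, nf))
  vox <- array(0, dim = c(dims, nf))
  for (fr in seq_len(nf)) {
    vox[, , , fr] <- mask_value * curve[fr]
    if (!is.null(background_curve)) {
      vox[1:2, , , fr] <- background_curve[fr]
    }
  }
  dynamic_image(vox, c(2, 2, 2), sched)
}

test_schedule <- function() default_frame_schedule()

# Metabolite-free bolus input with a thin slow tail, used by the closed-form
# Logan/2TCM oracles: pseudo-equilibrium is reached within the 90-min scan,
# so the graphical slope can be compared against K1/k2*(1+k3/k4) directly.
oracle_input <- function(g = c(seq(0, 3, 0.005), seq(3.02, 10, 0.02),
                               seq(10.1, 92, 0.1))) {
  u <- pmax(g - 1, 0)
  wb <- 200 * u * exp(-3 * u) + 1.2 * (exp(-0.18 * u) - exp(-3 * u)) +
    0.6 * (exp(-0.012 * u) - exp(-3 * u))
  wb[g <= 1] <- 0
  input_function(g, wb, parent_plasma = wb)
}

# small phantom spec for integration tests (coarser than the default grid)
test_spec <- function(...) {
  phantom_spec(grid_shape = c(64, 64, 64), voxel_size = 2.5, ...)
}
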