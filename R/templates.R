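#' Kinetic rate constants for a two-tissue compartment model
#'
#' @param K1 plasma-to-tissue influx, mL cm^-3 min^-1.
#' @param k2,k3,k4 first-order rates, min^-1.
#' @param delay input-function delay in minutes (default 0).
#' @return a `kinetic_params` list. Blood volume is fixed at zero throughout
#'   the package.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, delay = 0) {
  assert_that(all(c(K1, k2, k3, k4) >= 0), "rates must be >= 0")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, delay = delay, vB = 0),
            class = "kinetic_params")
}

#' Tracer templates for the synthetic study
#'
#' A tracer template bundles everything needed to generate one tracer's
#' synthetic data: the tri-exponential (Feng-type) whole-blood model, the
#' metabolite (parent/whole-blood ratio) anchor points with a Hill slope, the
#' total-plasma over whole-blood scalar, per-region two-tissue rate constants,
#' and the Chen calibration times / pseudo-blood truncation default for that
#' tracer class.
#'
#' Two built-in modes are provided. `rolipram_like` emulates a low-metabolite
#' radioligand: the parent remains the dominant blood component throughout
#' (parent/whole-blood about 0.99 at 60 min and 0.80 at 90 min).
#' `pbr28_like` emulates a high-metabolite radioligand (about 0.96 at 4 min
#' falling to 0.07 at 90 min). Both share the same whole-blood shape, peaking
#' at about 90 s after injection.
#'
#' @param name `"rolipram_like"` or `"pbr28_like"`.
#' @return a `tracer_template` list with elements `name`, `feng`, `metabolite`,
#'   `plasma_over_wholeblood`, `regions`, `chen_times`, `su_truncation`,
#'   `backes_defaults`.
#' @export
tracer_template <- function(name = c("rolipram_like", "pbr28_like")) {
  name <- match.arg(name)
  if (name == "rolipram_like") {
    tpl <- list(
      name = name,
      feng = list(A1 = 200, A2 = 3.0, A3 = 1.5,
                  lam1 = 3.0, lam2 = 0.18, lam3 = 0.012, tau = 1.0),
      metabolite = list(anchors = list(c(60, 0.99), c(90, 0.80)), hill_slope = 8),
      plasma_over_wholeblood = 1.05,
      regions = list(
        frontal_grey   = kinetic_params(0.35, 0.55, 0.25, 0.12),
        temporal_grey  = kinetic_params(0.33, 0.52, 0.24, 0.12),
        parietal_grey  = kinetic_params(0.34, 0.54, 0.26, 0.13),
        occipital_grey = kinetic_params(0.36, 0.56, 0.22, 0.11),
        basal_ganglia  = kinetic_params(0.30, 0.50, 0.20, 0.11),
        cerebellum     = kinetic_params(0.32, 0.55, 0.18, 0.10),
        white_matter   = kinetic_params(0.15, 0.35, 0.15, 0.10),
        scalp          = kinetic_params(0.10, 0.15, 0.03, 0.03),
        soft_tissue    = kinetic_params(0.06, 0.10, 0.02, 0.04)
      ),
      chen_times = c(6, 20, 60, 90),
      su_truncation = 20,
      backes_defaults = c(a_v = 0.4, k = 5e-4)
    )
  } else {
    tpl <- list(
      name = name,
      feng = list(A1 = 220, A2 = 3.2, A3 = 1.6,
                  lam1 = 3.2, lam2 = 0.20, lam3 = 0.015, tau = 0.95),
      metabolite = list(anchors = list(c(4, 0.96), c(90, 0.07)), hill_slope = 2),
      plasma_over_wholeblood = 1.05,
      regions = list(
        frontal_grey   = kinetic_params(0.12, 0.08, 0.04, 0.025),
        temporal_grey  = kinetic_params(0.11, 0.075, 0.042, 0.026),
        parietal_grey  = kinetic_params(0.12, 0.082, 0.038, 0.024),
        occipital_grey = kinetic_params(0.13, 0.085, 0.036, 0.024),
        basal_ganglia  = kinetic_params(0.10, 0.075, 0.04, 0.025),
        cerebellum     = kinetic_params(0.11, 0.08, 0.035, 0.023),
        white_matter   = kinetic_params(0.08, 0.07, 0.035, 0.025),
        scalp          = kinetic_params(0.10, 0.12, 0.03, 0.025),
        soft_tissue    = kinetic_params(0.08, 0.08, 0.03, 0.03)
      ),
      chen_times = c(4, 20, 60, 90),
      su_truncation = 40,
      backes_defaults = c(a_v = 0.5, k = 5e-2)
    )
  }
  validate_template(tpl)
  structure(tpl, class = "tracer_template")
}

validate_template <- function(tpl) {
  f <- tpl$feng
  rates <- c(f$lam1, f$lam2, f$lam3)
  assert_that(all(rates > 0), "Feng rates must be positive")
  assert_that(anyDuplicated(rates) == 0, "Feng rates must be distinct")
  ratios <- vapply(tpl$metabolite$anchors, `[`, numeric(1), 2)
  assert_that(all(ratios >= 0 & ratios <= 1.5), "anchor ratios must lie in [0, 1.5]")
  assert_that(ratios[1] >= ratios[length(ratios)],
              "anchor ratios must not increase overall")
  invisible(tpl)
}

#' Names of the grey-matter phantom regions
#'
#' The regions averaged when reporting "grey-matter" Logan VT ratios.
#' @return character vector.
#' @export
grey_matter_regions <- function() {
  c("frontal_grey", "temporal_grey", "parietal_grey", "occipital_grey",
    "basal_ganglia", "cerebellum")
}
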