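#' Simulate a dynamic PET scan of a labelled phantom
#'
#' Each frame is formed by assigning every voxel its label's time-activity
#' value — either sampled at the frame midpoint (punctual detection,
#' `frame_averaging = FALSE`) or averaged over the frame — then convolving
#' the frame with the two-Gaussian PSF and adding zero-mean Gaussian noise
#' with variance `alpha * activity / (decay(t_mid) * duration)`.
#'
#' @param lmap a [label_map()].
#' @param label_tacs tibble with a `time` column (minutes, fine grid) and one
#'   column per region name in `lmap`, giving each label's noise-free curve.
#' @param spec a [phantom_spec()].
#' @param schedule a [frame_schedule()].
#' @return a [dynamic_image()].
#' @export
simulate_dynamic_scan <- function(lmap, label_tacs, spec, schedule) {
  regions <- unique(unname(lmap$names))
  missing <- setdiff(regions, names(label_tacs))
  assert_that(length(missing) == 0,
              paste("missing label TACs:", paste(missing, collapse = ", ")))
  d <- dim(lmap$labels)
  nf <- nrow(schedule)
  ids <- as.integer(names(lmap$names))
  # per-frame value of each label
  frame_value <- function(curve) {
    if (spec$frame_averaging) {
      cum <- cum_trapz(label_tacs$time, curve)
      f <- function(t) approx(label_tacs$time, cum, xout = t, rule = 2)$y
      (f(schedule$end) - f(schedule$start)) / schedule$duration
    } else {
      approx(label_tacs$time, curve, xout = schedule$mid, rule = 2)$y
    }
  }
  vals <- vapply(lmap$names, function(rg) frame_value(label_tacs[[rg]]),
                 numeric(nf))               # nf x nlabels
  lut0 <- numeric(max(ids) + 1L)
  voxels <- array(0, dim = c(d, nf))
  set.seed(spec$seed)
  decay <- 2^(-schedule$mid / spec$isotope_half_life)
  lab1 <- as.integer(lmap$labels) + 1L
  for (fr in seq_len(nf)) {
    lut <- lut0
    lut[ids + 1L] <- vals[fr, ]
    vol <- array(lut[lab1], dim = d)
    vol <- apply_psf(vol, spec)
    if (spec$noise_alpha > 0) {
      sdv <- sqrt(spec$noise_alpha * pmax(vol, 0) /
                    (decay[fr] * schedule$duration[fr]))
      vol <- vol + array(rnorm(length(vol), 0, 1), dim = d) * sdv
    }
    voxels[, , , fr] <- vol
  }
  dynamic_image(voxels, rep(spec$voxel_size, 3), schedule)
}

#' Simulate a complete phantom study for one tracer template
#'
#' Convenience wrapper that builds the phantom, generates the arterial input
#' function and all regional tissue curves from the template's two-tissue
#' kinetics (carotid labels carry the whole-blood curve), simulates the
#' dynamic scan, and samples the arterial blood. This is the synthetic
#' stand-in for one subject's raw data.
#'
#' @param template a [tracer_template()].
#' @param spec a [phantom_spec()].
#' @param schedule a [frame_schedule()].
#' @param blood_noise_cv CV of the arterial sample noise (default 0: the
#'   sampled series is the noiseless arterial truth).
#' @return a `phantom_study` list: `image`, `label_map`, `arterial` (fine-grid
#'   [input_function()]), `blood` ([blood_series()]), `label_tacs`,
#'   `region_tacs` (noise-free tissue curves at frame midpoints), `template`,
#'   `spec`, `schedule`.
#' @export
simulate_phantom_study <- function(template, spec = phantom_spec(),
                                   schedule = default_frame_schedule(),
                                   blood_noise_cv = 0) {
  grid <- c(seq(0, 3, by = 0.005), seq(3.02, 10, by = 0.02),
            seq(10.1, max(schedule$end) + 2, by = 0.1))
  arterial <- make_input_function(template, grid)
  lmap <- build_head_phantom(spec)
  regions <- unique(unname(lmap$names))
  label_tacs <- tibble(time = grid)
  for (rg in regions) {
    if (grepl("^carotid", rg)) {
      label_tacs[[rg]] <- arterial$whole_blood
    } else {
      label_tacs[[rg]] <- tissue_tac_from_rates(template$regions[[rg]],
                                                arterial, grid)
    }
  }
  image <- simulate_dynamic_scan(lmap, label_tacs, spec, schedule)
  blood <- sample_arterial_blood(arterial, template, noise_cv = blood_noise_cv,
                                 seed = spec$seed + 1000L)
  tissue_regions <- setdiff(regions, grep("^carotid", regions, value = TRUE))
  region_tacs <- tibble(time = schedule$mid)
  for (rg in tissue_regions) {
    region_tacs[[rg]] <- approx(grid, label_tacs[[rg]], xout = schedule$mid,
                                rule = 2)$y
  }
  structure(list(image = image, label_map = lmap, arterial = arterial,
                 blood = blood, label_tacs = label_tacs,
                 region_tacs = region_tacs, template = template, spec = spec,
                 schedule = schedule),
            class = "phantom_study")
}

#' Mean regional time-activity curves measured from an image
#'
#' @param image a [dynamic_image()].
#' @param lmap a [label_map()] on the same grid.
#' @param regions region names (default: all tissue regions).
#' @return tibble with `time` (frame midpoints) and one column per region.
#' @export
measure_region_tacs <- function(image, lmap, regions = NULL) {
  assert_that(all(dim(image$voxels)[1:3] == dim(lmap$labels)),
              "image and label map grids differ")
  if (is.null(regions)) {
    regions <- setdiff(unique(unname(lmap$names)),
                       grep("^carotid", lmap$names, value = TRUE))
  }
  nf <- nrow(image$schedule)
  vmat <- matrix(image$voxels, ncol = nf)
  out <- tibble(time = image$schedule$mid)
  for (rg in regions) {
    m <- as.vector(label_mask(lmap, rg))
    assert_that(any(m), paste("empty region:", rg))
    out[[rg]] <- colMeans(vmat[m, , drop = FALSE])
  }
  out
}
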