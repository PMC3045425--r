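# Synthetic whole-blood curve with a linear rise and an exactly
# tri-exponential decay, so the Mourik/Croteau fit step is exact by
# construction and tests probe the method machinery, not the blood model.
triexp_blood <- function(t, t_peak = 1.25) {
  tail_v <- function(u) 15 * exp(-1.2 * u) + 1.2 * exp(-0.18 * u) +
    0.6 * exp(-0.012 * u)
  ifelse(t < t_peak, t / t_peak * tail_v(0), tail_v(pmax(t - t_peak, 0)))
}

# Constructed-image fixture: a carotid block carrying rc * C_wb + sp * C_sur
# and a surround block carrying C_sur, with masks matching the construction.
eq1_fixture <- function(rc, sp, n_frames = 27) {
  sched <- default_frame_schedule()
  wb <- triexp_blood(sched$mid)
  sur <- 1.5 * (1 - exp(-0.15 * sched$mid))       # tissue-like surround
  vox <- array(0, dim = c(10, 10, 6, nrow(sched)))
  for (fr in seq_len(nrow(sched))) {
    vox[, , , fr] <- sp * sur[fr]                  # background floor
    vox[4:6, 4:6, , fr] <- rc * wb[fr] + sp * sur[fr]
  }
  img <- dynamic_image(vox, c(2, 2, 2), sched)
  car <- array(FALSE, dim = c(10, 10, 6)); car[4:6, 4:6, ] <- TRUE
  bg <- array(FALSE, dim = c(10, 10, 6)); bg[9:10, , ] <- TRUE
  # recover C_sur itself in the background (not sp-scaled)
  for (fr in seq_len(nrow(sched))) {
    v <- img$voxels[, , , fr]; v[9:10, , ] <- sur[fr]; img$voxels[, , , fr] <- v
  }
  rois <- structure(list(carotid_mask = car, background_mask = bg,
                         plane_ids = 1:6,
                         clusters = list(which(car, arr.ind = TRUE))),
                    class = "carotid_roi_set")
  # dense blood table including the frame midpoints, so calibration values
  # are exact and constructed RC/SP recover to machine precision
  ts <- sort(unique(c(default_blood_sampling_times(), sched$mid)))
  blood <- blood_series(ts, triexp_blood(ts), triexp_blood(ts),
                        rep(1, length(ts)))
  list(img = img, rois = rois, blood = blood, wb = wb, sur = sur, sched = sched)
}

test_that("Chen calibration recovers constructed RC and SP near-exactly", {
  fx <- eq1_fixture(rc = 0.65, sp = 0.25)
  res <- chen_idif(fx$img, fx$rois, fx$blood, mode = "rolipram_like")
  expect_equal(res$fit$RC, 0.65, tolerance = 1e-6)
  expect_equal(res$fit$SP, 0.25, tolerance = 1e-6)
  expect_equal(res$input$whole_blood, fx$wb, tolerance = 1e-6)
  expect_equal(provenance(res$input), "chen")
  expect_equal(res$fit$calibration_times, c(6, 20, 60, 90))
})

test_that("Chen is the identity when the carotid signal is pure blood", {
  fx <- eq1_fixture(rc = 1, sp = 0)
  res <- chen_idif(fx$img, fx$rois, fx$blood, mode = "rolipram_like")
  expect_equal(res$fit$RC, 1, tolerance = 1e-6)
  expect_equal(res$fit$SP, 0, tolerance = 1e-6)
  expect_equal(res$input$whole_blood, fx$wb, tolerance = 1e-6)
})

test_that("a singular calibration design (surround proportional to blood) errors", {
  wb <- triexp_blood(c(6, 20, 60, 90))
  expect_error(petidif:::fit_rc_sp(0.8 * wb, wb, 0.5 * wb),
               class = "petidif_calibration_error")
})

test_that("Su propagates pseudo-blood bias exactly as the algebra predicts", {
  # carotid block carries 0.6*wb + 0.2*sur; one voxel carries 0.9*wb, which
  # dominates every frame because the surround is kept small
  sched <- default_frame_schedule()
  wb <- triexp_blood(sched$mid)
  sur <- 0.1 * (1 - exp(-0.15 * sched$mid))
  vox <- array(0, dim = c(10, 10, 6, nrow(sched)))
  for (fr in seq_len(nrow(sched))) {
    vox[4:6, 4:6, , fr] <- 0.6 * wb[fr] + 0.2 * sur[fr]
    vox[5, 5, 3, fr] <- 0.9 * wb[fr]
    vox[9:10, , , fr] <- sur[fr]
  }
  img <- dynamic_image(vox, c(2, 2, 2), sched)
  car <- array(FALSE, dim = c(10, 10, 6)); car[4:6, 4:6, ] <- TRUE
  bg <- array(FALSE, dim = c(10, 10, 6)); bg[9:10, , ] <- TRUE
  rois <- structure(list(carotid_mask = car, background_mask = bg,
                         plane_ids = 1:6,
                         clusters = list(which(car, arr.ind = TRUE))),
                    class = "carotid_roi_set")
  res <- su_idif(img, rois, truncation_min = 20)
  expect_equal(provenance(res$input), "su")
  expect_equal(res$pseudo_blood, 0.9 * wb, tolerance = 1e-8)
  # the pseudo-blood bias propagates: recovery reproduces 0.9*wb, not wb
  expect_equal(res$input$whole_blood / (0.9 * wb), rep(1, 27),
               tolerance = 0.01)
})

test_that("Su default truncations follow the tracer mode", {
  fx <- eq1_fixture(rc = 0.8, sp = 0.1)
  r1 <- su_idif(fx$img, fx$rois, mode = "rolipram_like")
  expect_lte(max(r1$fit$calibration_times), 20)
  r2 <- su_idif(fx$img, fx$rois, mode = "pbr28_like")
  expect_lte(max(r2$fit$calibration_times), 40)
  expect_gt(max(r2$fit$calibration_times), 20)
})

test_that("Parker's late-frame correction applies the printed formula", {
  fx <- eq1_fixture(rc = 1, sp = 0)
  res <- parker_idif(fx$img, fx$rois, mode = "rolipram_like")
  pf <- res$parker_fit
  # uniform carotid block: hottest 5% equals the ROI mean before correction
  uncorrected <- setdiff(seq_len(27), pf$corrected_frames)
  expect_equal(pf$imax_curve[uncorrected], pf$imean_curve[uncorrected],
               tolerance = 1e-9)
  # corrected frames: I_max replaced by I_max * I_mean / T_mean
  expect_true(all(pf$tmean_curve[pf$corrected_frames] >
                    pf$imean_curve[pf$corrected_frames]))
  # direct formula check on a synthetic triple: T_mean = 2 I_mean halves I_max
  imax <- 10; imean <- 4; tmean <- 8
  expect_equal(imax * imean / tmean, 5)
})

test_that("hottest-pixels curve equals a brute-force oracle", {
  img <- toy_image(c(10, 10, 4), n_frames = 6, seed = 42)
  mask <- array(TRUE, dim = c(10, 10, 4))
  curve <- hottest_pixels_curve(img, mask, n_per_plane = 4)
  # oracle: rank by early sum (frames within [0,2] min weighted by duration)
  summed <- apply(img$voxels, 1:3, function(v) sum(v * img$schedule$duration *
    (img$schedule$start >= 0 & img$schedule$end <= 2)))
  picks <- NULL
  for (z in 1:4) {
    pl <- summed[, , z]
    ord <- order(pl, decreasing = TRUE)[1:4]
    ij <- arrayInd(ord, dim(pl))
    picks <- rbind(picks, cbind(ij, z))
  }
  oracle <- sapply(seq_len(6), function(fr) {
    mean(img$voxels[cbind(picks, fr)])
  })
  expect_equal(curve, oracle, tolerance = 1e-12)
  # uniform image: curve equals the uniform per-frame value
  u <- curve_image(c(5, 4, 3, 2, 1, 0.5), dims = c(6, 6, 3))
  expect_equal(hottest_pixels_curve(u, array(TRUE, dim = c(6, 6, 3)), 4),
               c(5, 4, 3, 2, 1, 0.5))
  # plane with fewer voxels than requested warns and uses all
  small <- array(FALSE, dim = c(10, 10, 4)); small[1:2, 1, 1] <- TRUE
  expect_warning(hottest_pixels_curve(img, small, 4), "using all")
})

test_that("tri-exponential fit recovers exact parameters and nested models", {
  t <- default_frame_schedule()$mid
  true_l <- c(1.2, 0.18, 0.012); true_a <- c(15, 1.2, 0.6)
  rise <- pmin(t / t[3], 1)
  y <- rise * 0
  tail_v <- sapply(t, function(ti) sum(true_a * exp(-true_l * (ti - t[3]))))
  y <- ifelse(t < t[3], t / t[3] * sum(true_a), tail_v)
  fit <- fit_triexponential(t, y)
  expect_lt(fit$rmse / max(y), 1e-6)
  expect_equal(sort(fit$rates), sort(true_l), tolerance = 0.01)
  expect_equal(fit$amplitudes[order(fit$rates, decreasing = TRUE)],
               true_a, tolerance = 0.01)
  # mono-exponential data: surplus amplitudes collapse to ~0
  y2 <- ifelse(t < t[3], t / t[3] * 10, 10 * exp(-0.3 * (t - t[3])))
  fit2 <- fit_triexponential(t, y2)
  expect_lt(fit2$rmse, 1e-6 * 10)
  expect_lt(sort(fit2$amplitudes)[2], 1e-3 * 10)
  # fitted curve tracks the samples to < 2% RMS of the signal
  rel <- (fit$fitted - y) / max(y)
  expect_lt(sqrt(mean(rel^2)), 0.02)
  expect_error(fit_triexponential(t[1:4], y[1:4]), "at least 8")
})

test_that("Mourik scaling uses 20/60/90 and inverts a known attenuation", {
  fx <- eq1_fixture(rc = 0.5, sp = 0)
  res <- mourik_idif(fx$img, fx$rois, fx$blood)
  expect_equal(res$scale, 2, tolerance = 0.03)
  expect_equal(provenance(res$input), "mourik")
  rel <- (res$input$whole_blood - fx$wb) / max(fx$wb)
  expect_lt(sqrt(mean(rel^2)), 0.01)
  # curve equal to blood at the scaling times -> scale 1
  fx1 <- eq1_fixture(rc = 1, sp = 0)
  expect_equal(mourik_idif(fx1$img, fx1$rois, fx1$blood)$scale, 1,
               tolerance = 0.02)
})

test_that("Backes inversion is the inverse of its forward model", {
  sched <- default_frame_schedule()
  tpl <- tracer_template("rolipram_like")
  g <- seq(0, 92, 0.01)
  wb <- approx(g, feng_whole_blood(tpl, g), sched$mid)$y
  meas <- petidif:::forward_backes(sched$mid, wb, a_v = 0.5, k = 0.05)
  back <- petidif:::invert_backes(sched$mid, meas, a_v = 0.5, k = 0.05)
  expect_equal(back, wb, tolerance = 1e-9)
  # a_v = 1, k = 0: measured curve is returned unchanged
  vox <- array(0, dim = c(6, 6, 4, nrow(sched)))
  for (fr in seq_len(nrow(sched))) vox[2:4, 2:4, , fr] <- wb[fr]
  img <- dynamic_image(vox, c(2, 2, 2), sched)
  sq <- array(FALSE, dim = c(6, 6, 4)); sq[2:4, 2:4, ] <- TRUE
  res <- backes_idif(img, sq, c(a_v = 1, k = 0))
  expect_equal(res$input$whole_blood, wb, tolerance = 1e-9)
  expect_equal(provenance(res$input), "backes")
  expect_error(backes_idif(img, sq, c(a_v = 0, k = 0.1)), "a_v")
})

test_that("recovery table is monotone, bounded, and saturates for large objects", {
  spec <- phantom_spec(voxel_size = 2)
  tab <- build_recovery_table(spec, diameters = seq(3, 8, by = 0.5))
  expect_true(all(diff(tab$rc) >= -1e-9))
  expect_true(all(tab$rc > 0 & tab$rc <= 1 + 1e-9))
  big <- petidif:::cylinder_rc(spec, 40)
  expect_gt(big, 0.98)
  full <- build_recovery_table(spec, diameters = seq(3, 8, by = 0.1))
  expect_equal(nrow(full), 51)
})

test_that("Croteau divides the fitted curve by rc at the stated diameter", {
  fx <- eq1_fixture(rc = 1, sp = 0)
  tab <- tibble::tibble(diameter = seq(3, 8, 0.1), rc = rep(1, 51))
  class(tab) <- c("recovery_table", class(tab))
  res <- croteau_idif(fx$img, fx$rois, 5, tab)
  expect_equal(length(res$planes), 3)
  expect_equal(diff(res$planes), c(1, 1))
  rel <- (res$input$whole_blood - fx$wb) / max(fx$wb)
  expect_lt(sqrt(mean(rel^2)), 0.01)
  # rc < 1 scales the output up accordingly
  tab2 <- tab; tab2$rc <- rep(0.5, 51)
  res2 <- croteau_idif(fx$img, fx$rois, 5, tab2)
  expect_equal(res2$input$whole_blood, 2 * res$input$whole_blood,
               tolerance = 1e-9)
  expect_error(croteau_idif(fx$img, fx$rois, 9, tab),
               class = "petidif_range_error")
})

test_that("parameter-grid calibration matches brute force and breaks ties low", {
  fx <- eq1_fixture(rc = 0.7, sp = 0.15)
  ref <- input_function(fx$sched$mid, fx$wb, provenance = "arterial")
  cands <- as.list(seq(10, 90, by = 10))
  res <- calibrate_parameter_grid(cands, fx$img, fx$rois, ref, method = "su")
  brute <- sapply(cands, function(tr) {
    out <- su_idif(fx$img, fx$rois, truncation_min = tr)
    auc_ratio(out$input, ref, 90)
  })
  expect_equal(res$index, which.min(abs(brute - 1)))
  expect_equal(res$ratios, brute, tolerance = 1e-12)
  expect_equal(length(backes_grid()), 12)
  av <- vapply(backes_grid(), `[[`, numeric(1), "a_v")
  kk <- vapply(backes_grid(), `[[`, numeric(1), "k")
  expect_setequal(unique(av), c(0.3, 0.4, 0.5))
  expect_setequal(unique(kk), c(5e-1, 5e-2, 5e-3, 5e-4))
})

test_that("ICA separates a two-source mixture and is seed-reproducible", {
  sched <- default_frame_schedule()
  tpl <- tracer_template("rolipram_like")
  g <- seq(0, 92, 0.01)
  wb <- approx(g, feng_whole_blood(tpl, g), sched$mid)$y
  # slowly accumulating tissue-like source (low washout)
  tis <- approx(g, tissue_tac_from_rates(kinetic_params(0.2, 0.05),
                                         make_input_function(tpl, g), g),
                sched$mid)$y
  set.seed(5)
  d <- c(12, 12, 6)
  map_b <- array(runif(prod(d)) * rbinom(prod(d), 1, 0.15), dim = d)
  map_t <- array(runif(prod(d)), dim = d)
  vox <- array(0, dim = c(d, nrow(sched)))
  for (fr in seq_len(nrow(sched))) {
    vox[, , , fr] <- map_b * wb[fr] + map_t * tis[fr]
  }
  img <- dynamic_image(vox, c(2, 2, 2), sched)
  blood <- blood_series(default_blood_sampling_times(),
                        interpolate_curve(sched$mid, wb, default_blood_sampling_times()),
                        interpolate_curve(sched$mid, wb, default_blood_sampling_times()),
                        rep(1, length(default_blood_sampling_times())))
  res <- naganawa_idif(img, blood, n_components = 2, seed = 9)
  expect_equal(provenance(res$input), "naganawa")
  expect_gt(cor(res$components[, res$selected], wb), 0.99)
  res2 <- naganawa_idif(img, blood, n_components = 2, seed = 9)
  expect_identical(res2$input$whole_blood, res$input$whole_blood)
  # degenerate single-source image: curve equals the source after scaling
  vox1 <- array(0, dim = c(d, nrow(sched)))
  for (fr in seq_len(nrow(sched))) vox1[, , , fr] <- map_t * wb[fr]
  img1 <- dynamic_image(vox1, c(2, 2, 2), sched)
  res1 <- naganawa_idif(img1, blood, n_components = 2, seed = 9)
  expect_equal(res1$input$whole_blood, wb, tolerance = 0.01 * max(wb))
})
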