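test_that("whole-blood model is zero before appearance and peaks near 90 s", {
  tpl <- tracer_template("rolipram_like")
  g <- seq(0, 95, by = 0.005)
  wb <- feng_whole_blood(tpl, g)
  expect_true(all(wb[g <= tpl$feng$tau] == 0))
  expect_true(all(wb >= 0))
  peak <- g[which.max(wb)]
  expect_gt(peak, 1.2)
  expect_lt(peak, 1.8)
  tp <- tracer_template("pbr28_like")
  peak2 <- g[which.max(feng_whole_blood(tp, g))]
  expect_gt(peak2, 1.2)
  expect_lt(peak2, 1.8)
})

test_that("whole-blood AUC matches the analytic term-by-term integral", {
  tpl <- tracer_template("rolipram_like")
  g <- seq(0, 90, by = 1 / 1000)      # ~1 ms sampling in minutes
  numeric_auc <- trapz(g, feng_whole_blood(tpl, g))
  expect_equal(numeric_auc, feng_auc(tpl, 90), tolerance = 5e-3)
  expect_error(feng_whole_blood(list(feng = list(A1 = 1, A2 = 1, A3 = 1,
                                                 lam1 = -1, lam2 = 1, lam3 = 2,
                                                 tau = 0)), g),
               "positive")
})

test_that("parent fraction curve hits the tracer anchors and stays monotone", {
  roli <- tracer_template("rolipram_like")
  pbr <- tracer_template("pbr28_like")
  g <- seq(0, 95, by = 0.05)
  r1 <- parent_fraction_curve(roli, g)
  r2 <- parent_fraction_curve(pbr, g)
  expect_equal(r1[1], 1)
  expect_true(all(diff(r1) <= 1e-9) && all(diff(r2) <= 1e-9))
  at <- function(r, t) approx(g, r, t)$y
  expect_lt(abs(at(r1, 90) - 0.80), 0.02)
  expect_lt(abs(at(r2, 4) - 0.96), 0.02)
  expect_lt(abs(at(r2, 90) - 0.07), 0.02)
  # all-ones anchors give the constant curve
  flat <- roli
  flat$metabolite$anchors <- list(c(30, 1), c(90, 1))
  expect_equal(parent_fraction_curve(flat, g), rep(1, length(g)))
  # non-monotone anchors are rejected
  bad <- roli
  bad$metabolite$anchors <- list(c(30, 0.5), c(90, 0.9))
  expect_error(parent_fraction_curve(bad, g), "non-increasing")
})

test_that("arterial input combines blood and metabolite models", {
  tpl <- tracer_template("pbr28_like")
  g <- seq(0, 92, by = 0.01)
  inp <- make_input_function(tpl, g)
  expect_s3_class(inp, "input_function")
  expect_equal(provenance(inp), "arterial")
  # high-metabolite mode: parent AUC well below whole-blood AUC (~0.57 for
  # the default curves: the anchored ratio stays near 1 through the peak,
  # so the deficit is carried by the suppressed tail)
  expect_lt(trapz(g, inp$parent_plasma) / trapz(g, inp$whole_blood), 0.62)
  # ratio one everywhere -> parent == whole blood
  flat <- tpl
  flat$metabolite$anchors <- list(c(30, 1), c(90, 1))
  inp2 <- make_input_function(flat, g)
  expect_equal(inp2$parent_plasma, inp2$whole_blood)
})

test_that("2TCM tissue curves match an independent RK4 oracle", {
  tpl <- tracer_template("rolipram_like")
  g <- seq(0, 30, by = 0.01)
  inp <- make_input_function(tpl, g)
  cp_fun <- function(t) interpolate_curve(g, inp$parent_plasma, pmax(t, 0))
  kp <- kinetic_params(0.3, 0.4, 0.2, 0.1)
  ours <- tissue_tac_from_rates(kp, inp, g)
  oracle <- rk4_two_tissue(kp, cp_fun, 30, dt = 2e-3)
  at <- approx(oracle$time, oracle$ct, xout = g[g >= 2])$y
  rel <- abs(ours[g >= 2] - at) / pmax(at, max(at) * 0.05)
  expect_lt(max(rel), 1e-3)
})

test_that("2TCM limiting cases: zero influx and constant-input steady state", {
  g <- seq(0, 400, by = 0.05)
  inp <- input_function(g, rep(2, length(g)), rep(2, length(g)))
  expect_equal(tissue_tac_from_rates(kinetic_params(0, 0.1), inp, g),
               rep(0, length(g)))
  kp <- kinetic_params(0.1, 0.2, 0.05, 0.1)
  ct <- tissue_tac_from_rates(kp, inp, g)
  target <- 2 * vt_from_rates(kp)
  t_eq <- 20 / kp$k4
  expect_lt(abs(approx(g, ct, t_eq)$y - target) / target, 0.01)
})

test_that("head phantom labels are disjoint, named, and carotids sized right", {
  spec <- test_spec()
  lmap <- build_head_phantom(spec)
  ids <- sort(unique(as.integer(lmap$labels)))
  expect_true(all(as.character(setdiff(ids, 0L)) %in% names(lmap$names)))
  expect_setequal(grep("carotid", lmap$names, value = TRUE),
                  c("carotid_8mm", "carotid_5mm"))
  # cylinder volume check on a fine grid where rasterization error is small
  fine <- phantom_spec(grid_shape = c(220, 220, 120), voxel_size = 0.5)
  lf <- build_head_phantom(fine)
  m8 <- label_mask(lf, "carotid_8mm")
  zs <- range(which(apply(m8, 3, any)))
  length_mm <- (zs[2] - zs[1] + 1) * 0.5
  expected <- 2 * pi * 4^2 * length_mm / 0.5^3       # two 8 mm cylinders
  expect_lt(abs(sum(m8) - expected) / expected, 0.05)
  # a carotid that cannot fit errors out
  expect_error(build_head_phantom(phantom_spec(grid_shape = c(10, 10, 10),
                                               voxel_size = 2)),
               "fit")
})

test_that("PSF kernel is normalized, has the stated defaults, and Gaussian FWHM", {
  spec <- phantom_spec()
  expect_equal(spec$psf$sigma1, 0.9)
  expect_equal(spec$psf$sigma2, 2.5)
  expect_equal(spec$psf$rho, 0.07)
  k <- psf_kernel(spec, voxel_size = 1)
  expect_equal(sum(k), 1, tolerance = 1e-9)
  # pure narrow component: measured FWHM = 2.355 * sigma within one voxel
  spec0 <- phantom_spec(psf = list(sigma1 = 2, sigma2 = 5, rho = 0))
  k0 <- psf_kernel(spec0, voxel_size = 0.5)
  mid <- (dim(k0)[1] + 1) / 2
  prof <- k0[, mid, mid] / max(k0[, mid, mid])
  xs <- (seq_along(prof) - mid) * 0.5
  # interpolate the half-maximum crossings on each side
  left <- approx(prof[xs <= 0], xs[xs <= 0], xout = 0.5)$y
  right <- approx(prof[xs >= 0], xs[xs >= 0], xout = 0.5)$y
  expect_lt(abs((right - left) - 2.355 * 2), 0.5)
  expect_error(psf_kernel(phantom_spec(psf = list(sigma1 = -1, sigma2 = 2,
                                                  rho = 0.1))),
               "positive")
})

test_that("separable PSF application equals direct kernel convolution", {
  spec <- phantom_spec(voxel_size = 2)
  set.seed(2)
  vol <- array(0, dim = c(13, 13, 13))
  vol[7, 7, 7] <- 1                      # impulse: response is the kernel
  blurred <- petidif:::apply_psf(vol, spec)
  k <- psf_kernel(spec)
  n <- (dim(k)[1] - 1) / 2
  ctr <- blurred[(7 - n):(7 + n), (7 - n):(7 + n), (7 - n):(7 + n)]
  expect_equal(ctr, k, tolerance = 1e-10)
})

test_that("simulation reduces to label TACs with no PSF and no noise", {
  labels <- array(1L, dim = c(6, 6, 6)); labels[4:6, , ] <- 2L
  lmap <- label_map(labels, c(`1` = "a", `2` = "b"))
  sched <- frame_schedule(c(0, 1, 2), rep(1, 3))
  tacs <- tibble::tibble(time = seq(0, 4, 0.01))
  tacs$a <- 2 * tacs$time
  tacs$b <- 10 - tacs$time
  spec <- phantom_spec(grid_shape = c(6, 6, 6), voxel_size = 2,
                       psf = list(sigma1 = 0, sigma2 = 1, rho = 0),
                       noise_alpha = 0)
  img <- simulate_dynamic_scan(lmap, tacs, spec, sched)
  expect_equal(img$voxels[1, 1, 1, ], 2 * sched$mid)
  expect_equal(img$voxels[5, 5, 5, ], 10 - sched$mid)
  tacs2 <- tacs[, c("time", "a")]
  expect_error(simulate_dynamic_scan(lmap, tacs2, spec, sched), "missing label")
})

test_that("frame averaging lowers the sampled peak of the 30-s frames", {
  tpl <- tracer_template("rolipram_like")
  sched <- default_frame_schedule()
  g <- seq(0, 92, 0.005)
  wb <- feng_whole_blood(tpl, g)
  punctual <- approx(g, wb, sched$mid)$y
  cum <- cum_trapz(g, wb)
  averaged <- (approx(g, cum, sched$end)$y - approx(g, cum, sched$start)$y) /
    sched$duration
  pk <- which.max(punctual)
  expect_lt(averaged[pk], punctual[pk])
})

test_that("PSF convolution conserves activity away from the grid edge", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size = 2)
  set.seed(9)
  vol <- array(0, dim = c(32, 32, 32))
  vol[10:22, 10:22, 10:22] <- runif(13^3)
  blurred <- petidif:::apply_psf(vol, spec)
  # all mass stays >5 voxels from the edge, so totals match
  expect_equal(sum(blurred), sum(vol), tolerance = 1e-3)
})

test_that("scan noise is seed-deterministic and zero when alpha = 0", {
  tpl <- tracer_template("rolipram_like")
  spec1 <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size = 5,
                        carotid_diameters = c(8, 5), seed = 11)
  lmap <- build_head_phantom(spec1)
  g <- seq(0, 92, 0.05)
  inp <- make_input_function(tpl, g)
  tacs <- tibble::tibble(time = g)
  for (rg in unique(unname(lmap$names))) {
    tacs[[rg]] <- if (grepl("carotid", rg)) inp$whole_blood else
      tissue_tac_from_rates(tpl$regions[[rg]], inp, g)
  }
  sched <- frame_schedule(c(0, 1, 2), rep(1, 3))
  a <- simulate_dynamic_scan(lmap, tacs, spec1, sched)
  b <- simulate_dynamic_scan(lmap, tacs, spec1, sched)
  expect_identical(a$voxels, b$voxels)
  spec2 <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size = 5,
                        carotid_diameters = c(8, 5), seed = 12)
  c2 <- simulate_dynamic_scan(lmap, tacs, spec2, sched)
  expect_false(identical(a$voxels, c2$voxels))
})

test_that("arterial sampling is exact without noise and reproducible with it", {
  tpl <- tracer_template("rolipram_like")
  g <- seq(0, 92, 0.01)
  inp <- make_input_function(tpl, g)
  b0 <- sample_arterial_blood(inp, tpl, noise_cv = 0)
  expect_equal(nrow(b0), length(default_blood_sampling_times()))
  expect_equal(b0$whole_blood,
               interpolate_curve(g, inp$whole_blood, b0$time))
  b1 <- sample_arterial_blood(inp, tpl, noise_cv = 0.05, seed = 3)
  b2 <- sample_arterial_blood(inp, tpl, noise_cv = 0.05, seed = 3)
  expect_identical(b1, b2)
  expect_false(identical(b0$whole_blood, b1$whole_blood))
})
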