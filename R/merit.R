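#' Metabolite-correct an input function
#'
#' Multiplies the whole-blood curve by the parent/whole-blood ratio curve,
#' interpolated at the beginning of each frame, to obtain the parent-plasma
#' curve. `mode` records whether the supplied ratio curve is the subject's
#' own (`individual`) or a population average (`population_average`); the
#' arithmetic is identical.
#'
#' @param idif an [input_function()] on the frame grid (one value per frame).
#' @param ratio_curve tibble/data frame with `time` (minutes) and `ratio`
#'   (parent/whole-blood, nonnegative) columns.
#' @param schedule the [frame_schedule()] whose start times set the
#'   interpolation points.
#' @param mode `"individual"` or `"population_average"`.
#' @return the input function with a `parent_plasma` column added.
#' @export
metabolite_correct <- function(idif, ratio_curve, schedule,
                               mode = c("individual", "population_average")) {
  mode <- match.arg(mode)
  assert_that(all(ratio_curve$ratio >= 0), "negative metabolite ratio")
  assert_that(nrow(idif) == nrow(schedule), "curve/schedule length mismatch")
  r <- interpolate_curve(ratio_curve$time, ratio_curve$ratio, schedule,
                         mode = "frame_start")
  out <- input_function(idif$time, idif$whole_blood,
                        parent_plasma = idif$whole_blood * r,
                        provenance = provenance(idif))
  attr(out, "metabolite_mode") <- mode
  out
}

#' Image/arterial area-under-curve ratio
#'
#' Trapezoid AUC of the image-derived curve over `[0, t_end]` divided by the
#' AUC of the arterial curve, both evaluated on the union of their grids
#' (with the package's zero-origin extrapolation).
#'
#' @param image_curve,arterial_curve [input_function()]s.
#' @param t_end integration horizon in minutes (default 90).
#' @param value_col `"whole_blood"` or `"parent_plasma"`.
#' @return unitless ratio.
#' @export
auc_ratio <- function(image_curve, arterial_curve, t_end = 90,
                      value_col = c("whole_blood", "parent_plasma")) {
  value_col <- match.arg(value_col)
  assert_that(!is.null(image_curve[[value_col]]) && !is.null(arterial_curve[[value_col]]),
              paste("curves lack column", value_col))
  grid <- sort(unique(c(0, t_end, image_curve$time, arterial_curve$time)))
  grid <- grid[grid <= t_end + 1e-12]
  a_img <- trapz(grid, interpolate_curve(image_curve$time, image_curve[[value_col]], grid))
  a_art <- trapz(grid, interpolate_curve(arterial_curve$time, arterial_curve[[value_col]], grid))
  assert_that(a_art > 0, "arterial AUC is zero", "petidif_undefined_error")
  a_img / a_art
}

#' Scoring rule for image/blood VT ratios
#'
#' Each subject (replicate) contributes one mean ratio r: 2 points when
#' |r - 1| <= 0.05, 1 point when 0.05 < |r - 1| <= 0.10, 0 otherwise
#' (boundaries inclusive). The maximum is 2 points per subject.
#'
#' @param ratios_per_subject numeric vector of mean VT ratios.
#' @return list with `score`, `max_score`, `points` (per subject).
#' @export
vt_ratio_score <- function(ratios_per_subject) {
  assert_that(length(ratios_per_subject) > 0, "no ratios supplied")
  dev <- abs(ratios_per_subject - 1)
  eps <- 1e-9                       # boundaries are inclusive
  pts <- ifelse(dev <= 0.05 + eps, 2L, ifelse(dev <= 0.10 + eps, 1L, 0L))
  pts[!is.finite(dev)] <- 0L
  list(score = sum(pts), max_score = 2L * length(ratios_per_subject),
       points = pts)
}

#' Extract an IDIF from a simulated study with any of the seven methods
#'
#' Thin dispatcher used by [compare_methods()] and the pipeline commands.
#' `"arterial"` returns the sampled arterial truth on the frame grid
#' (self-comparison control).
#'
#' @param study a `phantom_study` from [simulate_phantom_study()].
#' @param method one of `arterial`, `chen`, `mourik`, `naganawa`, `su`,
#'   `parker`, `backes`, `croteau`.
#' @param rois optional precomputed [auto_carotid_rois()] result.
#' @param recovery_table optional precomputed [build_recovery_table()].
#' @param config optional per-method settings (named list; see Details).
#' @details Recognised `config` entries: `su_truncation`, `backes_params`,
#'   `croteau_diameter`, `ica_seed`, `ica_components`.
#' @return list with `input` and method-specific extras.
#' @export
extract_idif <- function(study, method, rois = NULL, recovery_table = NULL,
                         config = list()) {
  method <- match.arg(method, c("arterial", "chen", "mourik", "naganawa", "su",
                                "parker", "backes", "croteau"))
  sched <- study$schedule
  if (method == "arterial") {
    wb <- interpolate_curve(study$blood$time, study$blood$whole_blood, sched$mid)
    return(list(input = input_function(sched$mid, wb, provenance = "arterial")))
  }
  if (is.null(rois)) {
    rois <- auto_carotid_rois(study$image,
                              slab_fraction = config$slab_fraction %||% 1 / 3)
  }
  tpl_mode <- study$template$name
  switch(method,
    chen = chen_idif(study$image, rois, study$blood, mode = tpl_mode),
    mourik = mourik_idif(study$image, rois, study$blood),
    naganawa = naganawa_idif(study$image, study$blood,
                             n_components = config$ica_components %||% 3,
                             seed = config$ica_seed %||% study$spec$seed),
    su = su_idif(study$image, rois,
                 truncation_min = config$su_truncation %||% study$template$su_truncation),
    parker = parker_idif(study$image, rois, mode = tpl_mode),
    backes = {
      sq <- square_carotid_rois(study$image, rois)
      backes_idif(study$image, sq,
                  config$backes_params %||% study$template$backes_defaults)
    },
    croteau = {
      if (is.null(recovery_table)) recovery_table <- build_recovery_table(study$spec)
      croteau_idif(study$image, rois,
                   config$croteau_diameter %||% max(study$spec$carotid_diameters),
                   recovery_table)
    })
}

#' Compare IDIF methods on a simulated study
#'
#' For each requested method: extract the IDIF, metabolite-correct both the
#' image input and the arterial input with the template's parent/whole-blood
#' ratio curve (interpolated at frame starts), compute whole-blood and parent
#' AUC ratios over 0-90 min, compute grey-matter Logan VT with each input and
#' the image/blood VT ratio per region, and optionally fit the 2TCM
#' (Chen and Mourik by default). Per-method failures are recorded in the
#' `error` column rather than raised.
#'
#' @param study a `phantom_study`.
#' @param methods character vector of method tags.
#' @param config list: `t_star` (default 30), `do_2tcm` (character vector of
#'   methods, default `c("chen", "mourik")` when `two_tissue = TRUE`),
#'   `two_tissue` (default FALSE), `regions` (default
#'   [grey_matter_regions()]), plus the [extract_idif()] settings.
#' @return a `merit_report` tibble: one row per method with `wb_auc_ratio`,
#'   `parent_auc_ratio`, `mean_vt_ratio`, `vt_ratio_by_region` (list),
#'   `vt_2tcm_ratio`, `rate_ratios` (list), `error`.
#' @export
compare_methods <- function(study, methods = c("chen", "mourik"),
                            config = list()) {
  sched <- study$schedule
  t_star <- config$t_star %||% 30
  regions <- config$regions %||% grey_matter_regions()
  do2 <- if (isTRUE(config$two_tissue)) config$do_2tcm %||% c("chen", "mourik") else character(0)
  ratio_curve <- tibble(time = study$label_tacs$time,
                        ratio = parent_fraction_curve(study$template,
                                                      study$label_tacs$time))
  rois <- tryCatch(
    auto_carotid_rois(study$image,
                      slab_fraction = config$slab_fraction %||% 1 / 3),
    error = function(e) NULL)
  recovery_table <- if ("croteau" %in% methods) build_recovery_table(study$spec) else NULL

  # arterial reference on the frame grid, corrected the same way
  art_frame <- extract_idif(study, "arterial")$input
  art_q <- metabolite_correct(art_frame, ratio_curve, sched)
  tacs <- measure_region_tacs(study$image, study$label_map, regions)
  art_logan <- purrr::map_dbl(regions, function(rg) {
    logan_vt(tacs[[rg]], art_q, sched, t_star)$vt
  })
  names(art_logan) <- regions

  rows <- purrr::map(methods, function(m) {
    res <- tryCatch({
      ex <- extract_idif(study, m, rois = rois, recovery_table = recovery_table,
                         config = config)
      idif_q <- metabolite_correct(ex$input, ratio_curve, sched)
      wb_r <- auc_ratio(ex$input, art_frame, 90, "whole_blood")
      pp_r <- auc_ratio(idif_q, art_q, 90, "parent_plasma")
      vt_img <- purrr::map_dbl(regions, function(rg) {
        logan_vt(tacs[[rg]], idif_q, sched, t_star)$vt
      })
      vt_ratio <- vt_img / art_logan
      names(vt_ratio) <- regions
      row <- tibble(method = m, wb_auc_ratio = wb_r, parent_auc_ratio = pp_r,
                    mean_vt_ratio = mean(vt_ratio),
                    vt_ratio_by_region = list(vt_ratio),
                    vt_2tcm_ratio = NA_real_, vt_2tcm_by_region = list(NULL),
                    rate_ratios = list(NULL), error = NA_character_)
      if (m %in% do2) {
        two <- fit_2tcm_ratios(tacs, regions, idif_q, art_q, sched,
                               seed = study$spec$seed)
        row$vt_2tcm_ratio <- two$vt_ratio
        row$vt_2tcm_by_region <- list(two$vt_by_region)
        row$rate_ratios <- list(two$rate_ratios)
      }
      row
    }, error = function(e) {
      tibble(method = m, wb_auc_ratio = NA_real_, parent_auc_ratio = NA_real_,
             mean_vt_ratio = NA_real_, vt_ratio_by_region = list(NULL),
             vt_2tcm_ratio = NA_real_, vt_2tcm_by_region = list(NULL),
             rate_ratios = list(NULL), error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("merit_report", class(out))
  out
}

# image/blood ratios of 2TCM parameters, averaged over converged regions
fit_2tcm_ratios <- function(tacs, regions, idif_q, art_q, sched, seed = 1L) {
  per <- purrr::map(regions, function(rg) {
    f_img <- fit_two_tissue(tacs[[rg]], idif_q, sched, seed = seed)
    f_art <- fit_two_tissue(tacs[[rg]], art_q, sched, seed = seed)
    if (!f_img$converged || !f_art$converged) return(NULL)  # region excluded
    list(vt = f_img$vt / f_art$vt,
         rates = c(K1 = f_img$params$K1 / f_art$params$K1,
                   k2 = f_img$params$k2 / f_art$params$k2,
                   k3 = f_img$params$k3 / f_art$params$k3,
                   k4 = f_img$params$k4 / f_art$params$k4))
  })
  per <- purrr::compact(per)
  if (length(per) == 0) {
    return(list(vt_ratio = NA_real_, vt_by_region = numeric(0),
                rate_ratios = NULL))
  }
  vts <- purrr::map_dbl(per, "vt")
  list(vt_ratio = mean(vts), vt_by_region = vts,
       rate_ratios = colMeans(do.call(rbind, purrr::map(per, "rates"))))
}
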