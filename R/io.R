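#' Dynamic PET image
#'
#' Container for a 4D decay-corrected activity image (kBq/mL) with its voxel
#' size (mm) and frame schedule. The 4th array dimension indexes frames.
#'
#' @param voxels 4D numeric array, kBq/mL.
#' @param voxel_size voxel edge lengths in mm (length 3, all positive).
#' @param schedule a [frame_schedule()] whose length matches `dim(voxels)[4]`.
#' @return a `dynamic_image` object.
#' @export
dynamic_image <- function(voxels, voxel_size, schedule) {
  assert_that(length(dim(voxels)) == 4L, "voxels must be a 4D array")
  assert_that(all(is.finite(voxels)), "voxels must be finite")
  assert_that(length(voxel_size) == 3L && all(voxel_size > 0),
              "voxel_size must be 3 positive lengths (mm)")
  assert_that(inherits(schedule, "frame_schedule"), "schedule must be a frame_schedule")
  assert_that(dim(voxels)[4] == nrow(schedule),
              "4th dimension must equal the number of frames",
              "petidif_format_error")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels, %d frames, %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Label map (segmented anatomy)
#'
#' @param labels 3D integer array of region ids (0 = air/background outside
#'   the named regions).
#' @param names named character vector mapping label id (as name) to region
#'   name; must cover every nonzero id present.
#' @return a `label_map` object.
#' @export
label_map <- function(labels, names) {
  assert_that(length(dim(labels)) == 3L, "labels must be a 3D array")
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  assert_that(all(as.character(ids) %in% base::names(names)),
              "every nonzero label id must be named")
  structure(list(labels = labels, names = names), class = "label_map")
}

label_mask <- function(lmap, region) {
  ids <- as.integer(base::names(lmap$names)[lmap$names %in% region])
  array(lmap$labels %in% ids, dim = dim(lmap$labels))
}

#' Arterial blood sample table
#'
#' @param times sample times (minutes, strictly increasing).
#' @param whole_blood whole-blood activity (kBq/mL, nonnegative).
#' @param plasma total plasma activity (kBq/mL, nonnegative).
#' @param parent_fraction fraction of plasma activity that is unchanged
#'   parent, in `[0, 1]`.
#' @return a `blood_series` tibble with those four columns.
#' @export
blood_series <- function(times, whole_blood, plasma, parent_fraction) {
  assert_that(is_strictly_increasing(times), "times must be strictly increasing")
  assert_that(all(whole_blood >= 0) && all(plasma >= 0), "activities must be >= 0")
  assert_that(all(parent_fraction >= 0 & parent_fraction <= 1),
              "parent_fraction must lie in [0, 1]")
  out <- tibble(time = as.numeric(times),
                whole_blood = as.numeric(whole_blood),
                plasma = as.numeric(plasma),
                parent_fraction = as.numeric(parent_fraction))
  class(out) <- c("blood_series", class(out))
  out
}

#' Input function curve
#'
#' A whole-blood (and, after metabolite correction, parent-plasma) activity
#' curve on a time grid, tagged with the method that produced it.
#'
#' @param times minutes, strictly increasing.
#' @param whole_blood kBq/mL, nonnegative.
#' @param parent_plasma optional kBq/mL parent-in-plasma curve.
#' @param provenance one of `arterial`, `chen`, `mourik`, `naganawa`, `su`,
#'   `parker`, `backes`, `croteau`.
#' @return an `input_function` tibble (`time`, `whole_blood`, optionally
#'   `parent_plasma`) with a `provenance` attribute.
#' @export
input_function <- function(times, whole_blood, parent_plasma = NULL,
                           provenance = "arterial") {
  provenance <- match.arg(provenance, c("arterial", "chen", "mourik", "naganawa",
                                        "su", "parker", "backes", "croteau"))
  assert_that(length(times) > 0, "empty curve")
  assert_that(is_strictly_increasing(times), "times must be strictly increasing")
  assert_that(length(whole_blood) == length(times), "length mismatch")
  assert_that(all(whole_blood >= 0), "whole_blood must be >= 0")
  out <- tibble(time = as.numeric(times), whole_blood = as.numeric(whole_blood))
  if (!is.null(parent_plasma)) {
    assert_that(length(parent_plasma) == length(times), "length mismatch")
    assert_that(all(parent_plasma >= 0), "parent_plasma must be >= 0")
    out$parent_plasma <- as.numeric(parent_plasma)
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("input_function", class(out))
  out
}

#' @export
#' @rdname input_function
#' @param x an `input_function`.
provenance <- function(x) attr(x, "provenance")

#' Read / write a dynamic image as NIfTI plus JSON frame-timing sidecar
#'
#' The sidecar is a BIDS-like JSON object with `FrameStart` and
#' `FrameDuration` arrays in seconds.
#'
#' @param path 4D NIfTI file (`.nii`/`.nii.gz`).
#' @param sidecar_path JSON sidecar file.
#' @return [load_dynamic_image()] returns a validated [dynamic_image()];
#'   `save_dynamic_image()` writes the pair and returns `path` invisibly.
#' @export
load_dynamic_image <- function(path, sidecar_path) {
  nii <- read_nifti(path)
  assert_that(length(dim(nii$vol)) == 4L, "expected a 4D NIfTI",
              "petidif_format_error")
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  assert_that(all(c("FrameStart", "FrameDuration") %in% names(sc)),
              "sidecar must contain FrameStart and FrameDuration",
              "petidif_format_error")
  assert_that(length(sc$FrameStart) == dim(nii$vol)[4],
              "sidecar frame count does not match image frames",
              "petidif_format_error")
  schedule <- frame_schedule(sc$FrameStart / 60, sc$FrameDuration / 60)
  dynamic_image(nii$vol, nii$voxel_size, schedule)
}

#' @rdname load_dynamic_image
#' @param image a [dynamic_image()].
#' @export
save_dynamic_image <- function(image, path, sidecar_path) {
  assert_that(inherits(image, "dynamic_image"), "not a dynamic_image")
  write_nifti(image$voxels, path, image$voxel_size, datatype = "float64")
  jsonlite::write_json(
    list(FrameStart = image$schedule$start * 60,
         FrameDuration = image$schedule$duration * 60),
    sidecar_path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read / write a label map as NIfTI plus JSON region table
#'
#' @param path `.nii`/`.nii.gz` integer volume.
#' @param names_path JSON object mapping label id to region name.
#' @export
save_label_map <- function(lmap, path, names_path) {
  write_nifti(lmap$labels, path, c(1, 1, 1), datatype = "int32")
  jsonlite::write_json(as.list(lmap$names), names_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_label_map
#' @param lmap a [label_map()].
#' @export
load_label_map <- function(path, names_path) {
  nii <- read_nifti(path)
  nm <- unlist(jsonlite::read_json(names_path, simplifyVector = TRUE))
  label_map(array(as.integer(nii$vol), dim(nii$vol)), nm)
}

#' Read / write blood sample tables and input-function curves as CSV
#'
#' Blood tables use columns `time_min`, `whole_blood_kBq_ml`, `plasma_kBq_ml`,
#' `parent_fraction`. Curve tables carry the provenance tag in a `#` header
#' comment.
#'
#' @param path CSV file.
#' @return [load_blood_table()] returns a [blood_series()];
#'   [load_curve_table()] an [input_function()].
#' @export
load_blood_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_min", "whole_blood_kBq_ml", "plasma_kBq_ml", "parent_fraction")
  assert_that(all(need %in% names(df)),
              paste("blood table must have columns:", paste(need, collapse = ", ")),
              "petidif_format_error")
  blood_series(df$time_min, df$whole_blood_kBq_ml, df$plasma_kBq_ml,
               df$parent_fraction)
}

#' @rdname load_blood_table
#' @param blood a [blood_series()].
#' @export
save_blood_table <- function(blood, path) {
  df <- data.frame(time_min = blood$time, whole_blood_kBq_ml = blood$whole_blood,
                   plasma_kBq_ml = blood$plasma, parent_fraction = blood$parent_fraction)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname load_blood_table
#' @param input an [input_function()].
#' @export
save_curve_table <- function(input, path) {
  assert_that(inherits(input, "input_function"), "not an input_function")
  assert_that(nrow(input) > 0, "empty curve")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", provenance(input)), con)
  utils::write.csv(as.data.frame(input), con, row.names = FALSE)
  invisible(path)
}

#' @rdname load_blood_table
#' @export
load_curve_table <- function(path) {
  first <- readLines(path, n = 1)
  prov <- sub("^# provenance: *", "", first)
  assert_that(grepl("^# provenance:", first), "missing provenance header",
              "petidif_format_error")
  df <- utils::read.csv(path, comment.char = "#")
  input_function(df$time, df$whole_blood, df[["parent_plasma"]], provenance = prov)
}
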