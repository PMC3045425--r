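#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is a tibble with one row per frame and columns `start`,
#' `duration`, `mid` and `end`, all in minutes. Frames must be non-overlapping
#' with strictly increasing starts and positive durations.
#'
#' @param start_times frame start times in minutes.
#' @param durations frame durations in minutes.
#' @return a `frame_schedule` tibble.
#' @examples
#' frame_schedule(c(0, 0.5, 1), c(0.5, 0.5, 0.5))
#' @export
frame_schedule <- function(start_times, durations) {
  assert_that(length(start_times) == length(durations) && length(start_times) > 0,
              "start_times and durations must be equal-length and nonempty")
  assert_that(is_strictly_increasing(start_times), "frame starts must be strictly increasing")
  assert_that(all(durations > 0), "frame durations must be positive")
  ends <- start_times + durations
  assert_that(all(head(ends, -1) <= tail(start_times, -1) + 1e-9),
              "frames must not overlap")
  out <- tibble(
    start = as.numeric(start_times),
    duration = as.numeric(durations),
    mid = as.numeric(start_times + durations / 2),
    end = as.numeric(ends)
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Default clinical frame schedule
#'
#' The dynamic schedule used throughout: 6 frames of 30 s, 3 of 60 s, 2 of
#' 120 s and 5-min frames thereafter, truncated so that every frame ends
#' within `total_min` (default 90 min of analyzed scan), giving 27 frames.
#'
#' @param total_min analyzed scan length in minutes.
#' @return a [frame_schedule()].
#' @export
default_frame_schedule <- function(total_min = 90) {
  durations <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 17))
  starts <- cumsum(c(0, head(durations, -1)))
  keep <- (starts + durations) <= total_min + 1e-9
  frame_schedule(starts[keep], durations[keep])
}

#' Default arterial sampling schedule
#'
#' Radial-artery sampling times in minutes: every 15 s until 150 s, then at
#' 3, 4, 6, 8, 10, 15, 20, 30, 40, 50, 60, 75 and 90 minutes.
#'
#' @return numeric vector of sampling times (minutes).
#' @export
default_blood_sampling_times <- function() {
  c(seq(0.25, 2.5, by = 0.25), 3, 4, 6, 8, 10, 15, 20, 30, 40, 50, 60, 75, 90)
}

n_frames <- function(schedule) nrow(schedule)
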