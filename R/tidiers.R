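#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model summary, in the broom idiom.
#'
#' @param x a fitted object (`logan_fit`, `two_tissue_fit`, `chen_fit`,
#'   `triexp_fit`).
#' @param ... unused.
#' @name petidif-tidiers
NULL

#' @rdname petidif-tidiers
#' @export
tidy.logan_fit <- function(x, ...) {
  tibble(term = c("vt", "intercept"), estimate = c(x$vt, x$intercept))
}

#' @rdname petidif-tidiers
#' @export
glance.logan_fit <- function(x, ...) {
  tibble(vt = x$vt, intercept = x$intercept, t_star = x$t_star,
         n_points = x$n_points, r_squared = x$r_squared)
}

#' @rdname petidif-tidiers
#' @export
tidy.two_tissue_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(0), estimate = numeric(0)))
  }
  tibble(term = c("K1", "k2", "k3", "k4", "vt"),
         estimate = c(x$params$K1, x$params$k2, x$params$k3, x$params$k4, x$vt))
}

#' @rdname petidif-tidiers
#' @export
glance.two_tissue_fit <- function(x, ...) {
  tibble(vt = x$vt, converged = x$converged, objective = x$objective)
}

#' @rdname petidif-tidiers
#' @export
tidy.chen_fit <- function(x, ...) {
  tibble(term = c("RC", "SP"), estimate = c(x$RC, x$SP))
}

#' @rdname petidif-tidiers
#' @export
tidy.triexp_fit <- function(x, ...) {
  tibble(term = c(paste0("A", 1:3), paste0("lambda", 1:3)),
         estimate = c(x$amplitudes, x$rates))
}

#' Plot an input function
#'
#' Whole-blood (and parent-plasma, when present) activity against time.
#'
#' @param object an [input_function()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.input_function <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time",
                            names_to = "curve", values_to = "activity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$activity,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/mL)",
                  title = sprintf("Input function (%s)", provenance(object))) +
    ggplot2::theme_minimal()
}

#' Overlay an image-derived curve on the arterial reference
#'
#' The package's visual figure of merit: how well the image input matches
#' the height of the arterial peak and the slope of its tail.
#'
#' @param image_curve,arterial_curve [input_function()]s.
#' @param value_col column to plot.
#' @return a ggplot.
#' @export
plot_curve_comparison <- function(image_curve, arterial_curve,
                                  value_col = "whole_blood") {
  df <- dplyr::bind_rows(
    tibble(time = image_curve$time, activity = image_curve[[value_col]],
           source = sprintf("image (%s)", provenance(image_curve))),
    tibble(time = arterial_curve$time, activity = arterial_curve[[value_col]],
           source = "arterial"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$activity,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/mL)") +
    ggplot2::theme_minimal()
}

#' Plot a merit report
#'
#' Dot plot of AUC and VT ratios per method around the ideal ratio of 1.
#'
#' @param object a `merit_report` from [compare_methods()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.merit_report <- function(object, ...) {
  df <- object |>
    select("method", "wb_auc_ratio", "parent_auc_ratio", "mean_vt_ratio") |>
    tidyr::pivot_longer(-"method", names_to = "metric", values_to = "ratio")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$ratio,
                                   shape = .data$metric)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(0.9, 1.1), linetype = "dotted") +
    ggplot2::labs(y = "Image / arterial ratio", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
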