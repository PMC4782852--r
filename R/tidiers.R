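#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-slice measurements of a shagginess result
#'
#' @param x a `shagginess_result`.
#' @param ... unused.
#' @return tibble with one row per cross-section: `s_mm`, `A_mm`, `B_mm`,
#'   `C`, `irregularity`, `flags`, `used`.
#' @export
tidy.shagginess_result <- function(x, ...) {
  tibble::as_tibble(x$slices)
}

#' One-row summary of a shagginess result
#'
#' @param x a `shagginess_result`.
#' @param ... unused.
#' @return one-row tibble: `score`, `n_slices_used`, `n_slices_total`,
#'   `n_flagged`, `s_prox_mm`, `s_dist_mm`, `segment_length_mm`.
#' @export
glance.shagginess_result <- function(x, ...) {
  flagged <- sum(!is.na(x$slices$flags) & x$slices$flags != "")
  tibble::tibble(score = x$score,
                 n_slices_used = x$n_slices_used,
                 n_slices_total = nrow(x$slices),
                 n_flagged = flagged,
                 s_prox_mm = unname(x$s_range[1L]),
                 s_dist_mm = unname(x$s_range[2L]),
                 segment_length_mm = unname(diff(x$s_range)))
}

#' Plot the per-slice irregularity profile
#'
#' Irregularity `(C - 1) * 100` along the centerline arc length, with the
#' scored range shaded and the score drawn as a horizontal reference.
#'
#' @param object a `shagginess_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.shagginess_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$irregularity), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mm, y = .data$irregularity)) +
    ggplot2::annotate("rect", xmin = object$s_range[1L], xmax = object$s_range[2L],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$used), size = 1) +
    ggplot2::geom_hline(yintercept = object$score, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
                                name = "in score") +
    ggplot2::labs(x = "arc length along centerline (mm)",
                  y = "irregularity (C - 1) x 100",
                  title = sprintf("Shagginess score %.3f over %d slices",
                                  object$score, object$n_slices_used)) +
    ggplot2::theme_minimal()
}

#' Plot a traced luminal contour
#'
#' @param x a [contour()].
#' @param fan optional [diameter_fan()] whose mean circle is overlaid (the
#'   dotted reference circle of the circularity ratio).
#' @return a ggplot object.
#' @export
plot_contour <- function(x, fan = NULL) {
  p <- as.matrix(x)
  df <- tibble::tibble(x = c(p[, 1L], p[1L, 1L]), y = c(p[, 2L], p[1L, 2L]))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(fan)) {
    th <- seq(0, 2 * pi, length.out = 361L)
    circ <- tibble::tibble(x = fan$center[1L] + fan$mean_diameter / 2 * cos(th),
                           y = fan$center[2L] + fan$mean_diameter / 2 * sin(th))
    g <- g + ggplot2::geom_path(data = circ, linetype = "dotted", color = "red")
  }
  g
}

#' @importFrom rlang .data
NULL
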