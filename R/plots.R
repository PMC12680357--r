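#' Histogram of a surface-distance map
#'
#' @param object a `sac_distance_map`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sac_distance_map <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tibble::tibble(distance_mm = object$distance_mm),
                  ggplot2::aes(x = .data$distance_mm)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = attr(object, "mean"), colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "surface distance (mm)", y = "vertices",
                  subtitle = sprintf("mean %.2f mm, 95th %.2f mm, max %.2f mm",
                                     attr(object, "mean"), attr(object, "p95"),
                                     attr(object, "max"))) +
    ggplot2::theme_minimal()
}

#' Parameter-space view of a DoE plan
#'
#' @param object a `sac_doe_plan`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sac_doe_plan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$A, y = .data$AP,
                                       size = .data$LAT,
                                       colour = .data$ant_model)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::labs(x = "A (anterior notch ratio)", y = "AP (posterior notch ratio)",
                  size = "LAT", colour = "anterior\nspring") +
    ggplot2::theme_minimal()
}
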