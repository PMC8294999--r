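# ggplot2 views of the main result types.

matrix_to_long <- function(M, value_name = "value") {
  out <- tibble::tibble(
    row = rep(seq_len(nrow(M)), times = ncol(M)),
    col = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.vector(M)
  )
  names(out)[3] <- value_name
  out
}

#' Plot a phantom case
#'
#' Gray intensity raster with the ground-truth mask outlined.
#'
#' @param object A `phantom_case`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_case <- function(object, ...) {
  df <- matrix_to_long(object$image, "intensity")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Phantom (gold level %s)", object$gold_label),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (sum(object$mask) > 0) {
    dm <- matrix_to_long(object$mask, "mask")
    p <- p + ggplot2::geom_contour(
      data = dm, ggplot2::aes(z = .data$mask), breaks = 0.5,
      colour = "red", linewidth = 0.4)
  }
  p
}

#' Plot a hot-spot probability map
#'
#' @param object A `prob_map` from [scan_probability_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prob_map <- function(object, ...) {
  df <- matrix_to_long(unclass(object), "probability")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Hot-spot probability map", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Chan-Vese segmentation result
#'
#' Final mask plus the energy trace as a two-panel summary (mask panel only
#' when the trace is empty).
#'
#' @param object A `cv_segmentation` from [segment_cv()].
#' @param ... Unused.
#' @return A ggplot object (the mask raster; the energy trace is drawn when
#'   `which = "energy"`).
#' @param which `"mask"` (default) or `"energy"`.
#' @export
autoplot.cv_segmentation <- function(object, which = c("mask", "energy"), ...) {
  which <- match.arg(which)
  if (which == "energy") {
    df <- tibble::tibble(iteration = seq_along(object$diagnostics$energy_trace),
                         energy = object$diagnostics$energy_trace)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$energy)) +
        ggplot2::geom_line() +
        ggplot2::labs(title = "Chan-Vese energy trace",
                      x = "iteration", y = "fitting energy") +
        ggplot2::theme_minimal()
    )
  }
  df <- matrix_to_long(object$mask, "mask")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$mask))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "red"),
                               name = "mask") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Chan-Vese segmentation", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation benchmark report
#'
#' Per-case Dice distribution by method, ordered by mean Dice.
#'
#' @param object An `eval_report` from [benchmark_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ord <- object$summary$method
  df <- dplyr::mutate(object$per_case,
                      method = factor(.data$method, levels = rev(ord)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(title = "Per-case Dice by segmentation method",
                  x = NULL, y = "Dice") +
    ggplot2::theme_minimal()
}
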