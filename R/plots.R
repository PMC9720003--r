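#' Plot a trajectory of daily PB fractions
#'
#' Line plot of the PB fraction over days, with drug days marked by a rug
#' along the axis.
#'
#' @param object A trajectory from [simulate_trajectory()].
#' @param log10 Show the fraction on a log10 axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pb_trajectory <- function(object, log10 = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$x)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = object[object$drug == 1, , drop = FALSE],
                      sides = "b", colour = "firebrick", alpha = 0.4) +
    ggplot2::labs(x = "day", y = "plasmid-bearing fraction") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Heatmap of a cost-by-copy-number stability sweep
#'
#' Tiles of log10 AUC across the copy-number / per-copy-cost grid of a
#' [stability_sweep()].
#'
#' @param object A `pb_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pb_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$per_copy_cost,
                               fill = log10(pmax(.data$auc, 1e-12)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 AUC") +
    ggplot2::labs(x = "plasmid copy number", y = "per-copy cost / day") +
    ggplot2::theme_minimal()
}

#' Plot a minimum-selective-pressure curve
#'
#' MSalpha against copy number from [msalpha_curve()] output; combine several
#' costs by row-binding their tibbles with a `per_copy_cost` column.
#'
#' @param df Output of [msalpha_curve()], optionally with a `per_copy_cost`
#'   column distinguishing curves.
#' @return A ggplot.
#' @export
plot_msalpha_curve <- function(df) {
  stopifnot(all(c("n", "ms_alpha") %in% names(df)))
  aes <- if ("per_copy_cost" %in% names(df)) {
    ggplot2::aes(x = .data$n, y = .data$ms_alpha,
                 colour = factor(.data$per_copy_cost))
  } else {
    ggplot2::aes(x = .data$n, y = .data$ms_alpha)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "plasmid copy number", y = "minimum selective pressure",
                  colour = "per-copy cost") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
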