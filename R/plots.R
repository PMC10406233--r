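#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a motion series with its censoring threshold
#'
#' @param object an `enorm_series`.
#' @param threshold_mm optional censoring threshold to draw.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.enorm_series <- function(object, threshold_mm = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$enorm)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "volume", y = "volume-to-volume motion (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_mm)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_mm,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Heatmap of an FC matrix
#'
#' @param object an `fc_matrix`.
#' @param ... unused.
#' @return A ggplot tile map of edge values.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  df <- expand.grid(i = seq_along(object$region_ids),
                    j = seq_along(object$region_ids))
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = if (object$fisher_z) "z" else "r") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "region", y = "region") +
    ggplot2::theme_minimal()
}

#' Histogram of QC-FC edge correlations
#'
#' @param object a `qcfc_result`.
#' @param ... unused.
#' @return A ggplot column chart of the QC-FC histogram, with the mean
#'   marked.
#' @export
autoplot.qcfc_result <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$mid[1:2]),
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_r, colour = "firebrick") +
    ggplot2::labs(x = "QC-FC edge correlation", y = "edges") +
    ggplot2::theme_minimal()
}

#' Similarity-versus-motion panels for a threshold sweep
#'
#' One facet per (threshold, band) cell, each showing per-subject similarity
#' to the group mean against mean motion; the pattern across facets is what
#' drives the choice of censoring threshold.
#'
#' @param object a `sweep_table`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sweep_table <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$pearson))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_enorm_mm,
                                   y = .data$pearson)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.4) +
    ggplot2::facet_grid(band ~ threshold_mm,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mean volume-to-volume motion (mm)",
                  y = "similarity to group mean FC (r)") +
    ggplot2::theme_minimal()
}
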