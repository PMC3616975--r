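# ggplot2 visualisations of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a residue coupling matrix
#'
#' @param object a `td_coupling`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.td_coupling <- function(object, ...) {
  df <- expand.grid(residue_i = object$residues,
                    residue_j = object$residues,
                    stringsAsFactors = FALSE)
  df$coupling <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_i, y = .data$residue_j,
                                   fill = .data$coupling)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "coupling\n(nats)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Residue torsion-coupling matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' RMSF profile plot
#'
#' @param object a `td_rmsf`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.td_rmsf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_rmsf"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Time-series monitor plot (distance or segment RMSD)
#'
#' @param object a `td_series`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.td_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = object$label[1]) +
    ggplot2::theme_minimal()
}

#' Clustering penalty-trace plot
#'
#' Shows the combined NMRCLUST-style penalty across merge steps with the
#' chosen step marked.
#'
#' @param object a `td_clust`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.td_clust <- function(object, ...) {
  ggplot2::ggplot(object$penalty_trace,
                  ggplot2::aes(x = .data$step, y = .data$penalty)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_step,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "merge step", y = "combined penalty") +
    ggplot2::theme_minimal()
}
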