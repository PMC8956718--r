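#' Plot a cohort-size / unfairness trade-off sweep
#'
#' CTS size against the unfairness slack alpha; the dashed line marks the
#' first alpha attaining the minimum CTS size.
#'
#' @param object an [alpha_sweep()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.alpha_sweep <- function(object, ...) {
  best <- attr(object, "best_alpha")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$cts_size)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = object$alpha) +
    ggplot2::labs(x = expression(alpha ~ "(unfairness slack, extra targets per patient)"),
                  y = "cohort target set size",
                  title = "Cohort size vs per-patient fairness slack") +
    ggplot2::theme_minimal()
}

#' Plot gene frequencies across sampled optimal solutions
#'
#' @param object a [gene_frequencies()] table.
#' @param top show at most this many genes (by frequency).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.frequency_table <- function(object, top = 20, ...) {
  df <- object$genes |>
    dplyr::arrange(dplyr::desc(.data$frequency)) |>
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, .data$frequency),
                                   y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of sampled optimal solutions",
                  title = paste0("Gene occurrence over ", object$n_solutions,
                                 " sampled optima")) +
    ggplot2::theme_minimal()
}

#' Plot per-patient ITS sizes over replicates
#'
#' Boxplot of individual target set sizes per patient, one point per
#' replicate, mirroring the usual presentation of replicate variation.
#'
#' @param results tibble of tidied per-replicate ITS results (columns
#'   `patient_id`, `its_size`).
#' @return a ggplot object.
#' @export
plot_its_sizes <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$patient_id, y = .data$its_size)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "patient", y = "individual target set size") +
    ggplot2::theme_minimal()
}
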