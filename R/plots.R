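#' Plot a run's retention trajectories
#'
#' One grey line per gene (retention vs iteration) with the mean retention
#' overlaid in blue, the standard view of a transcription-arrest decay
#' simulation.
#'
#' @param object a `comics_run`.
#' @param max_genes cap on individual gene lines (sampled deterministically
#'   by name order when exceeded).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.comics_run <- function(object, max_genes = 500L, ...) {
  long <- tidy(object)
  shown <- head(sort(unique(long$gene)), max_genes)
  mean_line <- long |>
    group_by(.data$iteration) |>
    summarise(retention = mean(.data$retention), .groups = "drop")
  ggplot2::ggplot(long[long$gene %in% shown, ],
                  ggplot2::aes(.data$iteration, .data$retention)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene),
                       colour = "grey70", linewidth = 0.2, alpha = 0.6) +
    ggplot2::geom_line(data = mean_line, colour = "steelblue",
                       linewidth = 1) +
    ggplot2::labs(x = "iteration", y = "retention (%)",
                  title = "mRNA retention along the simulation") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a screen's retention matrix
#'
#' Genes x families tile map of final retention under single-family
#' overexpression.
#'
#' @param object a `comics_screen`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.comics_screen <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$family, .data$gene,
                                 fill = .data$retention)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 50,
                                  limits = c(0, 100)) +
    ggplot2::labs(x = "overexpressed family", y = "gene",
                  fill = "retention (%)",
                  title = sprintf("Retention under x%g overexpression",
                                  object$factor)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Retention of targets vs non-targets across overexpression factors
#'
#' Summary plot for a factor sweep of one family: mean final retention of
#' the family's target genes and of all other genes, per factor.
#'
#' @param sweep tibble with columns `factor`, `gene`, `retention` (e.g. from
#'   repeated [run_comics()] calls over [overexpress()]ed profiles).
#' @param interactions a `comics_interactions` table.
#' @param family the swept family.
#' @return a ggplot object.
#' @export
plot_factor_sweep <- function(sweep, interactions, family) {
  part <- partition_targets(unique(sweep$gene), interactions, family)
  sweep |>
    mutate(group = ifelse(.data$gene %in% part$targets,
                          "targets", "non-targets")) |>
    group_by(.data$factor, .data$group) |>
    summarise(retention = mean(.data$retention), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(factor(.data$factor), .data$retention,
                                 colour = .data$group,
                                 group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "overexpression factor", y = "mean retention (%)",
                  colour = NULL,
                  title = paste0("Overexpression sweep: ", family)) +
    ggplot2::theme_minimal()
}
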