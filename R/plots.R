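# Diagnostic figures for the main result tables.

#' Plot per-condition viability with SEM error bars
#'
#' Mirrors the usual screen figure: percent-of-control viability per
#' condition, mean plus/minus SEM, controls highlighted.
#'
#' @param summaries tibble from [normalize_to_control()].
#' @return a ggplot.
#' @export
plot_viability <- function(summaries) {
  summaries <- as_tibble(summaries)
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = stats::reorder(.data$condition_id,
                                                  -.data$mean_viability),
                               y = .data$mean_viability,
                               colour = .data$is_control)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_viability - .data$sem,
                                          ymax = .data$mean_viability + .data$sem),
                             size = 0.3) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "viability (% of control)", colour = "control") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot proliferative defects against the lethality threshold
#'
#' One point per gene pair, defect (predicted minus observed viability)
#' on the y axis, the 3x-average-SEM threshold as a dashed line, synthetic
#' lethal calls coloured.
#'
#' @param calls tibble from [call_interactions()].
#' @return a ggplot.
#' @export
plot_interaction_calls <- function(calls) {
  calls <- as_tibble(calls)
  calls$pair <- paste(calls$central_gene, calls$cancer_gene, sep = "+")
  ggplot2::ggplot(calls, ggplot2::aes(x = stats::reorder(.data$pair,
                                                         -.data$defect),
                                      y = .data$defect,
                                      colour = .data$is_synthetic_lethal)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "proliferative defect (% viability)",
                  colour = "synthetic lethal") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot the bipartite conservation network as a matrix
#'
#' Central genes by cancer genes, each cell coloured by its conservation
#' class (conserved, yeast-only, human-only, none) — the matrix view of the
#' network figure's line styles.
#'
#' @param edges edge tibble with both flags.
#' @return a ggplot.
#' @export
plot_conservation_matrix <- function(edges) {
  edges <- as_tibble(edges)
  edges$class <- dplyr::case_when(
    edges$yeast_predicted & edges$human_observed ~ "conserved",
    edges$yeast_predicted ~ "yeast only",
    edges$human_observed ~ "human only",
    TRUE ~ "none"
  )
  edges$class <- factor(edges$class,
                        levels = c("conserved", "yeast only", "human only",
                                   "none"))
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$cancer, y = .data$central,
                                      fill = .data$class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(conserved = "grey35",
                                          `yeast only` = "seagreen3",
                                          `human only` = "darkorange",
                                          none = "grey92")) +
    ggplot2::labs(x = "cancer-mutated gene", y = "central gene",
                  fill = "interaction") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
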