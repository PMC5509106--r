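#' Plot relative expression profiles across stages
#'
#' @param profiles Tibble with columns `gene`, `stage`, `x` and optionally
#'   `node` or `species` (used for facetting).
#' @param genes Optional subset of gene ids to display.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, genes = NULL) {
  if (!is.null(genes)) profiles <- dplyr::filter(profiles, .data$gene %in% genes)
  facet_var <- intersect(c("node", "species"), names(profiles))[1]
  p <- ggplot2::ggplot(profiles, ggplot2::aes(.data$stage, .data$x,
                                              colour = .data$gene, group = .data$gene)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "developmental stage", y = "relative expression (min stage = 1)") +
    ggplot2::theme_minimal()
  if (!is.na(facet_var)) p <- p + ggplot2::facet_wrap(facet_var)
  p
}

#' Plot the divergence-score distribution with the priority cut
#'
#' @param scores Output of [divergence_scores()].
#' @param top_fraction Cut fraction drawn as a vertical line on the A-up
#'   score quantile.
#' @return A ggplot object.
#' @export
plot_divergence <- function(scores, top_fraction = 0.10) {
  cut_a <- stats::quantile(scores$score_a_up, 1 - top_fraction, names = FALSE)
  ggplot2::ggplot(scores, ggplot2::aes(.data$score_a_up, fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = cut_a, linetype = 2) +
    ggplot2::labs(x = "largest evolved increase in stage-to-stage change",
                  y = "genes") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @param object A `consensus_network`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.consensus_network <- function(object, ...) {
  genes <- attr(object, "genes")
  theta <- seq(0, 2 * pi, length.out = length(genes) + 1L)[seq_along(genes)]
  lay <- tibble::tibble(gene = genes, px = cos(theta), py = sin(theta))
  ed <- tidy(object) |>
    dplyr::left_join(lay, by = c(from = "gene")) |>
    dplyr::rename(x = "px", y = "py") |>
    dplyr::left_join(lay, by = c(to = "gene")) |>
    dplyr::rename(xend = "px", yend = "py")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend, linewidth = .data$confidence),
                          arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt")),
                          colour = "grey40") +
    ggplot2::geom_label(data = lay, ggplot2::aes(.data$px, .data$py, label = .data$gene)) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), limits = c(0, 1)) +
    ggplot2::labs(title = attr(object, "node_id")) +
    ggplot2::theme_void()
}
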