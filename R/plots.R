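#' Histogram of network-effect scores
#'
#' @param scores Tibble from [network_effect_scores()].
#' @param threshold Optional influenced-gene cut drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, threshold = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::labs(x = "network-effect score S", y = "genes") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Dot plot of ranked pathways
#'
#' Mean member score against pathway, sized by the number of top-scored
#' genes mapped into the pathway and coloured by enrichment significance.
#'
#' @param results Ranked tibble from [rank_pathways()] (or
#'   [pathway_analysis()]).
#' @param top_n Pathways shown, default 20.
#' @return A ggplot object.
#' @export
plot_pathway_ranking <- function(results, top_n = 20) {
  d <- head(results, top_n) |>
    dplyr::mutate(pathway = factor(.data$pathway,
                                   levels = rev(.data$pathway)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_score, y = .data$pathway,
                                  size = .data$mapped_genes,
                                  colour = -log10(.data$enrichment_q))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean network-effect score", y = NULL,
                  size = "top genes\nin pathway",
                  colour = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}

#' @describeIn sa_cluster Cluster-size bar chart with DE-gene counts
#'   overlaid.
#' @param object An `sa_clustering` object.
#' @method autoplot sa_clustering
#' @export
autoplot.sa_clustering <- function(object, ...) {
  d <- object$assignment |>
    dplyr::count(.data$cluster, .data$is_de)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$cluster), y = .data$n,
                                  fill = .data$is_de)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               labels = c("other", "DE gene"),
                               name = NULL) +
    ggplot2::labs(x = "cluster", y = "genes",
                  title = sprintf("%d clusters, Q = %.3f", object$k,
                                  object$modularity)) +
    ggplot2::theme_minimal()
}

#' Plot a subnetwork with a force-directed layout
#'
#' @param sub A `subnetwork` from [extract_subnetwork()].
#' @param seed Layout seed.
#' @return A ggplot object; DE genes drawn in red.
#' @export
plot_subnetwork <- function(sub, seed = 1L) {
  g <- as_igraph(sub)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(sub$nodes, x = xy[, 1], y = xy[, 2])
  edges <- sub$edges |>
    dplyr::left_join(dplyr::select(nodes, "symbol", xa = "x", ya = "y"),
                     by = c(gene_a = "symbol")) |>
    dplyr::left_join(dplyr::select(nodes, "symbol", xb = "x", yb = "y"),
                     by = c(gene_b = "symbol"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$weight),
                          colour = "grey70", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.1, 0.8)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$is_de), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 labels = c("influenced", "DE gene"),
                                 name = NULL) +
    ggplot2::theme_void()
}
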