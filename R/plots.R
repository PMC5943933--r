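#' Plot the edge-weight distribution of a fitness network
#'
#' @param object A [fitness_network()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fitness_network <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy.fitness_network(object), ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "edge weight w(d,u)", y = "edges",
                  title = "Fitness-network edge weights") +
    ggplot2::theme_minimal()
}

#' Plot edge counts of a fitness network across weight cutoffs
#'
#' @param fn A [fitness_network()].
#' @param cutoffs Weight cutoffs; default the 0.005-step sweep from 0
#'   to 1.
#' @return A ggplot object.
#' @export
plot_cutoff_sweep <- function(fn, cutoffs = weight_cutoffs()) {
  counts <- purrr::map_int(cutoffs, ~ nrow(filter_by_weight(fn, .x)))
  ggplot2::ggplot(tibble::tibble(cutoff = cutoffs, n_edges = counts),
                  ggplot2::aes(x = .data$cutoff, y = .data$n_edges)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "weight cutoff", y = "edges retained",
                  title = "Edges under weight cutoffs") +
    ggplot2::theme_minimal()
}

#' Plot co-occurring and mutually exclusive edge fractions across cutoffs
#'
#' @param classified Output of [classify_network_edges()].
#' @return A ggplot object.
#' @export
plot_edge_classification <- function(classified) {
  long <- tidyr::pivot_longer(classified,
                              c("frac_cooccur", "frac_exclusive"),
                              names_to = "kind", values_to = "fraction")
  long$kind <- dplyr::recode(long$kind, frac_cooccur = "co-occurring",
                             frac_exclusive = "mutually exclusive")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$fraction,
                                     colour = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "weight cutoff", y = "fraction of edges", colour = NULL,
                  title = "Mutation support of fitness edges") +
    ggplot2::theme_minimal()
}

#' Plot indegree ratios with the core threshold
#'
#' @param fn A [fitness_network()].
#' @param delta Core threshold drawn as a reference line; default 0.7.
#' @return A ggplot object.
#' @export
plot_indegree_ratio <- function(fn, delta = 0.7) {
  idr <- indegree_ratio(fn)
  idr$core <- idr$idr > delta
  ggplot2::ggplot(idr, ggplot2::aes(x = stats::reorder(.data$gene, .data$idr),
                                    y = .data$idr, fill = .data$core)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = delta, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "indegree ratio", fill = "core",
                  title = "Indegree ratios and fitness core") +
    ggplot2::theme_minimal()
}
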