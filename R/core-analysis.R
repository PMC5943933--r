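#' Indegree ratio of fitness-network nodes
#'
#' For a node u, IDR(u) = indegree(u) / (indegree(u) + outdegree(u)),
#' with unweighted edge counts. Nodes of a fitness network always have at
#' least one incident edge, so the ratio is defined for every node.
#'
#' @param fn A [fitness_network()].
#' @param genes Optional character vector restricting the result; genes
#'   absent from the network raise an error.
#' @return A tibble with columns `gene`, `indegree`, `outdegree`, `idr`.
#' @export
indegree_ratio <- function(fn, genes = NULL) {
  nodes <- fn_nodes(fn)
  if (!is.null(genes)) {
    missing <- setdiff(genes, nodes)
    if (length(missing)) {
      rlang::abort(paste0("Gene(s) not in fitness network: ",
                          paste(missing, collapse = ", ")))
    }
  }
  indeg <- table(factor(fn$target, levels = nodes))
  outdeg <- table(factor(fn$source, levels = nodes))
  out <- tibble::tibble(gene = nodes,
                        indegree = as.integer(indeg),
                        outdegree = as.integer(outdeg))
  out$idr <- out$indegree / (out$indegree + out$outdegree)
  if (!is.null(genes)) out <- out[match(genes, out$gene), ]
  out
}

#' Fitness core: indegree-dominated genes
#'
#' A gene belongs to the fitness core when its indegree ratio strictly
#' exceeds delta; the default delta is 0.7.
#'
#' @param fn A [fitness_network()].
#' @param delta Threshold in [0, 1]; membership requires IDR > delta
#'   (strict).
#' @return Character vector of core genes.
#' @export
fitness_core <- function(fn, delta = 0.7) {
  stopifnot(delta >= 0, delta <= 1)
  idr <- indegree_ratio(fn)
  sort(idr$gene[idr$idr > delta])
}

#' Partition fitness-network edges by core membership of their endpoints
#'
#' Nodes are split into non-core (class I) and core (class II); edges fall
#' into four disjoint classes: C1 within non-core, C2 within core, C3 from
#' non-core into core, C4 from core out to non-core.
#'
#' @param fn A [fitness_network()].
#' @param core Character vector of core genes (subset of the network
#'   nodes).
#' @return A tibble of class `edge_partition`: the edges of `fn` with an
#'   added `class` column in {"C1","C2","C3","C4"}; attributes `core` and
#'   `noncore`.
#' @export
partition_edges <- function(fn, core) {
  nodes <- fn_nodes(fn)
  if (length(setdiff(core, nodes))) rlang::abort("`core` must be a subset of network nodes.")
  s_core <- fn$source %in% core
  t_core <- fn$target %in% core
  out <- tibble::as_tibble(unclass_fn(fn))
  out$class <- dplyr::case_when(
    !s_core & !t_core ~ "C1",
    s_core & t_core ~ "C2",
    !s_core & t_core ~ "C3",
    TRUE ~ "C4"
  )
  class(out) <- c("edge_partition", class(tibble::tibble()))
  attr(out, "core") <- sort(intersect(nodes, core))
  attr(out, "noncore") <- sort(setdiff(nodes, core))
  out
}

#' Sample coverage of a gene set
#'
#' The number of tumor samples altered in at least one gene of the set.
#'
#' @param genes Character vector of genes.
#' @param mut A [mutation_profile()].
#' @return Integer sample count.
#' @export
coverage <- function(genes, mut) length(altered_samples(mut, genes))

coverage_result <- function(denominator, numerator) {
  stopifnot(numerator >= 0, numerator <= denominator)
  out <- tibble::tibble(denominator = as.integer(denominator),
                        numerator = as.integer(numerator),
                        ratio = numerator / denominator)
  class(out) <- c("coverage_result", class(out))
  out
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("(%d, %d, %.4f)\n", x$denominator, x$numerator, x$ratio))
  invisible(x)
}

#' Relative coverage of a fitness core
#'
#' Fraction of the samples covered by non-core genes that are also
#' covered by core genes:
#' `|Gamma(core) ∩ Gamma(noncore)| / |Gamma(noncore)|`.
#'
#' @param core Character vector of core genes.
#' @param noncore Character vector of non-core genes (disjoint from
#'   `core`).
#' @param mut A [mutation_profile()].
#' @return A one-row `coverage_result` tibble: `denominator`, `numerator`,
#'   `ratio` (full precision; print shows 4 decimals).
#' @export
relative_coverage <- function(core, noncore, mut) {
  if (length(intersect(core, noncore))) rlang::abort("`core` and `noncore` must be disjoint.")
  g_core <- altered_samples(mut, core)
  g_non <- altered_samples(mut, noncore)
  if (length(g_non) == 0L) rlang::abort("Non-core genes cover no samples: ratio undefined.")
  coverage_result(length(g_non), length(intersect(g_core, g_non)))
}

#' Absolute coverage of a fitness core
#'
#' Fraction of all covered samples that core genes cover:
#' `|Gamma(core)| / |Gamma(core) ∪ Gamma(noncore)|`.
#'
#' @inheritParams relative_coverage
#' @return A one-row `coverage_result` tibble.
#' @export
absolute_coverage <- function(core, noncore, mut) {
  if (length(intersect(core, noncore))) rlang::abort("`core` and `noncore` must be disjoint.")
  g_core <- altered_samples(mut, core)
  g_non <- altered_samples(mut, noncore)
  denom <- length(union(g_core, g_non))
  if (denom == 0L) rlang::abort("No gene covers any sample: ratio undefined.")
  coverage_result(denom, length(g_core))
}

#' Edge and co-occurring-edge counts per edge class across weight cutoffs
#'
#' For each weight cutoff, edges surviving the cutoff are partitioned into
#' the four core/non-core classes; the count of edges and of
#' significantly co-occurring edges is reported per class, with a
#' one-sided Fisher enrichment p-value asking whether present edges are
#' over-represented in the class relative to all possible ordered pairs
#' of network nodes. The 2x2 table is {edge present, absent} x {ordered
#' pair in class, not}, over all ordered node pairs of the unfiltered
#' network; this contingency construction is a package design choice.
#'
#' @param fn A [fitness_network()].
#' @param core Character vector of core genes.
#' @param mut A [mutation_profile()].
#' @param alpha Significance level for per-edge co-occurrence calls.
#' @param cutoffs Numeric vector of weight cutoffs.
#' @return A tibble with columns `cutoff`, `class`, `n_edges`,
#'   `n_cooccur`, `p_enrich`.
#' @export
edge_class_counts <- function(fn, core, mut, alpha = 0.05,
                              cutoffs = c(0, 0.01, 0.05)) {
  nodes <- fn_nodes(fn)
  part <- partition_edges(fn, core)
  cls <- c("C1", "C2", "C3", "C4")
  # class sizes over all possible ordered pairs (no self-pairs)
  n_core <- length(attr(part, "core"))
  n_non <- length(attr(part, "noncore"))
  pair_universe <- c(C1 = n_non * (n_non - 1L), C2 = n_core * (n_core - 1L),
                     C3 = n_non * n_core, C4 = n_core * n_non)
  n_pairs <- sum(pair_universe)
  co <- edge_cooccurrence_status(fn, mut, alpha)
  purrr::map_dfr(cutoffs, function(ct) {
    keep <- part$weight >= ct
    sub <- part[keep, ]
    co_sub <- co[keep]
    n_present <- nrow(sub)
    purrr::map_dfr(cls, function(k) {
      in_k <- sub$class == k
      p <- if (n_present == 0L || pair_universe[[k]] == 0L) NA_real_ else
        stats::fisher.test(matrix(c(sum(in_k), n_present - sum(in_k),
                                    pair_universe[[k]] - sum(in_k),
                                    n_pairs - n_present - (pair_universe[[k]] - sum(in_k))),
                                  nrow = 2L),
                           alternative = "greater")$p.value
      tibble::tibble(cutoff = ct, class = k, n_edges = sum(in_k),
                     n_cooccur = sum(in_k & co_sub == "co-occurring"),
                     p_enrich = p)
    })
  })
}

# Per-edge co-occurrence status vector (delegates to the validation module).
edge_cooccurrence_status <- function(fn, mut, alpha = 0.05) {
  if (nrow(fn) == 0L) return(character())
  vapply(seq_len(nrow(fn)), function(i) {
    cooccurrence_test(fn$source[i], fn$target[i], mut, alpha)$status
  }, character(1))
}
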