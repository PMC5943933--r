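#' Construct a fitness network from an edge tibble
#'
#' A fitness network is a directed simple graph over driver genes stored
#' as a tibble of weighted edges (`source`, `target`, `weight`), with
#' weights in (0, 1]. Antiparallel edges are allowed; duplicate ordered
#' pairs and non-positive weights are not. Nodes are the edge endpoints.
#'
#' @param edges Data frame with columns `source`, `target`, `weight`.
#' @return A tibble of class `fitness_network`.
#' @export
fitness_network <- function(edges = tibble::tibble(source = character(),
                                                   target = character(),
                                                   weight = double())) {
  edges <- tibble::as_tibble(edges)[, c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.double(edges$weight)
  if (any(edges$source == edges$target)) rlang::abort("Self-loops are not allowed.")
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    rlang::abort("Edge weights must lie in (0, 1].")
  }
  if (anyDuplicated(paste(edges$source, edges$target))) {
    rlang::abort("Duplicate ordered pairs in fitness network.")
  }
  edges <- dplyr::arrange(edges, .data$source, .data$target)
  class(edges) <- c("fitness_network", class(tibble::tibble()))
  edges
}

#' Nodes of a fitness network
#' @param fn A [fitness_network()].
#' @return Character vector of driver genes with at least one edge.
#' @export
fn_nodes <- function(fn) sort(unique(c(fn$source, fn$target)))

# igraph view of a fitness network (directed, weighted).
fn_igraph <- function(fn) {
  igraph::graph_from_data_frame(as.data.frame(fn[, c("source", "target")]),
                                directed = TRUE)
}

#' @export
print.fitness_network <- function(x, ...) {
  cat("<fitness_network> ", length(fn_nodes(x)), " nodes, ", nrow(x), " edges\n", sep = "")
  NextMethod()
}

#' Extract weighted ordered pairs from a module collection
#'
#' For a driver seed d with retained modules DIMs^d, an ordered pair
#' (d, u) is emitted for every other driver u appearing in at least one
#' retained module, weighted by the fraction of retained modules (counted
#' with multiplicity) that contain u.
#'
#' @param dims A `dim_collection` from [filter_dims()] / [detect_dims()].
#' @param drivers A [driver_set()] or character vector of driver genes.
#' @return A tibble with columns `source`, `target`, `weight`; empty (with
#'   a message) when no modules were retained.
#' @export
extract_ordered_pairs <- function(dims, drivers) {
  if (inherits(drivers, "driver_set")) drivers <- drivers$genes
  seed <- attr(dims, "seed_gene") %||% (if (nrow(dims)) dims$seed[[1]] else NA_character_)
  if (nrow(dims) == 0L) {
    rlang::inform(paste0("No retained modules for seed ", seed, "; no pairs emitted."))
    return(tibble::tibble(source = character(), target = character(), weight = double()))
  }
  n_dims <- sum(dims$count)
  hits <- tibble::tibble(
    target = unlist(purrr::map(dims$members, ~ intersect(.x, setdiff(drivers, seed)))),
    count = rep(dims$count, purrr::map_int(dims$members,
                                           ~ length(intersect(.x, setdiff(drivers, seed)))))
  )
  if (nrow(hits) == 0L) {
    return(tibble::tibble(source = character(), target = character(), weight = double()))
  }
  hits |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(weight = sum(.data$count) / n_dims, .groups = "drop") |>
    dplyr::mutate(source = seed) |>
    dplyr::select("source", "target", "weight") |>
    dplyr::arrange(.data$target)
}

#' Assemble a fitness network from per-driver ordered pairs
#'
#' @param edge_lists A list of per-driver edge tibbles (or a single bound
#'   tibble) as produced by [extract_ordered_pairs()].
#' @return A [fitness_network()]; drivers without any edge do not appear
#'   as nodes.
#' @export
build_fitness_network <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  edges <- dplyr::bind_rows(edge_lists)
  if (nrow(edges) == 0L) return(fitness_network())
  fitness_network(edges)
}

#' Consensus of fitness networks
#'
#' Keeps the ordered pairs present in every input network; the consensus
#' weight is the arithmetic mean of the per-network weights.
#'
#' @param fns List of [fitness_network()] objects (>= 2).
#' @return A [fitness_network()].
#' @export
consensus_network <- function(fns) {
  stopifnot(length(fns) >= 2L)
  all_edges <- dplyr::bind_rows(lapply(fns, tibble::as_tibble))
  cons <- all_edges |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(n = dplyr::n(), weight = mean(.data$weight), .groups = "drop") |>
    dplyr::filter(.data$n == length(fns)) |>
    dplyr::select("source", "target", "weight")
  if (nrow(cons) == 0L) return(fitness_network())
  fitness_network(cons)
}

#' Filter a fitness network by edge weight
#'
#' Retains edges with weight greater than or equal to the cutoff (closed
#' threshold); nodes left without edges are dropped.
#'
#' @param fn A [fitness_network()].
#' @param cutoff Weight cutoff in [0, 1].
#' @return A [fitness_network()].
#' @export
filter_by_weight <- function(fn, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  kept <- tibble::as_tibble(fn) |> dplyr::filter(.data$weight >= cutoff)
  if (nrow(kept) == 0L) return(fitness_network())
  fitness_network(kept)
}

#' Weight cutoffs of a sweep from 0 to 1
#' @param step Cutoff step; default 0.005 giving 201 cutoffs.
#' @return Numeric vector of cutoffs.
#' @export
weight_cutoffs <- function(step = 0.005) seq(0, 1, by = step)

#' Shortest-path length distribution of a fitness network
#'
#' Unweighted directed shortest-path lengths over all ordered reachable
#' node pairs, with the fraction of lengths below 3.
#'
#' @param fn A [fitness_network()].
#' @return A tibble with columns `length` and `n`; attributes `n_pairs`
#'   (reachable ordered pairs) and `frac_lt_3`.
#' @export
shortest_path_stats <- function(fn) {
  g <- fn_igraph(fn)
  d <- igraph::distances(g, mode = "out", weights = NA)
  d <- d[row(d) != col(d)]
  d <- d[is.finite(d)]
  hist <- tibble::tibble(length = as.integer(sort(unique(d))))
  hist$n <- vapply(hist$length, function(l) sum(d == l), integer(1))
  attr(hist, "n_pairs") <- length(d)
  attr(hist, "frac_lt_3") <- if (length(d)) mean(d < 3) else NA_real_
  hist
}

#' Write a fitness network to TSV
#'
#' Columns `source`, `target`, `weight` (full precision), sorted by
#' (source, target) so repeated writes diff cleanly.
#'
#' @param fn A [fitness_network()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fitness_network <- function(fn, path) {
  tab <- tibble::as_tibble(fn) |> dplyr::arrange(.data$source, .data$target)
  tab$weight <- vapply(tab$weight, function(w) format(w, digits = 17), character(1))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a fitness network from TSV
#' @param path Path written by [write_fitness_network()].
#' @return A [fitness_network()].
#' @export
read_fitness_network <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(source = readr::col_character(),
                                                 target = readr::col_character(),
                                                 weight = readr::col_double()))
  fitness_network(tab)
}

#' Tidy a fitness network
#' @param x A `fitness_network`.
#' @param ... Unused.
#' @return The edge tibble (source, target, weight) without the subclass.
#' @export
tidy.fitness_network <- function(x, ...) tibble::as_tibble(unclass_fn(x))

unclass_fn <- function(x) {
  class(x) <- setdiff(class(x), "fitness_network")
  x
}

#' One-row summary of a fitness network
#' @param x A `fitness_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, weight summaries and the
#'   fraction of shortest paths below 3.
#' @export
glance.fitness_network <- function(x, ...) {
  sp <- shortest_path_stats(x)
  tibble::tibble(n_nodes = length(fn_nodes(x)), n_edges = nrow(x),
                 mean_weight = if (nrow(x)) mean(x$weight) else NA_real_,
                 max_weight = if (nrow(x)) max(x$weight) else NA_real_,
                 frac_paths_lt_3 = attr(sp, "frac_lt_3"))
}
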