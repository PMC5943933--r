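#' Run the full fitness-relationship pipeline on one background network
#'
#' Calls differentially expressed genes once, detects driver-induced
#' modules for every valid driver seed, extracts weighted ordered pairs
#' and assembles the fitness network. Seeds are processed independently
#' in a simple loop; per-seed reproducibility derives from `cfg$seed`
#' (seed `cfg$seed + i - 1` is used for the i-th driver).
#'
#' @param expr An [expression_dataset()].
#' @param net A [gene_network()] background network.
#' @param drivers A [driver_set()] or character vector of driver genes.
#' @param cfg A [sampling_config()].
#' @param degs Optional precomputed `deg_set`; computed with
#'   [detect_degs()] when missing.
#' @param alpha Adjusted p-value threshold for DEG calling and module
#'   enrichment.
#' @param n_perm Permutations for DEG calling when `degs` is missing.
#' @return A list of class `fitness_fit`: `network`
#'   ([fitness_network()]), `dims` (named list of per-seed
#'   `dim_collection`s), `degs`, `drivers`.
#' @export
fit_fitness_network <- function(expr, net, drivers, cfg = sampling_config(),
                                degs = NULL, alpha = 0.05, n_perm = 1000L) {
  if (!inherits(drivers, "driver_set")) drivers <- driver_set(drivers, net)
  if (is.null(degs)) {
    degs <- detect_degs(expr, n_perm = n_perm, alpha = alpha,
                        seed = if (!is.null(cfg$seed)) cfg$seed else NULL)
  }
  seeds <- intersect(drivers$valid, expr_genes(expr))
  skipped <- setdiff(drivers$genes, seeds)
  if (length(skipped)) {
    rlang::inform(paste0(length(skipped),
                         " driver(s) absent from network or expression data skipped."))
  }
  dims <- vector("list", length(seeds))
  names(dims) <- seeds
  edges <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg_i <- cfg
    if (!is.null(cfg$seed)) cfg_i$seed <- cfg$seed + i - 1L
    dims[[i]] <- detect_dims(seeds[i], net, expr, degs, cfg_i, alpha)
    edges[[i]] <- extract_ordered_pairs(dims[[i]], drivers)
  }
  structure(list(network = build_fitness_network(edges), dims = dims,
                 degs = degs, drivers = drivers),
            class = "fitness_fit")
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("<fitness_fit> ", length(x$dims), " seeds; ",
      sum(purrr::map_int(x$dims, ~ sum(.x$count))), " retained modules\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Tidy the edges of a fitted fitness network
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return The edge tibble of the fitted network.
#' @export
tidy.fitness_fit <- function(x, ...) tidy.fitness_network(x$network)

#' One-row summary of a pipeline fit
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return Tibble with seed, module, DEG and network summaries.
#' @export
glance.fitness_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_seeds = length(x$dims),
                   n_retained_dims = sum(purrr::map_int(x$dims, ~ sum(.x$count))),
                   n_degs = length(deg_genes(x$degs))),
    glance.fitness_network(x$network)
  )
}

#' Tidy a module collection
#' @param x A `dim_collection`.
#' @param ... Unused.
#' @return Tibble with one row per unique retained module: `seed`,
#'   `size`, `score`, `n_deg`, `p_adj`, `count`, `members` (list).
#' @export
tidy.dim_collection <- function(x, ...) {
  tibble::as_tibble(x)[, c("seed", "size", "score", "n_deg", "p_adj", "count", "members")]
}

#' One-row summary of a module collection
#' @param x A `dim_collection`.
#' @param ... Unused.
#' @return Tibble with candidate/retained counts and score summaries.
#' @export
glance.dim_collection <- function(x, ...) {
  tibble::tibble(seed = attr(x, "seed_gene"),
                 n_candidates = attr(x, "n_candidates"),
                 n_retained = sum(x$count),
                 n_unique = nrow(x),
                 mean_score = if (nrow(x)) stats::weighted.mean(x$score, x$count) else NA_real_,
                 mean_size = if (nrow(x)) stats::weighted.mean(x$size, x$count) else NA_real_)
}
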