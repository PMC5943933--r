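#' Co-occurrence / mutual-exclusivity test for a gene pair
#'
#' Classifies a pair of genes by how their altered-sample sets U and V
#' overlap across the profiled sample universe. The 2x2 table is
#' `[[|U∩V|, |U\\V|], [|V\\U|, |universe \\ (U∪V)|]]`; a one-sided Fisher
#' enrichment tail calls co-occurrence, the depletion tail calls mutual
#' exclusivity, each at level `alpha`. The two tails cannot both be
#' significant for `alpha < 0.5`. A two-sided variant (significance plus
#' odds-ratio direction) is available via `two_sided = TRUE`.
#'
#' @param u,v Gene symbols.
#' @param mut A [mutation_profile()].
#' @param alpha Significance level; default 0.05.
#' @param two_sided Use a two-sided Fisher test with the odds-ratio sign
#'   deciding the direction, instead of the two one-sided tails.
#' @return A one-row tibble: `gene1`, `gene2`, `n_both`, `n_u_only`,
#'   `n_v_only`, `n_neither`, `p_cooccur`, `p_exclusive`, `status` in
#'   {"co-occurring", "mutually-exclusive", "neither"}.
#' @export
cooccurrence_test <- function(u, v, mut, alpha = 0.05, two_sided = FALSE) {
  stopifnot(length(mut$samples) > 0L)
  U <- altered_samples(mut, u)
  V <- altered_samples(mut, v)
  n_both <- length(intersect(U, V))
  n_u <- length(U) - n_both
  n_v <- length(V) - n_both
  n_neither <- length(mut$samples) - n_both - n_u - n_v
  base <- tibble::tibble(gene1 = u, gene2 = v, n_both = n_both, n_u_only = n_u,
                         n_v_only = n_v, n_neither = n_neither)
  if (length(U) == 0L || length(V) == 0L) {
    return(dplyr::mutate(base, p_cooccur = 1, p_exclusive = 1, status = "neither"))
  }
  tab <- matrix(c(n_both, n_u, n_v, n_neither), nrow = 2L, byrow = TRUE)
  p_co <- stats::fisher.test(tab, alternative = "greater")$p.value
  p_ex <- stats::fisher.test(tab, alternative = "less")$p.value
  if (two_sided) {
    ft <- stats::fisher.test(tab)
    status <- if (ft$p.value < alpha) {
      if (isTRUE(unname(ft$estimate) > 1)) "co-occurring" else "mutually-exclusive"
    } else "neither"
  } else {
    status <- if (p_co < alpha) "co-occurring" else if (p_ex < alpha) "mutually-exclusive" else "neither"
  }
  dplyr::mutate(base, p_cooccur = p_co, p_exclusive = p_ex, status = status)
}

#' Classify fitness-network edges by mutation co-occurrence across cutoffs
#'
#' At each weight cutoff, every surviving edge is classified with
#' [cooccurrence_test()]; the fraction of co-occurring edges measures
#' agreement with the mutation data and the fraction of mutually
#' exclusive edges is the false rate. Significance compares co-occurrence
#' frequency among network edges against all other ordered driver pairs
#' (one-sided Fisher).
#'
#' @param fn A [fitness_network()].
#' @param mut A [mutation_profile()]; edge endpoints missing from the
#'   profile are treated as never altered (logged).
#' @param alpha Per-edge significance level.
#' @param cutoffs Numeric vector of weight cutoffs.
#' @param drivers Optional driver universe for the background ordered
#'   pairs; defaults to the network nodes.
#' @return A tibble with columns `cutoff`, `n_edges`, `frac_cooccur`,
#'   `frac_exclusive`, `p_enrich`.
#' @export
classify_network_edges <- function(fn, mut, alpha = 0.05,
                                   cutoffs = c(0, 0.05, 0.1), drivers = NULL) {
  if (is.null(drivers)) drivers <- fn_nodes(fn)
  if (inherits(drivers, "driver_set")) drivers <- drivers$genes
  missing <- setdiff(unique(c(fn$source, fn$target)), names(mut$gamma))
  if (length(missing)) {
    rlang::inform(paste0(length(missing),
                         " edge gene(s) absent from mutation profile; treated as unaltered."))
  }
  status <- edge_cooccurrence_status(fn, mut, alpha)
  # co-occurrence status of every ordered driver pair, for the background
  pair_status <- pair_cooccurrence_matrix(drivers, mut, alpha)
  edge_key <- paste(fn$source, fn$target)
  purrr::map_dfr(cutoffs, function(ct) {
    keep <- fn$weight >= ct
    st <- status[keep]
    n_e <- sum(keep)
    in_fn <- pair_status$key %in% edge_key[keep]
    k_fn <- sum(pair_status$co & in_fn)
    k_bg <- sum(pair_status$co & !in_fn)
    n_bg <- sum(!in_fn)
    p <- if (n_e == 0L) NA_real_ else
      stats::fisher.test(matrix(c(k_fn, n_e - k_fn, k_bg, n_bg - k_bg), nrow = 2L),
                         alternative = "greater")$p.value
    tibble::tibble(cutoff = ct, n_edges = n_e,
                   frac_cooccur = if (n_e) mean(st == "co-occurring") else NA_real_,
                   frac_exclusive = if (n_e) mean(st == "mutually-exclusive") else NA_real_,
                   p_enrich = p)
  })
}

# Co-occurrence calls for all ordered pairs over a driver universe.
# Symmetric in the pair, but kept ordered to align with directed edges.
pair_cooccurrence_matrix <- function(drivers, mut, alpha) {
  pairs <- expand.grid(source = drivers, target = drivers,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  # test each unordered pair once
  ukey <- ifelse(pairs$source < pairs$target,
                 paste(pairs$source, pairs$target),
                 paste(pairs$target, pairs$source))
  uniq <- !duplicated(ukey)
  res <- vapply(which(uniq), function(i) {
    cooccurrence_test(pairs$source[i], pairs$target[i], mut, alpha)$status
  }, character(1))
  status <- stats::setNames(res, ukey[uniq])[ukey]
  tibble::tibble(key = paste(pairs$source, pairs$target),
                 co = unname(status == "co-occurring"))
}

#' Signaling continuity of fitness edges
#'
#' An ordered pair (d, u) is functionally continuous when a directed path
#' of any length runs from d to u in the signaling network. Edges with an
#' endpoint absent from the signaling network are `unmapped`.
#'
#' @param fn A [fitness_network()] (or a tibble with `source`/`target`).
#' @param sig A directed [gene_network()] (signaling network).
#' @return The edge tibble with an added `continuity` column in
#'   {"continuous", "discontinuous", "unmapped"}.
#' @export
signaling_continuity <- function(fn, sig) {
  stopifnot(isTRUE(sig$directed))
  sig_nodes <- network_genes(sig)
  out <- tibble::as_tibble(fn)
  mapped <- out$source %in% sig_nodes & out$target %in% sig_nodes
  cont <- rep("unmapped", nrow(out))
  if (any(mapped)) {
    srcs <- unique(out$source[mapped])
    d <- igraph::distances(sig$graph, v = srcs, mode = "out", weights = NA)
    reach <- is.finite(d)
    cont[mapped] <- ifelse(reach[cbind(match(out$source[mapped], srcs),
                                       match(out$target[mapped], sig_nodes))],
                           "continuous", "discontinuous")
  }
  out$continuity <- cont
  out
}

#' Enrichment of signaling continuity among fitness edges
#'
#' Reports how many fitness-network genes and edges map into the
#' signaling network, how many mapped edges are continuous, and a
#' one-sided Fisher p comparing continuity among fitness edges against
#' all other ordered mapped driver pairs. When no edge maps, the result
#' row carries NA p-value and zero counts.
#'
#' @param fn A [fitness_network()].
#' @param sig A directed [gene_network()].
#' @param drivers A [driver_set()] or character vector; the driver
#'   universe for the background pairs. Defaults to the network nodes.
#' @return A one-row tibble: `n_genes_mapped`, `n_edges`,
#'   `n_edges_mapped`, `n_continuous`, `frac_continuous`, `p_value`.
#' @export
continuity_enrichment <- function(fn, sig, drivers = NULL) {
  if (is.null(drivers)) drivers <- fn_nodes(fn)
  if (inherits(drivers, "driver_set")) drivers <- drivers$genes
  sig_nodes <- network_genes(sig)
  mapped_genes <- intersect(fn_nodes(fn), sig_nodes)
  cont <- signaling_continuity(fn, sig)
  mapped <- cont$continuity != "unmapped"
  n_cont <- sum(cont$continuity == "continuous")
  if (!any(mapped)) {
    return(tibble::tibble(n_genes_mapped = length(mapped_genes), n_edges = nrow(fn),
                          n_edges_mapped = 0L, n_continuous = 0L,
                          frac_continuous = NA_real_, p_value = NA_real_))
  }
  # background: ordered mapped driver pairs that are not fitness edges
  md <- intersect(drivers, sig_nodes)
  d <- igraph::distances(sig$graph, v = md, mode = "out", weights = NA)
  reach <- is.finite(d[, match(md, colnames(d)), drop = FALSE])
  diag(reach) <- NA
  reach_v <- as.vector(reach)   # column-major: source varies fastest
  pair_key <- paste(rep(md, times = length(md)), rep(md, each = length(md)))
  keep <- !is.na(reach_v)
  edge_key <- paste(cont$source[mapped], cont$target[mapped])
  in_fn <- pair_key[keep] %in% edge_key
  bg_cont <- sum(reach_v[keep][!in_fn])
  n_bg <- sum(!in_fn)
  tab <- matrix(c(n_cont, sum(mapped) - n_cont, bg_cont, n_bg - bg_cont), nrow = 2L)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  tibble::tibble(n_genes_mapped = length(mapped_genes), n_edges = nrow(fn),
                 n_edges_mapped = sum(mapped), n_continuous = n_cont,
                 frac_continuous = n_cont / sum(mapped), p_value = p)
}

#' Common edges across fitness networks under weight cutoffs
#'
#' Counts, at each weight cutoff, the ordered pairs present in every
#' network, with a one-sided Fisher significance against the null that
#' the first network's edges and the intersection of the remaining
#' networks' edges are independent draws over the shared ordered-pair
#' universe (all ordered pairs of the union of filtered nodes).
#'
#' @param fns List of [fitness_network()] objects (>= 2).
#' @param cutoffs Numeric vector of weight cutoffs.
#' @return A tibble with columns `cutoff`, `n_common`, `p_value`.
#' @export
cross_network_overlap <- function(fns, cutoffs = weight_cutoffs()) {
  stopifnot(length(fns) >= 2L)
  purrr::map_dfr(cutoffs, function(ct) {
    filtered <- lapply(fns, filter_by_weight, cutoff = ct)
    keys <- lapply(filtered, function(f) paste(f$source, f$target))
    common <- Reduce(intersect, keys)
    nodes <- unique(unlist(lapply(filtered, fn_nodes)))
    n_univ <- length(nodes) * (length(nodes) - 1L)
    a <- keys[[1]]
    b <- Reduce(intersect, keys[-1])
    k <- length(intersect(a, b))
    p <- if (n_univ == 0L) NA_real_ else
      stats::fisher.test(matrix(c(k, length(a) - k, length(b) - k,
                                  n_univ - length(a) - length(b) + k), nrow = 2L),
                         alternative = "greater")$p.value
    tibble::tibble(cutoff = ct, n_common = length(common), p_value = p)
  })
}

#' Overlap significance among fitness cores
#'
#' Pairwise core overlaps are tested with a hypergeometric tail over the
#' driver universe; the all-way intersection is reported alongside.
#'
#' @param cores List of character vectors (fitness cores), optionally
#'   named.
#' @param universe A [driver_set()] or character vector: the driver
#'   universe.
#' @return A tibble of pairwise rows: `core1`, `core2`, `n1`, `n2`,
#'   `overlap`, `p_value`; attribute `common` holds the all-way
#'   intersection.
#' @export
core_overlap_significance <- function(cores, universe) {
  if (inherits(universe, "driver_set")) universe <- universe$genes
  if (!length(universe)) rlang::abort("Empty driver universe.")
  if (is.null(names(cores))) names(cores) <- paste0("core", seq_along(cores))
  cores <- lapply(cores, intersect, y = universe)
  n_u <- length(universe)
  idx <- utils::combn(length(cores), 2L)
  out <- purrr::map_dfr(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    k <- length(intersect(cores[[i1]], cores[[i2]]))
    n1 <- length(cores[[i1]]); n2 <- length(cores[[i2]])
    p <- stats::phyper(k - 1L, n1, n_u - n1, n2, lower.tail = FALSE)
    tibble::tibble(core1 = names(cores)[i1], core2 = names(cores)[i2],
                   n1 = n1, n2 = n2, overlap = k, p_value = p)
  })
  attr(out, "common") <- sort(Reduce(intersect, cores))
  out
}
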