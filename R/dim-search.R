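#' Sampling configuration for driver-induced module search
#'
#' @param n_iter Number of candidate modules generated per driver seed.
#'   Default 5000.
#' @param improvement_threshold Minimum score gain per accepted expansion
#'   step. Interpreted as relative gain `(S_new - S_old)/S_old` when the
#'   current score is positive, absolute gain otherwise. Default 0.05.
#' @param max_module_size Hard cap on module size; growth stops when the
#'   cap is reached (logged). Default 30.
#' @param seed Optional integer RNG seed for reproducible candidate lists.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(n_iter = 5000L, improvement_threshold = 0.05,
                            max_module_size = 30L, seed = NULL) {
  stopifnot(n_iter >= 1L, improvement_threshold >= 0, max_module_size >= 1L)
  structure(list(n_iter = as.integer(n_iter),
                 improvement_threshold = improvement_threshold,
                 max_module_size = as.integer(max_module_size),
                 seed = seed),
            class = "sampling_config")
}

#' Per-sample activity of a gene module
#'
#' Module activity in a sample is the mean z-scored expression of the
#' member genes in that sample; for a single-gene module it is that gene's
#' z-scored row.
#'
#' @param members Character vector of member gene symbols.
#' @param expr An [expression_dataset()].
#' @return Named numeric vector, one activity value per sample.
#' @export
module_activity <- function(members, expr) {
  members <- unique(as.character(members))
  missing <- setdiff(members, expr_genes(expr))
  if (length(missing)) {
    rlang::abort(paste0("Module members absent from expression data: ",
                        paste(missing, collapse = ", ")))
  }
  colMeans(expr$values[members, , drop = FALSE])
}

# Row-wise absolute Welch t statistics for a matrix of activity vectors.
# Zero variance in both groups with equal means gives 0, never NaN.
welch_t_rows <- function(a, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- a[, idx1, drop = FALSE]; x2 <- a[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- (rowSums(x1^2) - n1 * m1^2) / (n1 - 1L)
  v2 <- (rowSums(x2^2) - n2 * m2^2) / (n2 - 1L)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- abs(m1 - m2) / se
  t[se == 0] <- ifelse(abs(m1 - m2)[se == 0] < .Machine$double.eps^0.5, 0, Inf)
  t
}

#' Discriminative score of a gene module
#'
#' The module score S is the absolute Welch (unequal-variance) two-sample
#' t statistic comparing [module_activity()] between tumor and normal
#' samples. Larger scores mean better tumor/normal discrimination.
#'
#' @inheritParams module_activity
#' @return Non-negative scalar score.
#' @export
module_score <- function(members, expr) {
  idx <- condition_index(expr)
  if (length(idx$tumor) < 2L || length(idx$normal) < 2L) {
    rlang::abort("Scoring needs >= 2 samples per condition.")
  }
  a <- matrix(module_activity(members, expr), nrow = 1L)
  unname(welch_t_rows(a, idx$tumor, idx$normal))
}

# Internal search state shared by one seed's candidate generation:
# integer-indexed expression rows and adjacency lists over the universe of
# genes present in both the expression data and the background network.
dim_search_state <- function(net, expr) {
  universe <- intersect(expr_genes(expr), network_genes(net))
  g <- igraph::induced_subgraph(net$graph, universe)
  nodes <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  idx <- condition_index(expr)
  list(values = expr$values[nodes, , drop = FALSE],
       nodes = nodes, adj = adj,
       tumor = idx$tumor, normal = idx$normal)
}

# One stochastic greedy growth from an integer seed index. Returns the
# member index vector. At each step all neighbors of the current module
# whose addition improves the score beyond the threshold are enumerated
# and one is drawn uniformly at random.
grow_module <- function(state, seed_i, threshold, max_size) {
  members <- seed_i
  sums <- state$values[seed_i, ]
  score <- welch_t_rows(matrix(sums, nrow = 1L), state$tumor, state$normal)
  in_module <- rep(FALSE, length(state$nodes))
  in_module[seed_i] <- TRUE
  frontier <- setdiff(state$adj[[seed_i]], members)
  while (length(members) < max_size && length(frontier) > 0L) {
    cand_act <- (state$values[frontier, , drop = FALSE] +
                   rep(sums, each = length(frontier))) / (length(members) + 1L)
    cand_s <- welch_t_rows(cand_act, state$tumor, state$normal)
    gain <- if (score > 0) (cand_s - score) / score else cand_s - score
    ok <- which(gain > threshold)
    if (!length(ok)) break
    j <- ok[sample.int(length(ok), 1L)]
    pick <- frontier[j]
    members <- c(members, pick)
    sums <- sums + state$values[pick, ]
    score <- cand_s[j]
    in_module[pick] <- TRUE
    frontier <- unique(c(frontier[frontier != pick],
                         state$adj[[pick]][!in_module[state$adj[[pick]]]]))
  }
  list(members = members, score = unname(score))
}

#' Sample one candidate driver-induced module
#'
#' Grows a module from a driver seed by stochastic greedy expansion: at
#' each step, the neighbors of the current module whose addition raises
#' the score by more than the improvement threshold are enumerated and one
#' is added uniformly at random; growth terminates when no neighbor
#' qualifies or the size cap is reached.
#'
#' @param seed Driver gene symbol (must be in the network and expression
#'   data).
#' @param net A [gene_network()] background network.
#' @param expr An [expression_dataset()].
#' @param cfg A [sampling_config()]; its `seed` field is ignored here (the
#'   current RNG state is used).
#' @return A one-row tibble with columns `seed`, `members` (list-column)
#'   and `score`.
#' @export
sample_candidate_dim <- function(seed, net, expr, cfg = sampling_config()) {
  state <- dim_search_state(net, expr)
  seed_i <- match(seed, state$nodes)
  if (is.na(seed_i)) {
    if (!seed %in% network_genes(net)) rlang::abort(paste0("Seed not in network: ", seed))
    rlang::abort(paste0("Seed not in expression data: ", seed))
  }
  m <- grow_module(state, seed_i, cfg$improvement_threshold, cfg$max_module_size)
  tibble::tibble(seed = seed, members = list(state$nodes[m$members]), score = m$score)
}

#' Generate candidate driver-induced modules for a seed
#'
#' Repeats the stochastic growth of [sample_candidate_dim()] `cfg$n_iter`
#' times (default 5000), producing a multiset of candidate modules.
#' Identical runs with the same `cfg$seed` produce identical candidates.
#'
#' @inheritParams sample_candidate_dim
#' @return A tibble with one row per candidate: `seed`, `members`
#'   (list-column of gene vectors), `score`.
#' @export
generate_candidate_dims <- function(seed, net, expr, cfg = sampling_config()) {
  state <- dim_search_state(net, expr)
  seed_i <- match(seed, state$nodes)
  if (is.na(seed_i)) {
    if (!seed %in% network_genes(net)) rlang::abort(paste0("Seed not in network: ", seed))
    rlang::abort(paste0("Seed not in expression data: ", seed))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- vector("list", cfg$n_iter)
  scores <- numeric(cfg$n_iter)
  for (k in seq_len(cfg$n_iter)) {
    m <- grow_module(state, seed_i, cfg$improvement_threshold, cfg$max_module_size)
    out[[k]] <- state$nodes[m$members]
    scores[k] <- m$score
  }
  tibble::tibble(seed = seed, members = out, score = scores)
}

#' Call differentially expressed genes by permutation test
#'
#' Per gene, the observed statistic is the absolute Welch t comparing
#' tumor and normal samples; condition labels are permuted `n_perm` times
#' and the p-value is the add-one estimator
#' `(1 + #permuted >= observed) / (1 + n_perm)`. P-values are
#' Benjamini-Hochberg adjusted and genes with adjusted p below `alpha`
#' are called differentially expressed.
#'
#' @param expr An [expression_dataset()].
#' @param n_perm Number of label permutations (>= 100).
#' @param alpha Adjusted p-value threshold; default 0.05.
#' @param seed Optional integer RNG seed.
#' @return A tibble of class `deg_set` with columns `gene`, `statistic`,
#'   `p_value`, `p_adj`, `deg` (logical call).
#' @export
detect_degs <- function(expr, n_perm = 1000L, alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 100L)
  if (1 / (1 + n_perm) >= alpha) {
    rlang::warn("n_perm too small: the smallest attainable p-value cannot reach alpha after adjustment.")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- condition_index(expr)
  n1 <- length(idx$tumor)
  obs <- welch_t_rows(expr$values, idx$tumor, idx$normal)
  n <- ncol(expr$values)
  count <- numeric(nrow(expr$values))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    stat <- welch_t_rows(expr$values, p[seq_len(n1)], p[-seq_len(n1)])
    count <- count + (stat >= obs - 1e-9)  # tolerance guards fp ties
  }
  pval <- (1 + count) / (1 + n_perm)
  padj <- stats::p.adjust(pval, method = "BH")
  out <- tibble::tibble(gene = expr_genes(expr), statistic = obs,
                        p_value = pval, p_adj = padj, deg = padj < alpha)
  class(out) <- c("deg_set", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Genes called differentially expressed
#' @param degs A `deg_set` from [detect_degs()], or a character vector
#'   (returned as is).
#' @return Character vector of DEG symbols.
#' @export
deg_genes <- function(degs) {
  if (is.character(degs)) return(degs)
  degs$gene[degs$deg]
}

#' Filter candidate modules for enrichment of differentially expressed genes
#'
#' Identical member sets among the candidates are tested once with a
#' one-sided Fisher exact (hypergeometric) enrichment test of DEG content
#' against the gene universe; p-values are BH-adjusted across the unique
#' candidates, and candidates with adjusted p below `alpha` are retained
#' as driver-induced modules. Weights downstream are computed over the
#' retained multiset, so each row carries the multiplicity `count` of its
#' member set among the candidates.
#'
#' @param candidates Candidate tibble from [generate_candidate_dims()].
#' @param degs A `deg_set` or character vector of DEG symbols.
#' @param universe Character vector: genes present in both the expression
#'   data and the background network.
#' @param alpha Adjusted p-value threshold; default 0.05.
#' @return An object of class `dim_collection`: tibble with columns
#'   `seed`, `members`, `score`, `size`, `n_deg`, `p_value`, `p_adj`,
#'   `count`; attributes `n_candidates` and `seed_gene`.
#' @export
filter_dims <- function(candidates, degs, universe, alpha = 0.05) {
  stopifnot(nrow(candidates) > 0L)
  seed_gene <- candidates$seed[[1]]
  deg <- intersect(deg_genes(degs), universe)
  key <- purrr::map_chr(candidates$members, ~ paste(sort(.x), collapse = "\r"))
  uniq <- !duplicated(key)
  counts <- table(key)
  tab <- candidates[uniq, ]
  tab$count <- as.integer(counts[key[uniq]])
  tab$size <- lengths(tab$members)
  tab$n_deg <- purrr::map_int(tab$members, ~ length(intersect(.x, deg)))
  n_univ <- length(universe)
  n_deg_univ <- length(deg)
  if (n_deg_univ == 0L) {
    rlang::inform("No differentially expressed genes: no candidate retained.")
    tab$p_value <- rep(1, nrow(tab))
  } else {
    # one-sided enrichment: P(X >= k), X ~ Hypergeom(K DEGs, N-K others, m drawn)
    tab$p_value <- stats::phyper(tab$n_deg - 1L, n_deg_univ,
                                 n_univ - n_deg_univ, tab$size,
                                 lower.tail = FALSE)
  }
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  kept <- tab[tab$p_adj < alpha,
              c("seed", "members", "score", "size", "n_deg", "p_value", "p_adj", "count")]
  class(kept) <- c("dim_collection", class(tibble::as_tibble(kept)))
  attr(kept, "n_candidates") <- nrow(candidates)
  attr(kept, "seed_gene") <- seed_gene
  kept
}

#' Detect driver-induced modules for one seed (sample + filter)
#'
#' Convenience pipeline: generate candidates, then retain those enriched
#' for differentially expressed genes.
#'
#' @inheritParams generate_candidate_dims
#' @param degs A `deg_set` or character vector of DEG symbols.
#' @return A `dim_collection` (see [filter_dims()]).
#' @export
detect_dims <- function(seed, net, expr, degs, cfg = sampling_config(),
                        alpha = 0.05) {
  universe <- intersect(expr_genes(expr), network_genes(net))
  cands <- generate_candidate_dims(seed, net, expr, cfg)
  filter_dims(cands, degs, universe, alpha)
}

#' Coverage of driver genes by retained modules across sampling budgets
#'
#' Recomputes, at each iteration checkpoint, the set of driver genes
#' contained in modules retained from the first `c` candidates; the
#' covered set is accumulated across checkpoints, so it is monotone
#' non-decreasing. A stable covered set between checkpoints indicates the
#' sampling has converged.
#'
#' @inheritParams detect_dims
#' @param drivers A [driver_set()] or character vector of driver genes.
#' @param checkpoints Sorted increasing integer iteration counts (each
#'   <= `cfg$n_iter`).
#' @return A tibble with columns `checkpoint` and `covered` (list-column
#'   of driver gene sets).
#' @export
convergence_curve <- function(seed, net, expr, degs, drivers,
                              cfg = sampling_config(),
                              checkpoints = c(1000L, 5000L), alpha = 0.05) {
  stopifnot(!is.unsorted(checkpoints))
  if (inherits(drivers, "driver_set")) drivers <- drivers$genes
  universe <- intersect(expr_genes(expr), network_genes(net))
  cfg$n_iter <- max(checkpoints, 1L)
  cands <- generate_candidate_dims(seed, net, expr, cfg)
  covered <- character()
  out <- vector("list", length(checkpoints))
  for (i in seq_along(checkpoints)) {
    c_i <- checkpoints[i]
    if (c_i >= 1L) {
      kept <- filter_dims(cands[seq_len(c_i), ], degs, universe, alpha)
      covered <- union(covered,
                       intersect(unique(unlist(kept$members)), drivers))
    }
    out[[i]] <- sort(covered)
  }
  tibble::tibble(checkpoint = as.integer(checkpoints), covered = out)
}
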