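# Fixtures built in code; no files are shipped.

# Small deterministic expression dataset: n_genes x (n_tumor + n_normal),
# noise from a fixed seed, optional tumor shift on `shifted` genes.
make_expr <- function(n_genes = 6, n_tumor = 4, n_normal = 4, shifted = character(),
                      effect = 0, seed = 42) {
  genes <- paste0("g", seq_len(n_genes))
  samples <- c(paste0("T", seq_len(n_tumor)), paste0("N", seq_len(n_normal)))
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_tumor + n_normal)), nrow = n_genes,
              dimnames = list(genes, samples))
  m[shifted, seq_len(n_tumor)] <- m[shifted, seq_len(n_tumor)] + effect
  labels <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
  expression_dataset(m, labels)
}

# Expression dataset with fully specified raw values (list of per-gene rows).
make_expr_raw <- function(rows, n_tumor, n_normal) {
  m <- do.call(rbind, rows)
  samples <- c(paste0("T", seq_len(n_tumor)), paste0("N", seq_len(n_normal)))
  colnames(m) <- samples
  labels <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
  expression_dataset(m, labels)
}

make_net <- function(edges_chr) {
  # edges_chr: character vector like c("a-b", "b-c")
  parts <- strsplit(edges_chr, "-", fixed = TRUE)
  gene_network(data.frame(from = vapply(parts, `[`, "", 1),
                          to = vapply(parts, `[`, "", 2)))
}

make_sig <- function(edges_chr) {
  parts <- strsplit(edges_chr, ">", fixed = TRUE)
  gene_network(data.frame(from = vapply(parts, `[`, "", 1),
                          to = vapply(parts, `[`, "", 2)), directed = TRUE)
}

make_fn <- function(source, target, weight) {
  fitness_network(tibble::tibble(source = source, target = target, weight = weight))
}

make_mut <- function(gamma, samples = NULL) mutation_profile(gamma, samples)

# Minimal dim_collection for tests that start from known module sets.
make_dims <- function(seed, members_list, counts = rep(1L, length(members_list))) {
  tab <- tibble::tibble(seed = seed, members = members_list,
                        score = rep(1, length(members_list)),
                        size = lengths(members_list),
                        n_deg = NA_integer_, p_value = NA_real_, p_adj = NA_real_,
                        count = as.integer(counts))
  class(tab) <- c("dim_collection", class(tibble::tibble()))
  attr(tab, "n_candidates") <- sum(counts)
  attr(tab, "seed_gene") <- seed
  tab
}

# Exhaustive hypergeometric upper tail P(X >= k) via choose(), independent
# of stats::phyper / stats::fisher.test.
hyper_tail <- function(k, n_white, n_black, n_draw) {
  kk <- max(0, n_draw - n_black):min(n_draw, n_white)
  kk <- kk[kk >= k]
  sum(choose(n_white, kk) * choose(n_black, n_draw - kk)) /
    choose(n_white + n_black, n_draw)
}

# One-sided enrichment p for a 2x2 table [[a, b], [c, d]] (row = in set,
# col = success/failure), as a hypergeometric tail.
fisher_greater_oracle <- function(a, b, c, d) {
  hyper_tail(a, a + b, c + d, a + c)
}
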