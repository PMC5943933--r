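# Run code under a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification for a synthetic benchmark instance
#'
#' Defines the statistical structure of a generated dataset: a scale-free
#' (preferential-attachment) or Erdos-Renyi background network, standard
#' normal expression noise with planted differentially expressed modules
#' around driver seeds, Bernoulli somatic alteration profiles with planted
#' co-occurring / mutually exclusive gene pairs, and a random directed
#' signaling network containing planted directed paths.
#'
#' Defaults describe a modest two-condition cohort: 150 genes, 25 tumor
#' and 25 normal expression samples, 15 driver genes, one planted module
#' of 5 genes with a 2-standard-deviation tumor shift, a per-gene
#' alteration probability of 0.15 over 60 mutation-profiled tumor
#' samples, one planted co-occurring and one mutually exclusive pair, and
#' one planted signaling path.
#'
#' @param n_genes,n_tumor,n_normal Expression dimensions.
#' @param n_mut_samples Number of mutation-profiled tumor samples.
#' @param network_model `"pa"` (preferential attachment) or `"er"`.
#' @param n_drivers Number of driver genes.
#' @param n_planted_modules Planted differential modules, one per driver
#'   seed.
#' @param module_size Genes per planted module (including the seed).
#' @param effect_size Tumor mean shift of planted genes, in noise-sd
#'   units.
#' @param mutation_rate Per-gene Bernoulli alteration probability.
#' @param n_cooccur_pairs,n_exclusive_pairs Planted mutation-dependence
#'   pairs.
#' @param pair_strength Dependence strength in [0, 1] (1 = deterministic).
#' @param n_signaling_paths Planted directed paths in the signaling
#'   network.
#' @param seed Integer RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 150L, n_tumor = 25L, n_normal = 25L,
                           n_mut_samples = 60L,
                           network_model = c("pa", "er"), n_drivers = 15L,
                           n_planted_modules = 1L, module_size = 5L,
                           effect_size = 2, mutation_rate = 0.15,
                           n_cooccur_pairs = 1L, n_exclusive_pairs = 1L,
                           pair_strength = 1, n_signaling_paths = 1L,
                           seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot(effect_size >= 0, mutation_rate >= 0, mutation_rate <= 1,
            pair_strength >= 0, pair_strength <= 1,
            module_size >= 2L, n_drivers >= 2L,
            n_planted_modules * 2L + 2L * (n_cooccur_pairs + n_exclusive_pairs) <= n_drivers)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic benchmark instance
#'
#' Produces all five pipeline inputs plus a ground-truth record. Planted
#' module members are connected to their seed by construction (edges are
#' added to the background network when the sampled neighborhood is too
#' small), and the second member of each planted module is promoted to
#' the driver set so that each planted module implies a planted ordered
#' pair (seed, member-driver) in the fitness network.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_instance` with elements
#'   `expression` ([expression_dataset()]), `network` ([gene_network()]),
#'   `drivers` ([driver_set()]), `mutations` ([mutation_profile()]),
#'   `signaling` (directed [gene_network()]) and `truth` (list of planted
#'   structures).
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    genes <- sprintf("g%03d", seq_len(spec$n_genes))

    g <- if (spec$network_model == "pa") {
      igraph::sample_pa(spec$n_genes, m = 2, directed = FALSE)
    } else {
      igraph::sample_gnp(spec$n_genes, p = 4 / spec$n_genes, directed = FALSE)
    }
    igraph::V(g)$name <- genes

    drivers <- sample(genes, spec$n_drivers)
    planted <- list()
    seeds_used <- character()
    for (i in seq_len(spec$n_planted_modules)) {
      seed_gene <- setdiff(drivers, seeds_used)[1]
      members <- seed_gene
      while (length(members) < spec$module_size) {
        nb <- setdiff(unique(unlist(
          igraph::adjacent_vertices(g, members, mode = "all") |>
            lapply(function(v) igraph::V(g)$name[v]))), members)
        if (length(nb) == 0L) {
          new <- sample(setdiff(genes, members), 1L)
          g <- igraph::add_edges(g, c(seed_gene, new))
          nb <- new
        }
        members <- c(members, sample(nb, 1L))
      }
      # promote one non-seed member to driver: yields a planted ordered pair
      partner <- members[2]
      drivers <- union(drivers, partner)
      seeds_used <- c(seeds_used, seed_gene, partner)
      planted[[i]] <- list(seed = seed_gene, members = members,
                           partner_driver = partner,
                           effect_size = spec$effect_size)
    }

    n_s <- spec$n_tumor + spec$n_normal
    samples <- c(sprintf("T%02d", seq_len(spec$n_tumor)),
                 sprintf("N%02d", seq_len(spec$n_normal)))
    labels <- stats::setNames(rep(c("tumor", "normal"),
                                  c(spec$n_tumor, spec$n_normal)), samples)
    vals <- matrix(stats::rnorm(spec$n_genes * n_s), nrow = spec$n_genes,
                   dimnames = list(genes, samples))
    for (pm in planted) {
      vals[pm$members, seq_len(spec$n_tumor)] <-
        vals[pm$members, seq_len(spec$n_tumor)] + spec$effect_size
    }
    expr <- expression_dataset(vals, labels)

    mut_samples <- sprintf("M%03d", seq_len(spec$n_mut_samples))
    gamma <- lapply(stats::setNames(nm = drivers), function(gn) {
      mut_samples[stats::runif(spec$n_mut_samples) < spec$mutation_rate]
    })
    free <- setdiff(drivers, unlist(lapply(planted, `[[`, "seed")))
    free <- setdiff(free, unlist(lapply(planted, `[[`, "partner_driver")))
    mut_pairs <- list()
    for (i in seq_len(spec$n_cooccur_pairs)) {
      pr <- free[1:2]; free <- free[-(1:2)]
      keep <- stats::runif(length(gamma[[pr[1]]])) < spec$pair_strength
      gamma[[pr[2]]] <- gamma[[pr[1]]][keep]
      mut_pairs[[length(mut_pairs) + 1L]] <-
        list(gene1 = pr[1], gene2 = pr[2], mode = "co-occur",
             strength = spec$pair_strength)
    }
    for (i in seq_len(spec$n_exclusive_pairs)) {
      pr <- free[1:2]; free <- free[-(1:2)]
      cand <- gamma[[pr[2]]]
      drop <- cand %in% gamma[[pr[1]]] &
        stats::runif(length(cand)) < spec$pair_strength
      gamma[[pr[2]]] <- cand[!drop]
      mut_pairs[[length(mut_pairs) + 1L]] <-
        list(gene1 = pr[1], gene2 = pr[2], mode = "exclusive",
             strength = spec$pair_strength)
    }
    mut <- mutation_profile(gamma, samples = mut_samples)

    # random directed edges among drivers plus planted directed paths
    sig_edges <- expand.grid(from = drivers, to = drivers,
                             stringsAsFactors = FALSE)
    sig_edges <- sig_edges[sig_edges$from != sig_edges$to, ]
    sig_edges <- sig_edges[stats::runif(nrow(sig_edges)) < 0.05, ]
    sig_paths <- list()
    for (i in seq_len(spec$n_signaling_paths)) {
      pm <- planted[[1 + (i - 1) %% length(planted)]]
      via <- sample(setdiff(drivers, c(pm$seed, pm$partner_driver)), 1L)
      sig_edges <- rbind(sig_edges,
                         data.frame(from = c(pm$seed, via),
                                    to = c(via, pm$partner_driver)))
      sig_paths[[i]] <- list(from = pm$seed, to = pm$partner_driver, via = via)
    }
    sig <- gene_network(unique(sig_edges), directed = TRUE)

    net <- gene_network(igraph::as_edgelist(g), directed = FALSE)
    structure(
      list(expression = expr, network = net,
           drivers = driver_set(drivers, net), mutations = mut,
           signaling = sig,
           truth = list(planted_modules = planted,
                        planted_pairs = lapply(planted, function(pm)
                          list(source = pm$seed, target = pm$partner_driver)),
                        mutation_pairs = mut_pairs,
                        signaling_paths = sig_paths,
                        spec = spec)),
      class = "synthetic_instance")
  })
}

#' Deterministic 12-gene worked example
#'
#' A tiny fixed instance (12 genes, 6 tumor + 6 normal samples, one
#' planted module, one co-occurring and one mutually exclusive mutation
#' pair, one planted signaling path) used in documentation and doc
#' tests. Repeated calls return identical data.
#'
#' @return A `synthetic_instance` (see [generate_instance()]).
#' @export
generate_worked_example <- function() {
  spec <- synthetic_spec(n_genes = 12L, n_tumor = 6L, n_normal = 6L,
                         n_mut_samples = 24L, n_drivers = 7L,
                         n_planted_modules = 1L, module_size = 4L,
                         effect_size = 3, mutation_rate = 0.35,
                         n_cooccur_pairs = 1L, n_exclusive_pairs = 1L,
                         pair_strength = 1, n_signaling_paths = 1L,
                         seed = 20171225L)
  generate_instance(spec)
}

#' Write a synthetic instance to plain-text input files
#'
#' Emits `expression.tsv`, `labels.tsv`, `network.tsv`, `drivers.txt`,
#' `mutations.tsv`, `signaling.tsv` and `ground_truth.json` into a
#' directory, in the formats the readers of this package accept.
#'
#' @param instance A `synthetic_instance`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- instance$expression
  tab <- tibble::as_tibble(expr$values, rownames = "gene")
  readr::write_tsv(tab, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(sample = names(expr$labels),
                                  condition = as.character(expr$labels)),
                   file.path(dir, "labels.tsv"), progress = FALSE)
  readr::write_tsv(tidy.gene_network(instance$network),
                   file.path(dir, "network.tsv"), col_names = FALSE, progress = FALSE)
  writeLines(sort(instance$drivers$genes), file.path(dir, "drivers.txt"))
  write_mutations(instance$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(tidy.gene_network(instance$signaling),
                   file.path(dir, "signaling.tsv"), col_names = FALSE, progress = FALSE)
  jsonlite::write_json(instance$truth[setdiff(names(instance$truth), "spec")],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat("<synthetic_instance>\n")
  print(x$expression); print(x$network); print(x$drivers)
  print(x$mutations); print(x$signaling)
  cat("  planted modules: ", length(x$truth$planted_modules),
      "; mutation pairs: ", length(x$truth$mutation_pairs),
      "; signaling paths: ", length(x$truth$signaling_paths), "\n", sep = "")
  invisible(x)
}
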