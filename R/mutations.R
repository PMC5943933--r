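#' Somatic alteration profile
#'
#' Stores, for each gene g, the set of tumor samples carrying a genomic
#' alteration in g (written Gamma(g)), plus the universe of profiled
#' samples. Genes never altered map to the empty set; querying a gene
#' absent from the input also returns the empty set.
#'
#' @param gamma Named list of character vectors: gene -> altered samples.
#' @param samples Character vector, the universe of profiled samples.
#'   Defaults to the union of all altered-sample sets.
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(gamma, samples = NULL) {
  gamma <- lapply(gamma, function(s) unique(as.character(s)))
  if (is.null(samples)) samples <- unique(unlist(gamma, use.names = FALSE))
  samples <- unique(as.character(samples))
  extra <- setdiff(unlist(gamma, use.names = FALSE), samples)
  if (length(extra)) {
    rlang::abort("Altered samples outside the sample universe: check inputs.")
  }
  structure(list(gamma = gamma, samples = samples), class = "mutation_profile")
}

#' Altered-sample set of one or more genes
#'
#' @param mut A [mutation_profile()].
#' @param genes Character vector of gene symbols.
#' @return Character vector: the union of Gamma(g) over `genes` (empty for
#'   genes absent from the profile).
#' @export
altered_samples <- function(mut, genes) {
  hit <- intersect(as.character(genes), names(mut$gamma))
  unique(unlist(mut$gamma[hit], use.names = FALSE)) %||% character()
}

#' Read somatic alterations from a TSV file
#'
#' Two layouts are auto-detected by column count: a two-column long format
#' of (gene, sample) pairs, or a binary genes-by-samples matrix with gene
#' symbols in the first column and sample identifiers in the header.
#'
#' @param path Path to the TSV file.
#' @return A [mutation_profile()].
#' @export
read_mutations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) == 2L) {
    gene <- as.character(tab[[1]])
    sample <- as.character(tab[[2]])
    gamma <- split(sample, gene)
    return(mutation_profile(gamma, samples = unique(sample)))
  }
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || !all(m %in% c(0, 1))) {
    rlang::abort("Matrix-form mutation file must be binary (0/1).")
  }
  rownames(m) <- genes
  gamma <- apply(m, 1L, function(r) colnames(m)[r == 1], simplify = FALSE)
  mutation_profile(gamma, samples = colnames(m))
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat("<mutation_profile> ", length(x$gamma), " genes over ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' Tidy a mutation profile into (gene, sample) pairs
#' @param x A `mutation_profile`.
#' @param ... Unused.
#' @return A tibble with columns `gene` and `sample`, one row per alteration.
#' @export
tidy.mutation_profile <- function(x, ...) {
  tibble::tibble(gene = rep(names(x$gamma), lengths(x$gamma)),
                 sample = unlist(x$gamma, use.names = FALSE) %||% character())
}

#' Write a mutation profile as a long-format TSV
#' @param mut A [mutation_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mutations <- function(mut, path) {
  tab <- tidy.mutation_profile(mut) |> dplyr::arrange(.data$gene, .data$sample)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
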