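#' Build a gene network from an edge data frame
#'
#' Wraps an [igraph::graph] and keeps the tidy edge list alongside. Self
#' loops are dropped (with a message giving the count) and duplicate edges
#' collapsed; for undirected networks `A-B` and `B-A` are the same edge.
#'
#' @param edges Data frame whose first two columns are gene symbols
#'   (`from`, `to`).
#' @param directed Logical; `FALSE` for background interaction networks,
#'   `TRUE` for signaling networks.
#' @return An object of class `gene_network` (and `signaling_network` when
#'   directed): a list with `graph` (igraph) and `directed`.
#' @export
gene_network <- function(edges, directed = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) rlang::abort("`edges` needs at least two columns.")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  keep <- from != to
  if (any(!keep)) {
    rlang::inform(paste0("Dropped ", sum(!keep), " self-loop(s)."))
  }
  el <- cbind(from[keep], to[keep])
  if (nrow(el) == 0L && length(unique(c(from, to))) == 0L) {
    rlang::abort("Network has no edges or nodes.")
  }
  g <- igraph::graph_from_edgelist(el, directed = directed)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(
    list(graph = g, directed = directed),
    class = c(if (directed) "signaling_network", "gene_network")
  )
}

#' Read a network edge list from a TSV or SIF file
#'
#' Two-column TSV edge lists are read as (from, to). Files with three or
#' more columns are treated as SIF: the interaction-type middle column is
#' ignored and columns 1 and 3 are used.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; read as a directed (signaling) network?
#' @return A [gene_network()].
#' @export
read_network <- function(path, directed = FALSE) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0L) rlang::abort(paste0("Empty network file: ", path))
  if (ncol(tab) >= 3L) tab <- tab[, c(1L, 3L)]
  if (ncol(tab) < 2L) rlang::abort("Network file must have >= 2 columns.")
  gene_network(tab, directed = directed)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<", if (x$directed) "signaling_network" else "gene_network", "> ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      if (x$directed) " directed" else " undirected", " edges\n", sep = "")
  invisible(x)
}

#' Nodes of a gene network
#' @param x A `gene_network`.
#' @return Character vector of gene symbols.
#' @export
network_genes <- function(x) igraph::V(x$graph)$name

#' Tidy the edge list of a gene network
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return A tibble with columns `from` and `to`.
#' @export
tidy.gene_network <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph)
  tibble::tibble(from = el[, 1], to = el[, 2])
}

#' Validate a driver gene list against a background network
#'
#' Driver genes absent from the background network cannot seed a module
#' search; they are flagged invalid but kept so that valid/all counts can
#' be reported.
#'
#' @param genes Character vector of driver gene symbols.
#' @param network Optional [gene_network()] used to flag validity.
#' @return An object of class `driver_set`: list with `genes` (all),
#'   `valid` and `invalid`.
#' @export
driver_set <- function(genes, network = NULL) {
  genes <- unique(as.character(genes))
  if (!length(genes)) rlang::abort("Driver set must be non-empty.")
  valid <- genes
  invalid <- character()
  if (!is.null(network)) {
    valid <- intersect(genes, network_genes(network))
    invalid <- setdiff(genes, valid)
  }
  structure(list(genes = genes, valid = valid, invalid = invalid), class = "driver_set")
}

#' Read a driver gene list (one symbol per line)
#' @param path Path to the list file.
#' @param network Optional [gene_network()] for validity flagging.
#' @return A [driver_set()].
#' @export
read_drivers <- function(path, network = NULL) {
  driver_set(readLines(path, warn = FALSE) |> trimws() |> (\(x) x[nzchar(x)])(), network)
}

#' @export
print.driver_set <- function(x, ...) {
  cat("<driver_set> ", length(x$genes), " genes", sep = "")
  if (length(x$invalid)) cat(" (valid/all: ", length(x$valid), "/", length(x$genes), ")", sep = "")
  cat("\n")
  invisible(x)
}
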