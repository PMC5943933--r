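#' Build an expression dataset from a matrix and condition labels
#'
#' Container for a genes-by-samples expression matrix with binary
#' tumor/normal condition labels. Rows with duplicated gene symbols are
#' averaged, then every row is z-scored (sample standard deviation,
#' `n - 1` denominator). Zero-variance rows cannot be z-scored; they are
#' set to all zeros and recorded in the `zero_variance` field so that
#' downstream module scoring stays total.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample identifiers).
#' @param labels Character vector of conditions, one of `"tumor"` or
#'   `"normal"`, named by sample identifier (or unnamed, in column order).
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the z-scored matrix), `labels` (named factor) and
#'   `zero_variance` (character vector of constant genes).
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values))) {
    rlang::abort("`values` must have gene symbols as rownames.")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values)) {
      rlang::abort("Unnamed `labels` must have one entry per sample column.")
    }
    names(labels) <- colnames(values)
  }
  bad <- setdiff(unique(as.character(labels)), c("tumor", "normal"))
  if (length(bad)) {
    rlang::abort(paste0("Unknown condition label(s): ", paste(bad, collapse = ", "),
                        " (expected 'tumor' or 'normal')."))
  }
  labelled <- intersect(colnames(values), names(labels))
  dropped <- setdiff(colnames(values), labelled)
  if (length(dropped)) {
    rlang::warn(paste0(length(dropped), " sample(s) without condition labels dropped: ",
                       paste(utils::head(dropped, 5), collapse = ", ")))
    values <- values[, labelled, drop = FALSE]
  }
  if (ncol(values) == 0L) rlang::abort("No labelled samples remain.")
  labels <- factor(as.character(labels[colnames(values)]), levels = c("tumor", "normal"))
  names(labels) <- colnames(values)
  if (sum(labels == "tumor") < 2L || sum(labels == "normal") < 2L) {
    rlang::abort("At least 2 samples per condition are required.")
  }

  # average duplicated gene symbols before normalization
  if (anyDuplicated(rownames(values))) {
    values <- rowsum(values, group = rownames(values)) /
      as.vector(table(rownames(values))[sort(unique(rownames(values)))])
    # rowsum sorts groups; keep as returned
  }

  z <- zscore_rows(values)
  structure(
    list(values = z$values, labels = labels, zero_variance = z$zero_variance),
    class = "expression_dataset"
  )
}

# Row-wise z-scoring with n-1 standard deviation; constant rows -> zeros.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  centered <- m - mu
  sd <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  flat <- sd <= 0 | !is.finite(sd)
  sd[flat] <- 1
  z <- centered / sd
  z[flat, ] <- 0
  list(values = z, zero_variance = rownames(m)[flat])
}

#' Read an expression matrix and sample labels from TSV files
#'
#' @param path TSV file with gene symbols in the first column and sample
#'   identifiers in the header.
#' @param label_path Two-column TSV mapping sample identifier to condition
#'   (`tumor` or `normal`).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, label_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 3L) rlang::abort("Expression TSV needs a gene column and >= 2 samples.")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) rlang::abort("Expression values must be numeric.")
  rownames(m) <- genes
  lab <- readr::read_tsv(label_path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(lab) < 2L) rlang::abort("Label file must have two columns: sample, condition.")
  labels <- stats::setNames(lab[[2]], lab[[1]])
  expression_dataset(m, labels)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " genes x ", ncol(x$values), " samples (",
      sum(x$labels == "tumor"), " tumor / ", sum(x$labels == "normal"), " normal)\n", sep = "")
  if (length(x$zero_variance)) {
    cat("  zero-variance genes set to 0: ", length(x$zero_variance), "\n", sep = "")
  }
  invisible(x)
}

#' Gene symbols of an expression dataset
#' @param x An `expression_dataset`.
#' @return Character vector of gene symbols.
#' @export
expr_genes <- function(x) rownames(x$values)

# Column indices of each condition.
condition_index <- function(x) {
  list(tumor = which(x$labels == "tumor"), normal = which(x$labels == "normal"))
}
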