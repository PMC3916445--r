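#' Expression matrix container
#'
#' Holds a d x n real-valued gene expression matrix together with its gene and
#' sample identifiers. Values are kept exactly as supplied (they may be
#' negative, e.g. log-ratios); missing values are rejected.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @return An object of class `ExpressionMatrix` with elements `values`
#'   (dimnamed matrix), `gene_ids` and `sample_ids`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("dimensions of 'values' do not match the identifier vectors")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ID(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) stop("missing expression values are not supported")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Directed gene-interaction network container
#'
#' A directed graph over gene identifiers. By convention the adjacency matrix
#' `E` has `E[j, i] = 1` iff gene j regulates gene i, so the in-degree of
#' gene i (the number of its distinct regulators) is the i-th column sum.
#' Duplicate edges are collapsed to single edges and self-loops are dropped
#' (with a message reporting the counts), matching how aggregated interaction
#' resources are consumed.
#'
#' @param gene_ids character vector of unique node identifiers.
#' @param edges two-column matrix or data.frame of (regulator, target) pairs,
#'   either as gene identifiers or as 1-based indices into `gene_ids`.
#' @return An object of class `GeneNetwork` with elements `gene_ids`, `edges`
#'   (2-column integer matrix of regulator/target indices), `adjacency`
#'   (sparse 0/1 `Matrix` with entry (j,i) = 1 iff j regulates i) and
#'   `in_degree`.
#' @export
gene_network <- function(gene_ids, edges = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ID(s) in network: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  N <- length(gene_ids)
  if (is.null(edges) || NROW(edges) == 0L) {
    idx <- matrix(integer(0), 0L, 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("'edges' must have exactly two columns")
    if (is.character(edges)) {
      idx <- cbind(match(edges[, 1L], gene_ids), match(edges[, 2L], gene_ids))
      if (anyNA(idx))
        stop("edge references unknown gene ID(s): ",
             paste(unique(edges[is.na(idx)]), collapse = ", "))
    } else {
      idx <- matrix(as.integer(edges), ncol = 2L)
      if (anyNA(idx) || any(idx < 1L) || any(idx > N))
        stop("edge indices out of range")
    }
  }
  self <- idx[, 1L] == idx[, 2L]
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped")
    idx <- idx[!self, , drop = FALSE]
  }
  dup <- duplicated(idx)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
    idx <- idx[!dup, , drop = FALSE]
  }
  colnames(idx) <- c("regulator", "target")
  adjacency <- Matrix::sparseMatrix(i = idx[, 1L], j = idx[, 2L], x = 1,
                                    dims = c(N, N),
                                    dimnames = list(gene_ids, gene_ids))
  structure(list(gene_ids = gene_ids, edges = idx, adjacency = adjacency,
                 in_degree = Matrix::colSums(adjacency)),
            class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d genes, %d directed edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a gene network
#' @param net a `GeneNetwork`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)
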