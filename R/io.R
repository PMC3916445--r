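#' Read a gene expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene identifiers; the body must be fully numeric
#' with no missing values (input data are assumed pre-processed).
#'
#' @param path path to the TSV file.
#' @return An [expression_matrix()] with row/column order as in the file.
#' @export
load_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty expression matrix in ", path)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow(tab), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
    vals[, j] <- num
  }
  expression_matrix(vals, gene_ids, sample_ids)
}

#' Write a gene expression matrix to TSV
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  out <- data.frame(gene_id = expr$gene_ids, expr$values,
                    check.names = FALSE, row.names = NULL)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed gene-interaction network from a TSV edge list
#'
#' Each non-comment line holds a (regulator, target) pair separated by a tab;
#' lines starting with '#' are ignored. A third column, if present, is ignored
#' with a warning. Duplicate edges are collapsed, self-loops dropped, and --
#' when `gene_universe` is given -- edges touching genes outside the universe
#' are discarded (all with reported counts).
#'
#' @param path path to the edge-list file.
#' @param gene_universe optional ordered character vector restricting the node
#'   set; the returned network uses exactly this gene order.
#' @return A [gene_network()].
#' @export
load_network <- function(path, gene_universe = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf == 3L)) {
    warning(sum(nf == 3L), " line(s) with a third column; third column ignored")
  }
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad))
    stop(sprintf("malformed network line %d: expected 2 fields, got %d",
                 lineno[bad[1L]], nf[bad[1L]]))
  src <- vapply(fields, `[[`, "", 1L)
  dst <- vapply(fields, `[[`, "", 2L)
  if (!is.null(gene_universe)) {
    gene_universe <- as.character(gene_universe)
    inside <- src %in% gene_universe & dst %in% gene_universe
    if (any(!inside))
      message(sum(!inside), " edge(s) outside the gene universe discarded")
    src <- src[inside]; dst <- dst[inside]
    ids <- gene_universe
  } else {
    ids <- unique(c(rbind(src, dst)))
  }
  gene_network(ids, cbind(src, dst))
}

#' Write a network edge list to TSV
#'
#' @param net a `GeneNetwork`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "GeneNetwork"))
  out <- data.frame(regulator = net$gene_ids[net$edges[, 1L]],
                    target = net$gene_ids[net$edges[, 2L]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict expression matrix and network to their common genes
#'
#' Genes absent from either resource are ignored. The intersected gene order
#' follows the expression matrix, so downstream weight vectors and factor rows
#' align by construction; the edge set is restricted accordingly.
#'
#' @param expr an `ExpressionMatrix`.
#' @param net a `GeneNetwork`.
#' @return A list with elements `expression` and `network`, both over the
#'   common gene set in expression order.
#' @export
intersect_expression_network <- function(expr, net) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(net, "GeneNetwork"))
  common <- expr$gene_ids[expr$gene_ids %in% net$gene_ids]
  if (length(common) == 0L)
    stop("expression matrix and network share no genes")
  if (identical(common, expr$gene_ids) && identical(common, net$gene_ids))
    return(list(expression = expr, network = net))
  expr2 <- expression_matrix(expr$values[common, , drop = FALSE],
                             common, expr$sample_ids)
  old <- match(net$gene_ids, common)           # NA for genes dropped
  e <- net$edges
  reg <- old[e[, 1L]]; tgt <- old[e[, 2L]]
  keep <- !is.na(reg) & !is.na(tgt)
  net2 <- gene_network(common, cbind(reg[keep], tgt[keep]))
  list(expression = expr2, network = net2)
}

#' Write gene weights to TSV, sorted by descending weight
#'
#' @param gw a `GeneWeights` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(gw, path) {
  stopifnot(inherits(gw, "GeneWeights"))
  ord <- order(-gw$w)
  out <- data.frame(gene_id = gw$gene_ids[ord], weight = gw$w[ord])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
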