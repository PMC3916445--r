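#' Clustering accuracy under optimal label matching
#'
#' Cluster labels are arbitrary, so predicted labels are matched to true
#' labels by an exact optimal one-to-one assignment on the contingency table
#' (solved by dynamic programming over label subsets) before counting
#' agreements. When the predicted and true cluster counts differ, unmatched
#' clusters contribute no correct samples.
#'
#' @param pred vector of predicted cluster labels.
#' @param truth vector of true labels, same length.
#' @return Fraction of samples in \[0, 1\] whose optimally mapped predicted
#'   label equals the truth.
#' @export
clustering_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' must have the same length")
  tab <- table(pred, truth)
  if (nrow(tab) > 20L || ncol(tab) > 20L)
    stop("more than 20 clusters; exact assignment not attempted")
  best_assignment_score(unclass(tab)) / length(truth)
}

# Exact maximum assignment on a score matrix via bitmask DP: rows are
# processed in order, f[mask] = best score assigning the first popcount(mask)
# rows to the column set encoded by mask. Columns may outnumber rows or vice
# versa; leftover rows/columns stay unmatched (score 0).
best_assignment_score <- function(score) {
  score <- as.matrix(score)
  if (nrow(score) > ncol(score)) score <- t(score)
  r <- nrow(score); k <- ncol(score)
  # pad rows so every column subset of size r is reachable with skips allowed
  if (r < k) score <- rbind(score, matrix(0, k - r, k))
  nmask <- bitwShiftL(1L, k)
  f <- rep(-Inf, nmask)
  f[1L] <- 0
  bits <- bitwShiftL(1L, 0:(k - 1L))
  for (mask in 0:(nmask - 2L)) {
    cur <- f[mask + 1L]
    if (!is.finite(cur)) next
    i <- sum(bitwAnd(mask, bits) != 0L) + 1L   # next row to assign
    open <- bitwAnd(mask, bits) == 0L
    nm <- mask + bits[open]
    val <- cur + score[i, open]
    upd <- val > f[nm + 1L]
    f[nm[upd] + 1L] <- val[upd]
  }
  f[nmask]
}

#' Per-gene one-way ANOVA across sample clusters
#'
#' For every gene, tests whether mean expression differs between the sample
#' clusters with a fixed-effects one-way ANOVA F-test (computed by vectorized
#' sums of squares over all genes at once). Genes that separate the clusters
#' perfectly (zero within-cluster variance, positive between-cluster
#' variance) are reported at the smallest representable p-value; genes
#' constant everywhere get p = 1.
#'
#' @param expr an `ExpressionMatrix`.
#' @param labels per-sample cluster labels; at least 2 clusters, each with at
#'   least 2 samples.
#' @return Named numeric vector of p-values in \[0, 1\], one per gene.
#' @export
anova_per_gene <- function(expr, labels) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  X <- expr$values
  n <- ncol(X)
  if (length(labels) != n) stop("'labels' must have one entry per sample")
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 clusters")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("every cluster needs >= 2 samples; cluster(s) ",
         paste(names(sizes)[sizes < 2L], collapse = ","), " too small")
  ind <- stats::model.matrix(~ labels - 1)         # n x K indicator
  nk <- colSums(ind)
  means_k <- (X %*% ind) / rep(nk, each = nrow(X)) # d x K group means
  grand <- rowMeans(X)
  ssb <- rowSums(sweep(means_k, 2L, nk, `*`) * means_k) - n * grand^2
  sst <- rowSums(X^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  Fstat <- (ssb / (K - 1L)) / (ssw / (n - K))
  p <- stats::pf(Fstat, K - 1L, n - K, lower.tail = FALSE)
  p[is.nan(Fstat)] <- 1                 # constant gene: no variance anywhere
  p <- pmax(p, .Machine$double.xmin)    # perfect separators stay representable
  stats::setNames(p, expr$gene_ids)
}

#' Genes shared between the top of the p-value and weight rankings
#'
#' Orders genes by ANOVA p-value (ascending) and by gene weight (descending),
#' grows both prefix lists in lockstep, and collects genes present in both
#' prefixes until `k` genes are found (or the lists are exhausted). This
#' yields genes that both discriminate the subtypes and carry high network
#' weight. Ties in either ranking are broken by gene order.
#'
#' @param pvalues named numeric vector of per-gene p-values.
#' @param weights numeric vector of gene weights over the same genes (same
#'   order).
#' @param k number of shared genes requested.
#' @param gene_ids optional gene identifiers (defaults to `names(pvalues)`).
#' @return Character vector of up to `k` gene IDs, ordered by p-value
#'   ascending; shorter, with a warning, if fewer shared genes exist.
#' @export
top_shared_genes <- function(pvalues, weights, k, gene_ids = names(pvalues)) {
  d <- length(pvalues)
  if (length(weights) != d) stop("'pvalues' and 'weights' lengths differ")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(d))
  if (k > d) warning("k exceeds the number of genes; returning all shared genes")
  p_ord <- order(pvalues)                 # stable; ties by gene order
  w_ord <- order(-weights)
  in_p <- logical(d); in_w <- logical(d)
  shared <- integer(0)
  for (t in seq_len(d)) {
    in_p[p_ord[t]] <- TRUE
    in_w[w_ord[t]] <- TRUE
    shared <- which(in_p & in_w)
    if (length(shared) >= k) break
  }
  shared <- shared[order(pvalues[shared], shared)]
  gene_ids[utils::head(shared, k)]
}
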