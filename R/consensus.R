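#' Connectivity matrix of a hard clustering
#'
#' @param labels vector of cluster labels, one per item.
#' @return Symmetric 0/1 matrix with entry (i, j) = 1 iff items i and j carry
#'   the same label; the diagonal is all ones.
#' @export
connectivity_matrix <- function(labels) {
  stopifnot(length(labels) >= 1L)
  outer(labels, labels, `==`) * 1
}

#' Cophenetic correlation of a consensus matrix
#'
#' Treats `1 - C` as a distance, clusters it hierarchically (average linkage
#' by default), and returns the Pearson correlation between the input
#' distances and the cophenetic (dendrogram-induced) distances. Values near 1
#' indicate a stable, nearly binary consensus; an ideal 0/1 consensus
#' consistent with a partition yields exactly 1. A constant distance vector
#' (e.g. all runs agree on a single cluster) has no dispersion to correlate
#' and is reported as 1 with a warning.
#'
#' @param consensus symmetric matrix with entries in \[0, 1\] and unit
#'   diagonal.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A correlation in \[-1, 1\].
#' @export
cophenetic_coefficient <- function(consensus, linkage = "average") {
  consensus <- as.matrix(consensus)
  stopifnot(nrow(consensus) == ncol(consensus),
            all(consensus >= -1e-12), all(consensus <= 1 + 1e-12))
  dvec <- stats::as.dist(1 - consensus)
  if (stats::sd(dvec) == 0) {
    warning("constant consensus distances; cophenetic correlation reported as 1")
    return(1)
  }
  hc <- stats::hclust(dvec, method = linkage)
  coph <- stats::cophenetic(hc)
  if (stats::sd(coph) == 0) {
    warning("constant cophenetic distances; correlation undefined, reported as 0")
    return(0)
  }
  stats::cor(as.vector(dvec), as.vector(coph))
}

#' Consensus matrices over repeated random initializations
#'
#' Runs [ncis_fit()] `n_runs` times with seeds `base_seed`, `base_seed + 1`,
#' ..., averages the sample and gene connectivity matrices, and scores the
#' stability of each axis by its cophenetic correlation. Entry (i, j) of a
#' consensus matrix is the fraction of runs in which items i and j landed in
#' the same cluster.
#'
#' @inheritParams ncis_fit
#' @param n_runs number of random initializations (default 50).
#' @param base_seed seed of the first run; run r uses `base_seed + r - 1`.
#' @param linkage passed to [cophenetic_coefficient()].
#' @param ... further arguments passed to [ncis_fit()].
#' @return An object of class `ConsensusResult`: `consensus_samples` (n x n),
#'   `consensus_genes` (d x d), `rho_samples`, `rho_genes`, `rho_average`,
#'   `n_runs`, `sample_labels` and `gene_labels` (per-run label matrices).
#' @export
ncis_consensus <- function(X, w, m, c, n_runs = 50L, base_seed = 1L,
                           linkage = "average", ...) {
  stopifnot(n_runs >= 2L)
  X <- as.matrix(X)
  d <- nrow(X); n <- ncol(X)
  Ms <- matrix(0, n, n)
  Mg <- matrix(0, d, d)
  slab <- matrix(NA_integer_, n_runs, n)
  glab <- matrix(NA_integer_, n_runs, d)
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(ncis_fit(X, w, m, c, seed = base_seed + r - 1L, ...),
                    error = function(e)
                      stop("consensus run with seed ", base_seed + r - 1L,
                           " failed: ", conditionMessage(e)))
    slab[r, ] <- fit$sample_clusters
    glab[r, ] <- fit$gene_clusters
    Ms <- Ms + connectivity_matrix(fit$sample_clusters)
    Mg <- Mg + connectivity_matrix(fit$gene_clusters)
  }
  Ms <- Ms / n_runs
  Mg <- Mg / n_runs
  rho_s <- cophenetic_coefficient(Ms, linkage)
  rho_g <- cophenetic_coefficient(Mg, linkage)
  structure(list(consensus_samples = Ms, consensus_genes = Mg,
                 rho_samples = rho_s, rho_genes = rho_g,
                 rho_average = (rho_s + rho_g) / 2,
                 n_runs = n_runs, base_seed = base_seed,
                 sample_labels = slab, gene_labels = glab),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf(
    "ConsensusResult: %d runs; rho(samples) = %.4f, rho(genes) = %.4f, average = %.4f\n",
    x$n_runs, x$rho_samples, x$rho_genes, x$rho_average))
  invisible(x)
}

#' Scan a grid of cluster numbers and suggest (m, c)
#'
#' Computes the average cophenetic correlation for every (m, c) pair and
#' applies the "select where the averaged coefficient starts to decrease"
#' heuristic: for each m, scanning c in increasing order, the candidate is the
#' last c before the first strict decrease of the average coefficient (the
#' largest c, with a warning to extend the grid, if the sequence never
#' decreases). The overall suggestion is the candidate with the highest
#' average coefficient, ties broken by smaller c then smaller m. The full
#' table is always returned so the scan can be overridden by eye.
#'
#' @inheritParams ncis_consensus
#' @param grid data.frame (or 2-column matrix) of candidate `m`, `c` pairs.
#' @return A list with `table` (data.frame: m, c, rho_samples, rho_genes,
#'   rho_average) and `suggested` (one-row data.frame).
#' @export
select_m_c <- function(X, w, grid, n_runs = 50L, base_seed = 1L, ...) {
  grid <- as.data.frame(grid)
  names(grid)[1:2] <- c("m", "c")
  stopifnot(nrow(grid) >= 1L)
  tab <- grid
  tab$rho_samples <- tab$rho_genes <- tab$rho_average <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cr <- ncis_consensus(X, w, grid$m[i], grid$c[i], n_runs = n_runs,
                         base_seed = base_seed, ...)
    tab$rho_samples[i] <- cr$rho_samples
    tab$rho_genes[i] <- cr$rho_genes
    tab$rho_average[i] <- cr$rho_average
  }
  list(table = tab, suggested = suggest_from_table(tab))
}

#' Apply the "starts to decrease" selection rule to a coefficient table
#'
#' For each m, scanning c in increasing order, the per-m candidate is the
#' last c before the first strict decrease of `rho_average` (the largest c,
#' with a warning, if the sequence never decreases). The suggestion is the
#' candidate with the highest `rho_average`; ties broken by smaller c, then
#' smaller m.
#'
#' @param tab data.frame with columns `m`, `c`, `rho_average` (as produced by
#'   [select_m_c()]).
#' @return One-row data.frame: the suggested grid point.
#' @export
suggest_from_table <- function(tab) {
  stopifnot(all(c("m", "c", "rho_average") %in% names(tab)), nrow(tab) >= 1L)
  cand <- do.call(rbind, lapply(split(tab, tab$m), function(sub) {
    sub <- sub[order(sub$c), , drop = FALSE]
    drop <- which(diff(sub$rho_average) < 0)
    if (length(drop)) {
      sub[drop[1L], , drop = FALSE]
    } else {
      if (nrow(sub) > 1L)
        warning("rho_average never decreases for m = ", sub$m[1L],
                "; consider extending the c grid")
      sub[nrow(sub), , drop = FALSE]
    }
  }))
  cand <- cand[order(-cand$rho_average, cand$c, cand$m), , drop = FALSE]
  cand[1L, , drop = FALSE]
}
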