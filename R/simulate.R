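#' Generate a random directed gene network
#'
#' Draws a directed graph with a fixed number of distinct edges, no
#' self-loops and no duplicates. With `out_degree = "heavy"` (default)
#' regulators are sampled with Zipf-like propensities so a minority of hub
#' genes regulates many targets, mimicking the skewed out-degree of curated
#' regulatory networks; `"uniform"` samples regulators uniformly.
#'
#' @param n_genes number of genes (>= 2); IDs are `g0001`, `g0002`, ...
#' @param n_edges number of distinct directed edges; alternatively give
#'   `edge_density` (fraction of the `n_genes * (n_genes - 1)` possible
#'   edges).
#' @param edge_density optional density in \[0, 1\], used when `n_edges` is
#'   missing.
#' @param out_degree `"heavy"` or `"uniform"`.
#' @param seed integer seed; the edge set is deterministic given the seed.
#' @return A [gene_network()].
#' @export
generate_network <- function(n_genes, n_edges = NULL, edge_density = NULL,
                             out_degree = c("heavy", "uniform"), seed = 1L) {
  out_degree <- match.arg(out_degree)
  stopifnot(n_genes >= 2L)
  max_edges <- as.numeric(n_genes) * (n_genes - 1)
  if (is.null(n_edges)) {
    if (is.null(edge_density)) stop("give either 'n_edges' or 'edge_density'")
    n_edges <- round(edge_density * max_edges)
  }
  if (n_edges > max_edges)
    stop("requested ", n_edges, " edges but only ", max_edges, " are possible")
  ids <- sprintf("g%04d", seq_len(n_genes))
  if (n_edges == 0L) return(gene_network(ids))
  prop <- if (out_degree == "heavy") 1 / seq_len(n_genes) else rep(1, n_genes)
  edges <- with_seed(seed, {
    found <- matrix(integer(0), 0L, 2L)
    while (nrow(found) < n_edges) {
      need <- 2L * (n_edges - nrow(found)) + 10L
      reg <- sample.int(n_genes, need, replace = TRUE, prob = prop)
      tgt <- sample.int(n_genes, need, replace = TRUE)
      cand <- rbind(found, cbind(reg, tgt))
      cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
      found <- cand[!duplicated(cand), , drop = FALSE]
    }
    found[seq_len(n_edges), , drop = FALSE]
  })
  gene_network(ids, edges)
}

#' Simulate subtype-structured expression on a known network
#'
#' Each sample belongs to one of K subtypes. A fraction of "driver" genes
#' receives subtype-specific baseline means (drawn from normal distributions
#' whose spread is `effect_size`, or supplied directly via `baseline_means`);
#' every gene's expression is then its baseline plus `propagation` times the
#' average expression of its regulators, solved to the linear fixed point so
#' subtype signal flows along network edges, plus Gaussian noise. The fixed
#' point exists because `|propagation| < 1` and each gene averages over its
#' regulators (the propagation operator has row sums at most 1).
#'
#' @param net a `GeneNetwork` over the genes to simulate.
#' @param n_samples number of samples; must equal `sum(subtype_sizes)`.
#' @param subtype_sizes integer vector of per-subtype sample counts (K >= 2).
#' @param driver_fraction fraction of genes given subtype-specific baselines.
#'   The default 1 mirrors per-gene subtype means estimated from real tumor
#'   profiles, where essentially every gene's mean differs somewhat between
#'   subtypes; lower it to concentrate the signal in a driver subset.
#' @param effect_size standard deviation of the subtype-specific baseline
#'   means (default 2); larger values separate the subtypes more strongly.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 1).
#' @param propagation coefficient scaling the regulator average, absolute
#'   value < 1 (default 0.5).
#' @param baseline_means optional d x K matrix of per-gene, per-subtype
#'   baseline means overriding the random draw.
#' @param seed integer seed.
#' @return An object of class `SimulatedDataset`: `expression`
#'   (`ExpressionMatrix`), `network`, `true_labels` (1..K per sample),
#'   `driver_genes`, `noisy_gene_ids` (empty until
#'   [inject_noisy_genes()]), and `config`.
#' @export
simulate_expression <- function(net, n_samples, subtype_sizes,
                                driver_fraction = 1, effect_size = 2,
                                noise_sd = 1, propagation = 0.5,
                                baseline_means = NULL, seed = 1L) {
  stopifnot(inherits(net, "GeneNetwork"))
  K <- length(subtype_sizes)
  if (K < 2L) stop("need at least 2 subtypes")
  if (sum(subtype_sizes) != n_samples)
    stop("sum(subtype_sizes) must equal n_samples")
  if (abs(propagation) >= 1)
    stop("'propagation' must have absolute value < 1 for the fixed point to exist")
  d <- length(net$gene_ids)
  labels <- rep(seq_len(K), subtype_sizes)
  sim <- with_seed(seed, {
    if (is.null(baseline_means)) {
      baseline_means <- matrix(0, d, K)
      n_driver <- round(driver_fraction * d)
      drivers <- sort(sample.int(d, n_driver))
      baseline_means[drivers, ] <- matrix(stats::rnorm(n_driver * K,
                                                       sd = effect_size),
                                          n_driver, K)
    } else {
      baseline_means <- as.matrix(baseline_means)
      stopifnot(nrow(baseline_means) == d, ncol(baseline_means) == K)
      drivers <- which(apply(baseline_means, 1L, function(x) length(unique(x)) > 1L))
    }
    B <- baseline_means[, labels, drop = FALSE]
    # fixed point x = b + propagation * D^-1 E^T x, per sample
    deg <- net$in_degree
    inv <- ifelse(deg > 0, 1 / deg, 0)
    M <- Matrix::Diagonal(x = inv) %*% Matrix::t(net$adjacency)
    X0 <- as.matrix(Matrix::solve(Matrix::Diagonal(d) - propagation * M, B))
    X <- X0 + matrix(stats::rnorm(d * n_samples, sd = noise_sd), d, n_samples)
    list(X = X, drivers = drivers)
  })
  expr <- expression_matrix(sim$X, net$gene_ids,
                            sprintf("s%04d", seq_len(n_samples)))
  structure(list(expression = expr, network = net, true_labels = labels,
                 driver_genes = net$gene_ids[sim$drivers],
                 noisy_gene_ids = character(0),
                 config = list(n_samples = n_samples,
                               subtype_sizes = subtype_sizes,
                               driver_fraction = driver_fraction,
                               effect_size = effect_size, noise_sd = noise_sd,
                               propagation = propagation, seed = seed)),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf(
    "SimulatedDataset: %d genes x %d samples, %d subtypes, %d noisy gene(s)\n",
    length(x$expression$gene_ids), length(x$expression$sample_ids),
    length(x$config$subtype_sizes), length(x$noisy_gene_ids)))
  invisible(x)
}

#' Gene weights from network structure alone
#'
#' Runs the closed-form weight solver with the variability seed replaced by
#' the all-ones vector, so the weights reflect only each gene's position in
#' the network. Used to pick the least network-relevant genes for noise
#' injection.
#'
#' @param net a `GeneNetwork`.
#' @param alpha damping factor (default 0.85).
#' @return A `GeneWeights` object.
#' @export
network_only_weights <- function(net, alpha = 0.85) {
  train_weights_closed_form(net, rep(1, length(net$gene_ids)), alpha)
}

#' Permute the expression rows of the least network-relevant genes
#'
#' Selects the `l` genes with the lowest [network_only_weights()] (ties broken
#' by gene order) and independently permutes each selected gene's expression
#' values across samples. The permutation preserves each row's value multiset
#' while destroying any subtype signal, producing "uninformative" noisy
#' genes.
#'
#' @param dataset a `SimulatedDataset`.
#' @param l number of genes to permute (0 <= l <= d).
#' @param seed integer seed for the permutations.
#' @param alpha damping factor for the network-only weights (default 0.85).
#' @return The dataset with permuted rows and `noisy_gene_ids` recorded.
#' @export
inject_noisy_genes <- function(dataset, l, seed = 1L, alpha = 0.85) {
  stopifnot(inherits(dataset, "SimulatedDataset"))
  d <- length(dataset$expression$gene_ids)
  if (l < 0L || l > d) stop("'l' must lie in [0, ", d, "]")
  if (l == 0L) return(dataset)
  w <- network_only_weights(dataset$network, alpha)$w
  sel <- order(w)[seq_len(l)]              # stable: ties broken by gene index
  X <- dataset$expression$values
  n <- ncol(X)
  ident <- 0L
  with_seed(seed, {
    for (g in sel) {
      p <- sample.int(n)
      if (all(p == seq_len(n))) ident <- ident + 1L
      X[g, ] <- X[g, p]
    }
  })
  if (ident > 0L)
    message(ident, " identity permutation(s) drawn during noise injection")
  dataset$expression <- expression_matrix(X, dataset$expression$gene_ids,
                                          dataset$expression$sample_ids)
  dataset$noisy_gene_ids <- dataset$expression$gene_ids[sel]
  dataset$config$l <- l
  dataset$config$noise_seed <- seed
  dataset
}

#' One-call simulation of a subtype study
#'
#' Convenience wrapper chaining [generate_network()], [simulate_expression()]
#' and [inject_noisy_genes()]. The defaults describe the desk-scale study the
#' package's tests exercise: 900 genes on a heavy-tailed network with ~2
#' edges per gene, 150 samples in 3 balanced subtypes, strong subtype effect
#' relative to noise, and ~11% of the genes permuted as noise.
#'
#' @param n_genes,n_edges,out_degree passed to [generate_network()].
#' @param subtype_sizes,driver_fraction,effect_size,noise_sd,propagation
#'   passed to [simulate_expression()].
#' @param l number of noisy genes for [inject_noisy_genes()].
#' @param alpha damping factor for the network-only weights.
#' @param seed single integer driving all three stages.
#' @return A `SimulatedDataset`.
#' @export
simulate_dataset <- function(n_genes = 900L, n_edges = 1800L,
                             out_degree = "heavy",
                             subtype_sizes = c(50L, 50L, 50L),
                             driver_fraction = 1, effect_size = 2,
                             noise_sd = 1, propagation = 0.5, l = 100L,
                             alpha = 0.85, seed = 1L) {
  net <- generate_network(n_genes, n_edges, out_degree = out_degree,
                          seed = seed)
  ds <- simulate_expression(net, sum(subtype_sizes), subtype_sizes,
                            driver_fraction = driver_fraction,
                            effect_size = effect_size, noise_sd = noise_sd,
                            propagation = propagation, seed = seed + 1L)
  inject_noisy_genes(ds, l, seed = seed + 2L, alpha = alpha)
}
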