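#' Weighted co-clustering objective
#'
#' The weighted squared Frobenius norm
#' `J = sum_i w_i || X[i, ] - (G S F^T)[i, ] ||^2`, equivalently
#' `tr(X^T W X - 2 X^T W G S F^T + F S^T G^T W G S F^T)` with `W = diag(w)`.
#' Gene weights multiply the row (gene) residual norms, so high-weight genes
#' dominate the fit.
#'
#' @param X d x n numeric expression matrix.
#' @param w length-d nonnegative gene weights.
#' @param F_mat n x c nonnegative sample partition matrix.
#' @param G_mat d x m nonnegative gene partition matrix.
#' @param S m x c real centroid matrix (entries may be negative).
#' @return The objective value, a single nonnegative number.
#' @export
snmtf_objective <- function(X, w, F_mat, G_mat, S) {
  check_snmtf_shapes(X, w, F_mat, G_mat, S)
  sum(w * rowSums((X - G_mat %*% S %*% t(F_mat))^2))
}

check_snmtf_shapes <- function(X, w, F_mat, G_mat, S) {
  d <- nrow(X); n <- ncol(X)
  if (length(w) != d) stop("length of 'w' does not match nrow(X)")
  if (nrow(F_mat) != n) stop("nrow(F_mat) does not match ncol(X)")
  if (nrow(G_mat) != d) stop("nrow(G_mat) does not match nrow(X)")
  if (nrow(S) != ncol(G_mat) || ncol(S) != ncol(F_mat))
    stop("'S' must be m x c, conforming with G_mat and F_mat")
  invisible(TRUE)
}

positive_part <- function(M) (abs(M) + M) / 2
negative_part <- function(M) (abs(M) - M) / 2

#' Closed-form centroid update
#'
#' Computes the exact minimizer `S = (G^T W G)^-1 G^T W X F (F^T F)^-1` of the
#' weighted objective with the partition matrices held fixed. For hard 0/1
#' partitions, `S[k, l]` is the weight-weighted mean of X over genes in gene
#' cluster k and samples in sample cluster l, i.e. the bi-cluster centroids.
#'
#' @inheritParams snmtf_objective
#' @return The m x c centroid matrix.
#' @export
update_S <- function(X, w, F_mat, G_mat) {
  GtWG <- crossprod(G_mat, w * G_mat)
  FtF <- crossprod(F_mat)
  dg <- diag(as.matrix(GtWG))
  if (any(dg == 0))
    stop("singular G^T W G: gene cluster ",
         paste(which(dg == 0), collapse = ","),
         " is empty or has zero total weight")
  df <- diag(as.matrix(FtF))
  if (any(df == 0))
    stop("singular F^T F: sample cluster ",
         paste(which(df == 0), collapse = ","), " is empty")
  tryCatch(solve(GtWG, crossprod(w * G_mat, X) %*% F_mat %*% solve(FtF)),
           error = function(e)
             stop("degenerate cluster structure (singular G^T W G or F^T F): ",
                  conditionMessage(e)))
}

#' Multiplicative update of the sample partition matrix
#'
#' Applies `F <- F * (A^+ + F B^-) / (A^- + F B^+)` with `A = X^T W G S` and
#' `B = S^T G^T W G S`, where `M^+ = (|M| + M)/2` and `M^- = (|M| - M)/2` are
#' the positive and negative parts. With `update_form = "sqrt"` the ratio is
#' applied under a square root; both forms share the same fixed points.
#' Denominators are floored by a small epsilon, so entries at exactly zero
#' stay zero. Rows are not rescaled here; see [ncis_fit()] for how feasibility
#' (rows summing to 1) is restored.
#'
#' @inheritParams snmtf_objective
#' @param update_form `"ratio"` (the bare KKT ratio, default) or `"sqrt"`.
#' @param eps denominator floor, default 1e-12.
#' @return The updated n x c matrix.
#' @export
update_F <- function(X, w, G_mat, S, F_mat, update_form = c("ratio", "sqrt"),
                     eps = 1e-12) {
  update_form <- match.arg(update_form)
  A <- crossprod(X, (w * G_mat) %*% S)
  B <- crossprod(S, crossprod(G_mat, w * G_mat) %*% S)
  R <- (positive_part(A) + F_mat %*% negative_part(B)) /
       (negative_part(A) + F_mat %*% positive_part(B) + eps)
  if (update_form == "sqrt") R <- sqrt(R)
  F_mat * R
}

#' Multiplicative update of the gene partition matrix
#'
#' Applies `G <- G * (C^+ + W G D^-) / (C^- + W G D^+)` with `C = W X F S^T`
#' and `D = S F^T F S^T` (the update intermediate, distinct from the network
#' degree matrix). Symmetric to [update_F()]; a zero-weight gene has a zero
#' row in both C and WGD, so its row is left untouched by the floored ratio
#' and is resolved at the end of [ncis_fit()].
#'
#' @inheritParams update_F
#' @return The updated d x m matrix.
#' @export
update_G <- function(X, w, F_mat, S, G_mat, update_form = c("ratio", "sqrt"),
                     eps = 1e-12) {
  update_form <- match.arg(update_form)
  Cm <- w * (X %*% F_mat %*% t(S))
  D2 <- S %*% crossprod(F_mat) %*% t(S)
  WG <- w * G_mat
  R <- (positive_part(Cm) + WG %*% negative_part(D2)) /
       (negative_part(Cm) + WG %*% positive_part(D2) + eps)
  if (update_form == "sqrt") R <- sqrt(R)
  G_mat * R
}

#' Hard cluster assignments from a relaxed partition matrix
#'
#' @param P nonnegative matrix, one row per item.
#' @return Integer vector of 1-based labels: the index of each row's maximum,
#'   ties broken by the lowest index.
#' @export
hard_assignments <- function(P) {
  stopifnot(all(P >= 0))
  max.col(P, ties.method = "first")
}

# Seeded initialization of the partition matrices. "kmeans" (default) seeds
# each factor with a k-means labeling (random starting centers) softened by a
# 0.2 offset, the standard indicator + 0.2 scheme of the tri-factorization
# literature; uniform(0,1) init sits close to a column-permutation saddle of
# the multiplicative dynamics and can stall there, so it is kept only as an
# explicit option. k-means falling over (e.g. fewer distinct rows than
# centers) falls back to a random partition.
init_factors <- function(X, m, c, seed, init = "kmeans", nstart = 5L) {
  d <- nrow(X); n <- ncol(X)
  soften <- function(lab, k) {
    P <- matrix(0.2, length(lab), k)
    P[cbind(seq_along(lab), lab)] <- 1.2
    P / rowSums(P)
  }
  with_seed(seed, {
    if (init == "uniform") {
      F_mat <- matrix(stats::runif(n * c), n, c)
      G_mat <- matrix(stats::runif(d * m), d, m)
      list(F_mat = F_mat / rowSums(F_mat), G_mat = G_mat / rowSums(G_mat))
    } else {
      fl <- tryCatch(stats::kmeans(t(X), c, nstart = nstart)$cluster,
                     error = function(e) sample(rep_len(seq_len(c), n)))
      gl <- tryCatch(stats::kmeans(X, m, nstart = nstart)$cluster,
                     error = function(e) sample(rep_len(seq_len(m), d)))
      list(F_mat = soften(fl, c), G_mat = soften(gl, m))
    }
  })
}

#' Fit the weighted semi-NMF tri-factorization co-clustering model
#'
#' Minimizes the weighted objective by alternating the closed-form S update
#' with multiplicative updates of F and G until the relative change in the
#' objective falls below `tol` or `max_iter` sweeps are reached. Before each
#' S update, F and G are divided by their mean row sum; this global rescale
#' is absorbed exactly by the closed-form S and keeps the iterates well
#' scaled without disturbing the monotone descent of the objective. Rows of
#' F and G are renormalized to sum 1 once at convergence, which preserves
#' every argmax assignment. If a cluster empties during the S update the fit
#' restarts from a new seed derived from `seed`, up to `max_restarts` times.
#'
#' @inheritParams snmtf_objective
#' @param m number of gene clusters (2 <= m <= d).
#' @param c number of sample clusters / subtypes (2 <= c <= n).
#' @param seed integer seed; the fit is bitwise reproducible given the seed.
#' @param tol relative objective-change convergence threshold (default 1e-6).
#' @param max_iter sweep cap (default 500).
#' @param update_form passed to [update_F()] and [update_G()].
#' @param init `"kmeans"` (default; seeded k-means labelings softened by a
#'   0.2 offset) or `"uniform"` (i.i.d. uniform rows). See Details.
#' @param init_nstart number of random k-means starts per axis for the
#'   `"kmeans"` init (default 5); runs remain stochastic across seeds.
#' @param max_restarts empty-cluster restart budget (default 10).
#' @return An object of class `CoclusterModel`: list with `F_mat`, `G_mat`,
#'   `S`, `m`, `c`, `objective_trace`, `sample_clusters`, `gene_clusters`,
#'   `seed`, `seed_used`, `converged`, `iterations`, `zero_weight_genes`,
#'   `update_form`.
#' @export
ncis_fit <- function(X, w, m, c, seed = 1L, tol = 1e-6, max_iter = 500L,
                     update_form = c("ratio", "sqrt"),
                     init = c("kmeans", "uniform"), init_nstart = 5L,
                     max_restarts = 10L) {
  update_form <- match.arg(update_form)
  init <- match.arg(init)
  X <- as.matrix(X)
  d <- nrow(X); n <- ncol(X)
  if (length(w) != d) stop("length of 'w' does not match nrow(X)")
  if (any(w < 0)) stop("gene weights must be nonnegative")
  if (m < 2L || m > d) stop("'m' must satisfy 2 <= m <= d")
  if (c < 2L || c > n) stop("'c' must satisfy 2 <= c <= n")
  for (attempt in 0:max_restarts) {
    seed_used <- as.integer((as.numeric(seed) + 999983 * attempt) %% .Machine$integer.max)
    fit <- try(ncis_fit_once(X, w, m, c, seed_used, tol, max_iter, update_form,
                             init, init_nstart),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      fit$seed <- seed
      fit$seed_used <- seed_used
      return(fit)
    }
  }
  stop("co-clustering failed after ", max_restarts + 1L, " seeded attempts: ",
       attr(fit, "condition")$message)
}

ncis_fit_once <- function(X, w, m, c, seed, tol, max_iter, update_form, init,
                          init_nstart = 5L) {
  d <- nrow(X); n <- ncol(X)
  ini <- init_factors(X, m, c, seed, init, init_nstart)
  F_mat <- ini$F_mat; G_mat <- ini$G_mat
  trace <- numeric(0)
  converged <- FALSE
  S <- NULL
  for (it in seq_len(max_iter)) {
    F_mat <- F_mat / mean(rowSums(F_mat))
    G_mat <- G_mat / mean(rowSums(G_mat))
    S <- update_S(X, w, F_mat, G_mat)
    F_mat <- update_F(X, w, G_mat, S, F_mat, update_form)
    G_mat <- update_G(X, w, F_mat, S, G_mat, update_form)
    J <- snmtf_objective(X, w, F_mat, G_mat, S)
    trace <- c(trace, J)
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) / max(trace[it - 1L], 1e-12) < tol) {
      converged <- TRUE
      break
    }
  }
  # restore feasibility (rows sum to 1); uniform fallback for rows that are
  # all zero (zero-weight genes or fully locked rows), flagged for the caller
  zero_w <- which(w == 0)
  fixrow <- function(P) {
    bad <- rowSums(P) <= 0
    if (any(bad)) P[bad, ] <- 1 / ncol(P)
    P / rowSums(P)
  }
  if (length(zero_w)) G_mat[zero_w, ] <- 1 / m
  F_mat <- fixrow(F_mat)
  G_mat <- fixrow(G_mat)
  structure(list(F_mat = F_mat, G_mat = G_mat, S = S, m = m, c = c,
                 objective_trace = trace,
                 sample_clusters = hard_assignments(F_mat),
                 gene_clusters = hard_assignments(G_mat),
                 converged = converged, iterations = length(trace),
                 zero_weight_genes = zero_w, update_form = update_form),
            class = "CoclusterModel")
}

#' @export
print.CoclusterModel <- function(x, ...) {
  cat(sprintf(
    "CoclusterModel: %d gene clusters x %d sample clusters; %d sweep(s), %s (final J = %.6g)\n",
    x$m, x$c, x$iterations,
    if (x$converged) "converged" else "iteration cap reached",
    x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
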