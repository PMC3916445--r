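test_that("objective evaluates the weighted row-residual norm", {
  pb <- planted_biclusters()
  G <- cbind(pb$gene_blocks == 1, pb$gene_blocks == 2) * 1
  F_mat <- cbind(pb$sample_blocks == 1, pb$sample_blocks == 2) * 1
  S <- rbind(c(1, 3), c(5, 9))
  expect_equal(snmtf_objective(pb$X, rep(1, 8), F_mat, G, S), 0)
  expect_equal(snmtf_objective(pb$X, rep(0, 8), F_mat, G, S), 0)

  # 2x2 hand example: zero residual, then S perturbed to zero
  X <- diag(2)
  expect_equal(snmtf_objective(X, c(1, 2), diag(2), diag(2), diag(2)), 0)
  expect_equal(snmtf_objective(X, c(1, 2), diag(2), diag(2), matrix(0, 2, 2)), 3)
  expect_error(snmtf_objective(X, c(1, 2, 3), diag(2), diag(2), diag(2)), "w")
})

test_that("closed-form S equals weighted block means on hard partitions", {
  X <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(5, 5, 8, 8))
  G <- rbind(c(1, 0), c(1, 0), c(0, 1))
  F_mat <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(update_S(X, c(1, 1, 1), F_mat, G), rbind(c(1, 2), c(5, 8)))

  # single block: grand mean
  ones_G <- matrix(1, 3, 1)
  ones_F <- matrix(1, 4, 1)
  expect_equal(update_S(X, rep(1, 3), ones_F, ones_G)[1, 1], mean(X))

  # weighted centroid: (0*1 + 4*3) / (1 + 3) = 3
  Xw <- rbind(rep(0, 4), rep(4, 4))
  expect_equal(update_S(Xw, c(1, 3), ones_F, matrix(1, 2, 1))[1, 1], 3)

  # brute-force weighted block-mean oracle on random hard partitions
  set.seed(11)
  for (trial in 1:20) {
    d <- sample(4:9, 1); n <- sample(4:8, 1)
    m <- sample(2:3, 1); c <- sample(2:3, 1)
    gl <- sample(rep_len(seq_len(m), d)); sl <- sample(rep_len(seq_len(c), n))
    X <- matrix(rnorm(d * n), d, n)
    w <- runif(d, 0.1, 2)
    Gh <- outer(gl, seq_len(m), `==`) * 1
    Fh <- outer(sl, seq_len(c), `==`) * 1
    S <- update_S(X, w, Fh, Gh)
    for (k in seq_len(m)) for (l in seq_len(c)) {
      block <- X[gl == k, sl == l, drop = FALSE]
      bw <- rep(w[gl == k], ncol(block))
      expect_equal(S[k, l], sum(block * bw) / sum(bw), tolerance = 1e-10)
    }
  }

  # empty cluster is reported
  G_empty <- rbind(c(1, 0), c(1, 0), c(1, 0))
  expect_error(update_S(X[1:3, , drop = FALSE] * 0 + 1, rep(1, 3), F_mat, G_empty),
               "gene cluster 2")
})

test_that("exact factorizations are fixed points of both multiplicative updates", {
  set.seed(5)
  for (form in c("ratio", "sqrt")) {
    G <- matrix(runif(12, 0.1, 1), 6, 2); G <- G / rowSums(G)
    F_mat <- matrix(runif(8, 0.1, 1), 4, 2); F_mat <- F_mat / rowSums(F_mat)
    S <- matrix(rnorm(4), 2, 2)
    X <- G %*% S %*% t(F_mat)
    w <- runif(6, 0.5, 2)
    F2 <- update_F(X, w, G, S, F_mat, update_form = form)
    G2 <- update_G(X, w, F_mat, S, G, update_form = form)
    expect_equal(F2, F_mat, tolerance = 1e-8)
    expect_equal(G2, G, tolerance = 1e-8)
  }
})

test_that("multiplicative updates cannot revive an exact zero", {
  set.seed(6)
  G <- matrix(runif(12, 0.1, 1), 6, 2)
  F_mat <- matrix(runif(8, 0.1, 1), 4, 2)
  F_mat[2, 1] <- 0
  G[3, 2] <- 0
  S <- matrix(rnorm(4), 2, 2)
  X <- matrix(rnorm(24), 6, 4)
  w <- runif(6, 0.5, 2)
  expect_identical(update_F(X, w, G, S, F_mat)[2, 1], 0)
  expect_identical(update_G(X, w, F_mat, S, G)[3, 2], 0)
})

test_that("the objective is non-increasing across full sweeps", {
  set.seed(13)
  for (trial in 1:200) {
    d <- sample(5:30, 1); n <- sample(5:20, 1)
    m <- sample(2:4, 1); c <- sample(2:4, 1)
    X <- matrix(rnorm(d * n), d, n)
    w <- runif(d, 0.05, 1)
    fit <- ncis_fit(X, w, m, c, seed = trial, max_iter = 10)
    tr <- fit$objective_trace
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= abs(tr[-length(tr)]) * 1e-9 + 1e-12))
  }
})

test_that("fit recovers noiseless planted biclusters and is deterministic", {
  pb <- planted_biclusters(d = 12, n = 10)
  ok <- 0
  for (s in 1:40) {
    fit <- ncis_fit(pb$X, rep(1, 12), 2, 2, seed = s)
    if (clustering_accuracy(fit$sample_clusters, pb$sample_blocks) == 1 &&
        clustering_accuracy(fit$gene_clusters, pb$gene_blocks) == 1)
      ok <- ok + 1
  }
  expect_gte(ok / 40, 0.95)

  f1 <- ncis_fit(pb$X, rep(1, 12), 2, 2, seed = 3)
  f2 <- ncis_fit(pb$X, rep(1, 12), 2, 2, seed = 3)
  expect_identical(f1$F_mat, f2$F_mat)
  expect_identical(f1$G_mat, f2$G_mat)
  expect_identical(f1$S, f2$S)

  # rows of the returned factors lie on the simplex
  expect_equal(rowSums(f1$F_mat), rep(1, 10), tolerance = 1e-8)
  expect_equal(rowSums(f1$G_mat), rep(1, 12), tolerance = 1e-8)
  expect_true(all(f1$F_mat >= 0) && all(f1$G_mat >= 0))
})

test_that("weight scaling leaves factors and assignments unchanged", {
  set.seed(21)
  X <- matrix(rnorm(60), 10, 6)
  w <- runif(10, 0.2, 1)
  f1 <- ncis_fit(X, w, 3, 2, seed = 4)
  f2 <- ncis_fit(X, 5 * w, 3, 2, seed = 4)
  # the epsilon floor in the update denominators is not scale-invariant, so
  # iterates agree only up to a small drift accumulated over the sweeps
  expect_equal(f1$F_mat, f2$F_mat, tolerance = 1e-4)
  expect_equal(f1$G_mat, f2$G_mat, tolerance = 1e-4)
  expect_identical(f1$sample_clusters, f2$sample_clusters)
  expect_identical(f1$gene_clusters, f2$gene_clusters)
})

test_that("zero-weight genes pass through fit with a flagged uniform row", {
  pb <- planted_biclusters(d = 12, n = 10)
  w <- rep(1, 12); w[c(2, 7)] <- 0
  fit <- ncis_fit(pb$X, w, 2, 2, seed = 1)
  expect_identical(fit$zero_weight_genes, c(2L, 7L))
  expect_equal(fit$G_mat[2, ], rep(0.5, 2))
  expect_equal(fit$G_mat[7, ], rep(0.5, 2))
})

test_that("hard assignments take the row argmax with lowest-index ties", {
  expect_identical(hard_assignments(rbind(c(0.2, 0.7, 0.1))), 2L)
  expect_identical(hard_assignments(rbind(c(0.5, 0.5))), 1L)
  P <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_identical(hard_assignments(P), c(1L, 3L, 2L))
  expect_error(hard_assignments(rbind(c(-1, 2))))
})
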