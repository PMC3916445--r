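# Small in-code fixtures shared across the test files.

# d x n block matrix with 2 gene blocks x 2 sample blocks and distinct block
# means; returns the matrix plus the true labels on both axes.
planted_biclusters <- function(d = 8, n = 6, means = c(1, 3, 5, 9)) {
  gb <- rep(1:2, each = d / 2)
  sb <- rep(1:2, each = n / 2)
  X <- outer(gb == 1, sb == 1) * means[1] + outer(gb == 1, sb == 2) * means[2] +
       outer(gb == 2, sb == 1) * means[3] + outer(gb == 2, sb == 2) * means[4]
  list(X = X, gene_blocks = gb, sample_blocks = sb)
}

tiny_expr <- function() {
  expression_matrix(rbind(c(1.5, 2.5), c(-1, 0), c(10, 20)),
                    gene_ids = c("a", "b", "c"),
                    sample_ids = c("s1", "s2"))
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Brute-force clustering accuracy: pad the contingency table to a square and
# enumerate every permutation (feasible for <= 6 clusters).
brute_force_accuracy <- function(pred, truth) {
  tab <- unclass(table(pred, truth))
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- perm_all(k)
  best <- max(apply(perms, 1, function(p) sum(sq[cbind(seq_len(k), p)])))
  best / length(truth)
}

perm_all <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perm_all(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub), k - 1))
  }))
}

# Direct dense-matrix oracle for the weight fixed point:
# w_raw = (1 - alpha) * solve(I - alpha * E %*% Dinv) %*% nmad
weights_oracle <- function(net, nmad, alpha) {
  E <- as.matrix(net$adjacency)
  deg <- colSums(E)
  Dinv <- diag(ifelse(deg > 0, 1 / deg, 0), length(deg))
  as.numeric((1 - alpha) * solve(diag(length(deg)) - alpha * E %*% Dinv) %*% nmad)
}
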