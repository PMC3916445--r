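test_that("generated networks have the requested size and no degenerate edges", {
  net <- generate_network(10, 15, seed = 1)
  expect_identical(n_edges(net), 15L)
  expect_false(any(net$edges[, 1] == net$edges[, 2]))
  expect_false(any(duplicated(net$edges)))

  net_b <- generate_network(10, 15, seed = 1)
  expect_identical(net$edges, net_b$edges)
  net_c <- generate_network(10, 15, seed = 2)
  expect_false(identical(net$edges, net_c$edges))

  expect_identical(n_edges(generate_network(6, edge_density = 0, seed = 1)), 0L)
  expect_error(generate_network(4, 13, seed = 1), "possible")
})

test_that("heavy-tailed option concentrates out-degree on hub regulators", {
  net <- generate_network(200, 600, out_degree = "heavy", seed = 3)
  outdeg <- tabulate(net$edges[, 1], 200)
  unif <- generate_network(200, 600, out_degree = "uniform", seed = 3)
  outdeg_u <- tabulate(unif$edges[, 1], 200)
  expect_gt(max(outdeg), 3 * max(outdeg_u))
})

test_that("expression baselines and network propagation behave as specified", {
  # no network, no noise: values are exactly the subtype baselines
  empty <- gene_network(c("g1", "g2"))
  bm <- rbind(c(1, 4), c(-2, 0.5))
  ds <- simulate_expression(empty, 4, c(2, 2), noise_sd = 0,
                            baseline_means = bm, seed = 1)
  expect_equal(unname(ds$expression$values), bm[, c(1, 1, 2, 2)])
  expect_identical(ds$true_labels, c(1L, 1L, 2L, 2L))

  # chain g1 -> g2 with propagation 0.5: downstream values halve
  chain <- gene_network(c("g1", "g2"), rbind(c("g1", "g2")))
  bm2 <- rbind(c(0, 10), c(0, 0))
  ds2 <- simulate_expression(chain, 4, c(2, 2), noise_sd = 0,
                             propagation = 0.5, baseline_means = bm2, seed = 1)
  expect_equal(unname(ds2$expression$values["g2", ]), c(0, 0, 5, 5))

  expect_error(simulate_expression(chain, 4, c(2, 2), propagation = 1),
               "propagation")
  expect_error(simulate_expression(chain, 5, c(2, 2)), "subtype_sizes")

  # per-subtype sample counts match the configuration
  net <- generate_network(20, 40, seed = 2)
  ds3 <- simulate_expression(net, 9, c(2, 3, 4), seed = 2)
  expect_identical(as.integer(table(ds3$true_labels)), c(2L, 3L, 4L))

  ds3b <- simulate_expression(net, 9, c(2, 3, 4), seed = 2)
  expect_identical(ds3$expression$values, ds3b$expression$values)
})

test_that("network-only weights rank hub regulators above isolated genes", {
  empty <- gene_network(paste0("g", 1:3))
  expect_equal(unname(network_only_weights(empty)$w), rep(1, 3))

  # star: g1 regulates g2..g5; g6 isolated
  star <- gene_network(paste0("g", 1:6),
                       cbind(rep("g1", 4), paste0("g", 2:5)))
  gw <- network_only_weights(star, alpha = 0.85)
  expect_gt(gw$w_raw[["g1"]], gw$w_raw[["g6"]])
  expect_equal(max(gw$w), 1)
  # oracle: dense closed-form solve on the star graph
  expect_equal(unname(gw$w_raw), weights_oracle(star, rep(1, 6), 0.85),
               tolerance = 1e-10)
})

test_that("noise injection permutes exactly the lowest-weight rows", {
  net <- generate_network(30, 90, seed = 4)
  base <- simulate_expression(net, 12, c(6, 6), seed = 4)

  expect_identical(inject_noisy_genes(base, 0), base)

  all_p <- suppressMessages(inject_noisy_genes(base, 30, seed = 5))
  expect_identical(length(all_p$noisy_gene_ids), 30L)
  for (g in seq_len(30))
    expect_equal(sort(unname(all_p$expression$values[g, ])),
                 sort(unname(base$expression$values[g, ])))

  one <- suppressMessages(inject_noisy_genes(base, 1, seed = 6))
  lowest <- net$gene_ids[order(network_only_weights(net)$w)[1]]
  expect_identical(one$noisy_gene_ids, lowest)
  changed <- which(rowSums(one$expression$values != base$expression$values) > 0)
  expect_true(all(net$gene_ids[changed] == lowest))

  two_a <- suppressMessages(inject_noisy_genes(base, 5, seed = 7))
  two_b <- suppressMessages(inject_noisy_genes(base, 5, seed = 7))
  expect_identical(two_a$expression$values, two_b$expression$values)
})

test_that("permuted genes lose their subtype signal", {
  ds <- simulate_dataset(n_genes = 400, n_edges = 800,
                         subtype_sizes = c(20, 20, 20), l = 200, seed = 8)
  p <- anova_per_gene(ds$expression, ds$true_labels)
  pn <- p[ds$noisy_gene_ids]
  expect_gte(length(pn), 200)
  ks <- suppressWarnings(stats::ks.test(pn, "punif"))
  expect_gt(ks$p.value, 0.01)
  # informative genes, by contrast, are mostly significant (per-gene effects
  # are drawn from a normal, so a minority are legitimately weak)
  clean <- setdiff(names(p), ds$noisy_gene_ids)
  expect_gt(mean(p[clean] < 0.01), 0.7)
})
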