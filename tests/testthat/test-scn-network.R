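test_that("partial correlations equal residual correlations from lm", {
  set.seed(101)
  n <- 60
  covs <- cbind(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5))
  vols <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, paste0("r", 1:5)))
  vols[, 2] <- vols[, 1] * 0.7 + rnorm(n, sd = 0.5) + 0.05 * covs[, "age"]
  r <- partial_correlation_matrix(vols, covs)
  res <- apply(vols, 2, function(v) residuals(lm(v ~ covs)))
  expect_equal(unname(r), unname(cor(res)), tolerance = 1e-10)
  expect_equal(unname(diag(r)), rep(1, 5))
  # no covariates reduces to the plain correlation matrix
  expect_equal(partial_correlation_matrix(vols, NULL), cor(vols),
               tolerance = 1e-12)
  expect_error(partial_correlation_matrix(vols[1:4, ], covs[1:4, ]),
               "degrees of freedom")
  vols[, 3] <- 5
  expect_error(partial_correlation_matrix(vols, covs), "constant")
})

test_that("Fisher z is atanh with clipping and rejects |r| > 1", {
  r <- c(-0.9, -0.3, 0, 0.5, 0.99)
  expect_equal(fisher_z(r), atanh(r))
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-15))
  expect_error(fisher_z(1.01), "exceeds 1")
})

test_that("proportional threshold keeps exactly k signed-strongest edges", {
  set.seed(7)
  for (N in c(10, 25)) {
    for (p in c(0.1, 0.35, 0.8)) {
      Z <- matrix(rnorm(N * N), N, N)
      Z <- (Z + t(Z)) / 2
      diag(Z) <- 0
      dimnames(Z) <- list(paste0("r", 1:N), paste0("r", 1:N))
      net <- threshold_proportional(Z, p)
      k <- round(p * N * (N - 1) / 2)
      kept <- net$W[upper.tri(net$W)]
      if (!net$augmented) {
        expect_equal(net$n_edges, k)
        expect_equal(mean(rowSums(net$W != 0)), 2 * k / N)
        # every kept edge is at least as strong as every dropped edge
        dropped <- Z[upper.tri(Z)][kept == 0]
        expect_gte(min(kept[kept != 0]), max(dropped))
      } else {
        expect_gte(net$n_edges, k)
      }
      expect_equal(net$W, t(net$W))
      expect_equal(max(morphocov:::.components(net$W != 0)), 1)
    }
  }
  # absolute ranking keeps the strongest magnitudes regardless of sign
  Z <- matrix(0, 4, 4)
  Z[upper.tri(Z)] <- c(-3, 2, 0.5, 1, -0.2, 0.1)
  Z <- Z + t(Z)
  net_abs <- threshold_proportional(Z, 0.5, rank_by = "absolute")
  expect_setequal(net_abs$W[upper.tri(net_abs$W)][
    net_abs$W[upper.tri(net_abs$W)] != 0], c(-3, 2, 1))
  expect_error(threshold_proportional(Z, 0), "proportion")
  expect_error(threshold_proportional(matrix(rnorm(16), 4, 4), 0.5),
               "symmetric")
})

test_that("disconnected thresholding errors or augments to connectivity", {
  # two dense cliques joined by one weak edge; low p disconnects them
  Z <- matrix(0.1, 8, 8)
  Z[1:4, 1:4] <- 0.9
  Z[5:8, 5:8] <- 0.9
  Z[1, 5] <- Z[5, 1] <- 0.2
  diag(Z) <- 0
  expect_error(threshold_proportional(Z, 0.35, disconnected = "error"),
               "disconnected")
  net <- threshold_proportional(Z, 0.35, disconnected = "augment")
  expect_true(net$augmented)
  expect_gte(net$augment_edges, 1)
  expect_equal(max(morphocov:::.components(net$W != 0)), 1)
  # the augmenting bridge is the strongest available cross edge
  expect_equal(net$W[1, 5], 0.2)
})

test_that("binary graph metrics agree with igraph on connected graphs", {
  # exhaustive over all labelled connected graphs on up to 5 nodes
  for (N in 2:5) {
    graphs <- Filter(is_connected_graph, all_graphs(N))
    for (A in graphs) {
      got <- graph_metrics(A, mode = "binary")
      want <- oracle_binary_metrics(A)
      expect_equal(got$path_length, want$path_length)
      expect_equal(got$global_efficiency, want$global_efficiency)
      expect_equal(unname(got$clustering), want$clustering)
      expect_equal(unname(got$degree), unname(want$degree))
      expect_equal(unname(got$efficiency), want$efficiency)
      expect_equal(got$small_worldness,
                   want$global_clustering / want$path_length)
    }
  }
})

test_that("weighted graph metrics agree with Dijkstra and Onnela oracles", {
  set.seed(11)
  for (rep in 1:25) {
    W <- random_connected_graph(sample(4:9, 1), p_edge = 0.5,
                                weighted = TRUE)
    got <- graph_metrics(W, mode = "weighted")
    want <- oracle_weighted_metrics(W)
    expect_equal(got$path_length, want$path_length, tolerance = 1e-10)
    expect_equal(got$global_efficiency, want$global_efficiency,
                 tolerance = 1e-10)
    expect_equal(unname(got$clustering), want$clustering,
                 tolerance = 1e-10)
    expect_equal(got$global_clustering, want$global_clustering,
                 tolerance = 1e-10)
  }
  A <- diag(0, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  expect_error(graph_metrics(A), "disconnected")
  W <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(graph_metrics(W, mode = "weighted"), "non-negative")
})

test_that("group comparisons match exact Wilcoxon enumeration and BH", {
  set.seed(5)
  x <- rnorm(7)
  y <- rnorm(6) + 1.2
  z <- rnorm(8) - 0.5
  metrics <- list(g1 = list(m1 = x, m2 = x + 0.1),
                  g2 = list(m1 = y, m2 = y * 2),
                  g3 = list(m1 = z, m2 = z - 1))
  out <- compare_groups(metrics)
  expect_equal(nrow(out), 6)  # 3 pairs x 2 metrics
  for (i in seq_len(nrow(out))) {
    a <- metrics[[out$group1[i]]][[out$metric[i]]]
    b <- metrics[[out$group2[i]]][[out$metric[i]]]
    expect_equal(out$p[i], wilcox_exact_p(a, b))
  }
  m1 <- out[out$metric == "m1", ]
  expect_equal(m1$p_fdr, bh_manual(m1$p))
  expect_warning(
    compare_groups(list(a = list(m = rep(1, 3)), b = list(m = rep(1, 3)))),
    "tied")
})
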