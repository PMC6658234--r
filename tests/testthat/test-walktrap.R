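test_that("a single edge collapses to one community", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- graph_from_matrix(m)
  d <- walktrap_dendrogram(g)
  expect_equal(nrow(d$merges), 1)
  p <- best_partition(d, g)
  expect_equal(p$n_communities, 1)
  expect_equal(unname(p$membership), c(1, 1))
})

test_that("weak-bridge barbell cut recovers the two cliques", {
  g <- barbell_graph(4, bridge_weight = 0.1)
  p <- walktrap_communities(g)
  expect_equal(p$n_communities, 2)
  expect_equal(unname(p$membership)[1:4], rep(p$membership[[1]], 4))
  expect_equal(unname(p$membership)[5:8], rep(p$membership[[8]], 4))
  # the chosen cut attains the exhaustive maximum over all 4140 partitions
  oracle <- oracle_best_partition(g)
  expect_equal(p$modularity, oracle$modularity)
})

test_that("planted two-block graphs are recovered and match the reference", {
  skip_if_not_installed("igraph")
  set.seed(20)
  pb <- planted_block_graph(20, p_in = 1, p_out = 1,
                            w_in = c(1, 1), w_out = c(0.05, 0.05))
  p <- walktrap_communities(pb$graph)
  expect_equal(p$n_communities, 2)
  expect_equal(adjusted_rand_index(p$membership, pb$block), 1)
  ref <- igraph::cluster_walktrap(pb$graph,
                                  weights = igraph::E(pb$graph)$weight,
                                  steps = 4)
  expect_equal(adjusted_rand_index(p$membership,
                                   as.vector(igraph::membership(ref))), 1)
})

test_that("modularity matches the analytic identities and the brute-force sum", {
  g <- barbell_graph(4)
  expect_equal(graph_modularity(g, rep(1, 8)), 0)

  # two disjoint equal cliques, each its own community
  m <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
  m[1:4, 1:4] <- 1
  m[5:8, 5:8] <- 1
  diag(m) <- 0
  g2 <- graph_from_matrix(m)
  expect_equal(graph_modularity(g2, rep(1:2, each = 4)), 0.5)

  set.seed(13)
  for (i in 1:20) {
    g3 <- random_weighted_graph(8)
    mem <- sample(1:3, 8, replace = TRUE)
    expect_equal(graph_modularity(g3, mem), oracle_modularity(g3, mem))
  }

  expect_error(graph_modularity(g, c(1, 1)), "every vertex")
  mem_named <- stats::setNames(rep(1, 7), paste0("n", 1:7))
  expect_error(graph_modularity(g, mem_named), "missing")
})

test_that("a complete uniform graph is never split", {
  m <- matrix(1, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(m) <- 0
  p <- walktrap_communities(graph_from_matrix(m))
  expect_equal(p$n_communities, 1)
  expect_equal(p$modularity, 0)
})

test_that("best_partition never exceeds and usually attains the exhaustive optimum", {
  set.seed(31)
  # unstructured graphs: the dendrogram restricts the cut space, so the
  # chosen cut may fall short of the exhaustive optimum but never beats it
  for (i in 1:8) {
    g <- random_weighted_graph(7)
    p <- walktrap_communities(g)
    oracle <- oracle_best_partition(g)
    expect_lte(p$modularity, oracle$modularity + 1e-12)
  }
  # strongly modular fixtures: the optimum is attained
  for (i in 1:5) {
    pb <- planted_block_graph(8, p_in = 1, p_out = 0.3,
                              w_in = c(0.8, 1), w_out = c(0.05, 0.15))
    p <- walktrap_communities(pb$graph)
    oracle <- oracle_best_partition(pb$graph)
    expect_equal(p$modularity, oracle$modularity)
  }
})

test_that("dendrogram and partition are deterministic and permutation-equivariant", {
  set.seed(55)
  g <- random_weighted_graph(12)
  d1 <- walktrap_dendrogram(g)
  d2 <- walktrap_dendrogram(g)
  expect_identical(d1, d2)
  p1 <- best_partition(d1, g)

  perm <- sample(igraph::vcount(g))
  gp <- igraph::permute(g, perm)
  p2 <- walktrap_communities(gp)
  # same grouping of the same vertex names
  m1 <- p1$membership[sort(names(p1$membership))]
  m2 <- p2$membership[sort(names(p2$membership))]
  expect_equal(adjusted_rand_index(m1, m2), 1)
})

test_that("disconnected graphs are handled per component", {
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1 # e is isolated
  g <- graph_from_matrix(m)
  d <- walktrap_dendrogram(g)
  expect_equal(d$n_components, 3)
  expect_equal(nrow(d$merges), 2)
  p <- best_partition(d, g)
  expect_equal(p$n_communities, 3)
  expect_equal(unname(p$membership[c("a", "b")]),
               rep(p$membership[["a"]], 2))
})

test_that("non-positive weights are rejected", {
  m <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  expect_error(walktrap_dendrogram(g), "positive")
})

test_that("agreement with the independent reference implementation", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    set.seed(seed)
    pb <- planted_block_graph(sample(8:20, 1))
    g <- pb$graph
    mine <- walktrap_communities(g, 4)
    ref <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                    steps = 4)
    ref_mem <- as.vector(igraph::membership(ref))
    q_ref <- igraph::modularity(g, ref_mem, weights = igraph::E(g)$weight)
    identical_partition <-
      adjusted_rand_index(mine$membership, ref_mem) == 1
    expect_true(identical_partition ||
                  abs(mine$modularity - q_ref) < 1e-9,
                label = sprintf("seed %d: same partition or equal modularity",
                                seed))
  }
})

test_that("modularity curve covers every cut and the adjusted Rand index is sane", {
  g <- barbell_graph(3)
  d <- walktrap_dendrogram(g)
  curve <- modularity_curve(d, g)
  expect_equal(nrow(curve), nrow(d$merges) + 1)
  expect_equal(curve$n_communities[1], igraph::vcount(g))
  expect_equal(curve$n_communities[nrow(curve)], 1)
  expect_equal(curve$modularity[nrow(curve)], 0)

  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  expect_lt(abs(adjusted_rand_index(c(1, 2, 1, 2), c(1, 1, 2, 2))), 1)
  skip_if_not_installed("mclust")
  set.seed(61)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
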