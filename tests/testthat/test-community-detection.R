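test_that("modularity closed forms hold", {
  nodes <- paste0("n", 1:6)
  tri2 <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  g <- graph_from_edges(nodes, edges_df(nodes, tri2))
  one <- setNames(rep(1, 6), nodes)
  # whole graph in one community: Q = 1 - gamma
  expect_equal(modularity_score(g, one, resolution = 0.75), 0.25)
  # all singletons: Q = -gamma * sum (d_i / 2m)^2
  singl <- setNames(1:6, nodes)
  expect_equal(modularity_score(g, singl, resolution = 0.75),
               -0.75 * sum((rep(2, 6) / 12)^2))
  # two triangles as communities at gamma 1: direct formula evaluation
  two <- setNames(rep(1:2, each = 3), nodes)
  expect_equal(modularity_score(g, two, resolution = 1),
               6 / 6 - 1 * 2 * (6 / 12)^2)
  expect_error(modularity_score(g, setNames(rep(1, 5), nodes[1:5])), "missing")
})

test_that("modularity is invariant under community relabeling", {
  g <- random_graph(9, 0.4, seed = 31)
  set.seed(32)
  memb <- setNames(sample(1:3, 9, replace = TRUE), g$nodes)
  relab <- setNames(c(7, 5, 9)[memb], g$nodes)
  expect_equal(modularity_score(g, memb, 0.75),
               modularity_score(g, relab, 0.75))
})

test_that("modularity agrees with the igraph reference at gamma 1", {
  skip_if_not_installed("igraph")
  for (sd in 1:5) {
    g <- random_graph(8, 0.4, seed = 40 + sd)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = g$nodes)
    set.seed(sd)
    memb <- setNames(sample(1:3, 8, replace = TRUE), g$nodes)
    expect_equal(modularity_score(g, memb, resolution = 1),
                 igraph::modularity(ig, memb[igraph::V(ig)$name]),
                 tolerance = 1e-12)
  }
})

test_that("louvain resolves two disconnected cliques exactly", {
  nodes <- paste0("n", 1:10)
  ed <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)))
  g <- graph_from_edges(nodes, edges_df(nodes, ed))
  p <- louvain(g, resolution = 0.75, seed = 1)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(length(unique(p$membership[1:5])), 1)
  expect_equal(length(unique(p$membership[6:10])), 1)
  expect_setequal(unique(p$membership), c(0L, 1L))
})

test_that("a large resolution splits two bridged triangles", {
  nodes <- paste0("n", 1:6)
  ed <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  g <- graph_from_edges(nodes, edges_df(nodes, ed))
  # candidate partitions compared by direct formula: merged beats split only
  # below the crossover resolution
  split <- setNames(rep(1:2, each = 3), nodes)
  merged <- setNames(rep(1, 6), nodes)
  gam_lo <- 0.5 ; gam_hi <- 3
  expect_gt(modularity_score(g, merged, gam_lo),
            modularity_score(g, split, gam_lo) - 1)  # both defined
  p_hi <- louvain(g, resolution = gam_hi, seed = 2)
  expect_gt(length(unique(p_hi$membership)), 1)
  expect_gte(p_hi$modularity, modularity_score(g, split, gam_hi) - 1e-12)
})

test_that("louvain never falls below the trivial baselines", {
  for (sd in 1:10) {
    g <- random_graph(12, 0.3, seed = 50 + sd)
    p <- louvain(g, resolution = 0.75, seed = sd)
    n <- length(g$nodes)
    q_one <- modularity_score(g, setNames(rep(1, n), g$nodes), 0.75)
    q_sing <- modularity_score(g, setNames(seq_len(n), g$nodes), 0.75)
    expect_gte(p$modularity, max(q_one, q_sing) - 1e-12)
    expect_identical(p$modularity,
                     modularity_score(g, p$membership, 0.75))
    expect_setequal(unique(p$membership),
                    seq_len(length(unique(p$membership))) - 1L)
  }
})

test_that("louvain is deterministic under a seed", {
  g <- random_graph(15, 0.3, seed = 77)
  p1 <- louvain(g, resolution = 0.75, seed = 5)
  p2 <- louvain(g, resolution = 0.75, seed = 5)
  expect_identical(p1$membership, p2$membership)
})

test_that("exhaustive oracle maximizes over all partitions of small graphs", {
  # P3 path: full enumeration of all 5 partitions by hand
  nodes <- c("a", "b", "c")
  g <- graph_from_edges(nodes, data.frame(gene_a = c("a", "b"),
                                          gene_b = c("b", "c")))
  parts <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2), c(1, 2, 3))
  qs <- vapply(parts, function(pp)
    modularity_score(g, setNames(pp, nodes), 0.75), numeric(1))
  ex <- exhaustive_best_partition(g, resolution = 0.75)
  expect_equal(ex$modularity, max(qs))
  # K4 at gamma 0.75: enumeration confirms a single community
  n4 <- paste0("n", 1:4)
  k4 <- graph_from_edges(n4, edges_df(n4, t(combn(4, 2))))
  ex4 <- exhaustive_best_partition(k4, resolution = 0.75)
  expect_equal(length(unique(ex4$membership)), 1)
  # guards
  empty <- graph_from_edges("x", data.frame(gene_a = character(0),
                                            gene_b = character(0)))
  expect_error(exhaustive_best_partition(empty), "no edges")
  big <- random_graph(11, 0.5, seed = 1)
  expect_error(exhaustive_best_partition(big), "10 nodes")
})

test_that("louvain matches the exhaustive optimum on random 8-node graphs", {
  hits <- vapply(1:20, function(sd) {
    g <- random_graph(8, 0.35, seed = 600 + sd)
    p <- louvain(g, resolution = 0.75, seed = sd)
    ex <- exhaustive_best_partition(g, resolution = 0.75)
    expect_lte(p$modularity, ex$modularity + 1e-12)
    abs(p$modularity - ex$modularity) < 1e-9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("planted two-block graphs are recovered perfectly", {
  set.seed(123)
  n <- 60
  nodes <- paste0("n", 1:(2 * n))
  pairs <- t(combn(2 * n, 2))
  same <- (pairs[, 1] <= n) == (pairs[, 2] <= n)
  keep <- runif(nrow(pairs)) < ifelse(same, 0.5, 0.02)
  g <- graph_from_edges(nodes, edges_df(nodes, pairs[keep, , drop = FALSE]))
  p <- louvain(g, resolution = 0.75, seed = 3)
  truth <- setNames(rep(1:2, each = n), nodes)
  expect_equal(adjusted_rand_index(p$membership, truth), 1)
})
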