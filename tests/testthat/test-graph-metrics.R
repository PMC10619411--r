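test_that("node strength sums adjacent edge weights", {
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  s <- node_strength(w)
  expect_equal(as.numeric(s), rep(1, 3))
  expect_equal(attr(s, "global"), 1)

  w2 <- matrix(0, 4, 4); w2[1, 2] <- w2[2, 1] <- 0.3  # nodes 3, 4 isolated
  expect_equal(as.numeric(node_strength(w2)), c(0.3, 0.3, 0, 0))

  set.seed(21)
  w8 <- random_graph(8)
  expect_equal(as.numeric(node_strength(w8)),
               sapply(1:8, function(i) sum(w8[i, ])))
})

test_that("shortest paths use reciprocal-weight lengths (worked 3-node example)", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5   # length 2
  w[2, 3] <- w[3, 2] <- 0.5   # length 2
  w[1, 3] <- w[3, 1] <- 0.2   # length 5, beaten by the 2 + 2 detour
  d <- shortest_paths(w)
  expect_equal(d[1, 3], 4)
  expect_equal(d[1, 2], 2)
  expect_equal(characteristic_path_length(d)$cpl, 8 / 3)
  expect_equal(global_efficiency(d), 5 / 12)

  w2 <- matrix(c(0, 0.25, 0.25, 0), 2, 2)  # two nodes: D = 1/w
  expect_equal(shortest_paths(w2)[1, 2], 4)
})

test_that("disconnected components are excluded from the mean and flagged", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  d <- shortest_paths(w)
  expect_true(is.infinite(d[1, 3]))
  pl <- characteristic_path_length(d)
  expect_false(pl$connected)
  expect_equal(pl$cpl, mean(c(1, 1, 2, 2)))
  expect_equal(global_efficiency(d), mean(c(1, 1, 0.5, 0.5, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_error(characteristic_path_length(matrix(c(0, Inf, Inf, 0), 2, 2)),
               "unreachable")
})

test_that("complete uniform and path graphs hit their analytic metric values", {
  w1 <- matrix(1, 5, 5); diag(w1) <- 0
  d <- shortest_paths(w1)
  expect_equal(characteristic_path_length(d)$cpl, 1)
  expect_equal(global_efficiency(d), 1)
  cl <- weighted_clustering(w1)
  expect_equal(cl$transitivity, 1)
  expect_equal(unname(cl$clustering), rep(1, 5))

  # 3-node complete uniform: per-node triangle intensity 1, clustering 1
  w3 <- matrix(0.4, 3, 3); diag(w3) <- 0
  cl3 <- weighted_clustering(w3)
  expect_equal(unname(cl3$triangle_intensity), rep(1, 3))
  expect_equal(cl3$transitivity, 1)

  # path graph has no triangles
  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- 0.8; wp[2, 3] <- wp[3, 2] <- 0.6
  clp <- weighted_clustering(wp)
  expect_equal(unname(clp$triangle_intensity), rep(0, 3))
  expect_equal(clp$transitivity, 0)

  expect_error(weighted_clustering(matrix(0, 3, 3)), "undefined")
})

test_that("Dijkstra and clustering agree with independent oracles on random graphs", {
  set.seed(77)
  for (rep in 1:40) {
    r <- sample(4:12, 1)
    w <- random_graph(r, density = runif(1, 0.3, 0.9))
    if (max(w) == 0) next
    expect_equal(shortest_paths(w), fw_distances(w), tolerance = 1e-12)
    if (requireNamespace("igraph", quietly = TRUE)) {
      g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
      dig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
      expect_equal(unname(shortest_paths(w)), unname(dig), tolerance = 1e-10)
    }
    cl <- weighted_clustering(w)
    bf <- clustering_bruteforce(w)
    expect_equal(unname(cl$triangle_intensity), bf$t_i, tolerance = 1e-10)
    expect_equal(unname(cl$clustering), bf$c_i, tolerance = 1e-10)
    expect_equal(cl$transitivity, bf$transitivity, tolerance = 1e-10)
  }
})

test_that("metrics respect permutation equivariance and weight scaling", {
  set.seed(5)
  w <- random_graph(9, 0.7)
  perm <- sample(9)
  wp <- w[perm, perm]
  expect_equal(weighted_clustering(wp)$transitivity, weighted_clustering(w)$transitivity)
  expect_equal(as.numeric(node_strength(wp)), as.numeric(node_strength(w))[perm])
  expect_equal(unname(weighted_clustering(wp)$clustering),
               unname(weighted_clustering(w)$clustering)[perm])
  dp <- shortest_paths(wp); d <- shortest_paths(w)
  expect_equal(unname(dp), unname(d[perm, perm]))

  cc <- 0.37  # scaling: T, C_i invariant; D divides; E and strength multiply
  expect_equal(weighted_clustering(cc * w)$transitivity, weighted_clustering(w)$transitivity)
  expect_equal(unname(weighted_clustering(cc * w)$clustering),
               unname(weighted_clustering(w)$clustering))
  expect_equal(shortest_paths(cc * w), d / cc)
  expect_equal(global_efficiency(shortest_paths(cc * w)), cc * global_efficiency(d))
  expect_equal(as.numeric(node_strength(cc * w)), cc * as.numeric(node_strength(w)))
})

test_that("clustering and transitivity stay within [0, 1] on fuzzed matrices", {
  set.seed(123)
  for (rep in 1:60) {
    r <- sample(3:15, 1)
    w <- random_graph(r, runif(1, 0.1, 1))
    if (max(w) == 0) next
    cl <- weighted_clustering(w)
    expect_true(all(cl$clustering >= 0 & cl$clustering <= 1))
    if (any(cl$degree >= 2)) {
      expect_true(cl$transitivity >= 0 && cl$transitivity <= 1)
    } else {
      expect_true(is.na(cl$transitivity))  # no connected triples
    }
    expect_true(all(cl$degree >= 0 & cl$degree <= r - 1))
  }
})

test_that("connectome_metrics and node_metrics assemble coherent tables", {
  set.seed(8)
  cm <- connectivity_matrix(random_graph(6, 0.9), id = "S1")
  g <- connectome_metrics(cm)
  expect_equal(g$id, "S1")
  expect_equal(g$strength, mean(rowSums(unclass(cm))))
  expect_true(g$connected)
  nm <- node_metrics(cm)
  expect_equal(nrow(nm), 6)
  expect_equal(nm$degree, as.integer(rowSums(unclass(cm) > 0)))
  g2 <- connectome_metrics(cm, include_paths = FALSE)
  expect_true(is.na(g2$cpl) && is.na(g2$efficiency))
  expect_equal(g2$transitivity, g$transitivity)
})
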