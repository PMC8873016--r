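test_that("density grid construction and validation", {
  g <- density_grid()
  expect_length(g, 25)
  expect_equal(g[1], 0.10)
  expect_equal(g[25], 0.34)
  expect_lt(abs(g[length(g)] - 0.34), 1e-12)
  expect_error(density_grid(0.3, 0.1), "kappa_min < kappa_max")
  expect_error(density_grid(0.1, 0.34, 0.07), "tile")
  expect_error(density_grid(0, 0.3))
})

test_that("proportional thresholding keeps exactly the K largest edges", {
  set.seed(21)
  # 4 nodes, kappa = 0.5: exactly 3 edges, the 3 largest
  z <- matrix(0, 4, 4)
  vals <- c(0.9, 0.1, 0.5, 0.7, 0.3, 0.2)
  z[upper.tri(z)] <- vals
  z <- z + t(z)
  g <- proportional_threshold(z, 0.5, normalize = FALSE)
  expect_equal(g$n_edges, 3)
  expect_equal(sort(g$w[upper.tri(g$w)][g$w[upper.tri(g$w)] > 0]),
               sort(vals)[4:6])
  # sorting oracle on a 20-node matrix
  z2 <- matrix(rnorm(400), 20, 20)
  z2 <- (z2 + t(z2)) / 2
  diag(z2) <- 0
  K <- round(0.2 * 20 * 19 / 2)
  g2 <- proportional_threshold(z2, 0.2, normalize = FALSE)
  ut <- z2[upper.tri(z2)]
  cutoff <- sort(ut[ut > 0], decreasing = TRUE)[K]
  expect_equal(sort(g2$w[upper.tri(g2$w)][g2$w[upper.tri(g2$w)] > 0]),
               sort(ut[ut >= cutoff]))
  expect_equal(g2$n_edges, K)
  # negative edges removed before thresholding
  expect_true(all(g2$w >= 0))
})

test_that("thresholding ties break lexicographically and saturation warns", {
  z <- matrix(1, 4, 4)
  diag(z) <- 0
  g <- proportional_threshold(z, 0.5, normalize = FALSE)
  expect_equal(g$n_edges, 3)
  expect_equal(g$w[1, 2:4], c(1, 1, 1))   # (1,2),(1,3),(1,4) by tie rule
  expect_equal(g$w[2, 3], 0)
  # fewer positive edges than K: keep all, warn, flag
  z2 <- matrix(0, 4, 4)
  z2[1, 2] <- z2[2, 1] <- 0.5
  expect_warning(g2 <- proportional_threshold(z2, 0.5), "keeping all")
  expect_true(g2$saturated)
  expect_equal(g2$n_edges, 1)
  expect_error(proportional_threshold(matrix(0, 3, 3), 0.05), "zero edges")
})

test_that("threshold exactness holds across the default grid", {
  set.seed(22)
  grid <- density_grid()
  for (rep in 1:40) {
    z <- matrix(rnorm(15 * 15, mean = 0.3), 15, 15)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    for (kappa in grid) {
      g <- proportional_threshold(z, kappa)
      expect_equal(g$n_edges, round(kappa * 15 * 14 / 2))
      expect_equal(sum(g$w[upper.tri(g$w)] > 0), g$n_edges)
    }
  }
})

test_that("weight-to-length map: reciprocal, infinite absence, monotone", {
  w <- matrix(c(0, 0.5, 0, 0.5, 0, 2, 0, 2, 0), 3, 3)
  L <- to_length_matrix(w)
  expect_equal(L[1, 2], 2)
  expect_equal(L[2, 3], 0.5)
  expect_equal(L[1, 3], Inf)
  expect_equal(diag(L), rep(0, 3))
  set.seed(23)
  w1 <- runif(50, 0.1, 1)
  w2 <- w1 + runif(50, 0.01, 0.5)
  expect_true(all(1 / w2 < 1 / w1))
})

test_that("shortest paths match Floyd-Warshall on random graphs", {
  # 3-node path: d(a, c) = 2; disconnected pair infinite
  L <- to_length_matrix(path_graph(3))
  D <- shortest_path_matrix(L)
  expect_equal(D[1, 3], 2)
  w <- path_graph(4)
  w[3, 4] <- w[4, 3] <- 0
  D2 <- shortest_path_matrix(to_length_matrix(w))
  expect_equal(D2[1, 4], Inf)
  set.seed(24)
  for (rep in 1:50) {
    wr <- rand_weighted_graph(10, p_edge = 0.4)
    if (all(wr == 0)) next
    Lr <- to_length_matrix(wr)
    expect_equal(shortest_path_matrix(Lr), oracle_fw(Lr), tolerance = 1e-10)
  }
})

test_that("closed forms: complete graph, star, path", {
  K5 <- complete_graph(5)
  expect_equal(global_efficiency(K5), 1)
  expect_equal(local_efficiency(K5), 1)
  expect_equal(clustering_coefficient(K5), 1)
  expect_equal(as.numeric(characteristic_path_length(K5)), 1)
  expect_equal(betweenness(K5), rep(0, 5))
  expect_equal(nodal_degree(K5), rep(4L, 5))

  S4 <- star_graph(4)
  expect_equal(clustering_coefficient(S4), 0)
  expect_equal(local_efficiency(S4), 0)
  en <- nodal_efficiency(S4)
  expect_equal(en[1], 1)                      # centre
  expect_equal(en[2], 2 / 3, tolerance = 1e-12)  # leaf: (1 + 1/2 + 1/2)/3

  P3 <- path_graph(3)
  expect_equal(as.numeric(characteristic_path_length(P3)), 4 / 3,
               tolerance = 1e-12)              # ordered pairs {1,1,2,1,1,2}
  expect_equal(betweenness(P3)[2], 1)          # middle node transits all
  expect_equal(betweenness(P3)[1], 0)

  # fully disconnected graph
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(nodal_degree(matrix(0, 4, 4)), rep(0L, 4))
})

test_that("every metric matches its brute-force oracle on random graphs", {
  set.seed(25)
  for (rep in 1:60) {
    n <- sample(5:12, 1)
    w <- rand_weighted_graph(n, p_edge = runif(1, 0.3, 0.9))
    if (sum(w > 0) < 4) next
    expect_equal(global_efficiency(w), oracle_global_eff(w),
                 tolerance = 1e-8)
    expect_equal(nodal_efficiency(w), oracle_nodal_eff(w), tolerance = 1e-8)
    expect_equal(local_efficiency(w), oracle_local_eff(w), tolerance = 1e-8)
    expect_equal(clustering_coefficient(w), oracle_clustering(w),
                 tolerance = 1e-8)
    if (any(is.finite(oracle_fw(oracle_lengths(w))[upper.tri(w)])))
      expect_equal(as.numeric(characteristic_path_length(w)), oracle_lp(w),
                   tolerance = 1e-8)
    expect_equal(betweenness(w), oracle_betweenness(w), tolerance = 1e-8)
    expect_equal(nodal_degree(w), as.integer(rowSums(w > 0)))
  }
})

test_that("distances and betweenness agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(26)
  for (rep in 1:20) {
    w <- rand_weighted_graph(9, p_edge = 0.6)
    if (sum(w > 0) < 6) next
    gi <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
    lens <- 1 / igraph::E(gi)$weight
    Di <- igraph::distances(gi, weights = lens)
    expect_equal(unname(shortest_path_matrix(to_length_matrix(w))),
                 unname(Di), tolerance = 1e-10)
    bi <- igraph::betweenness(gi, weights = lens)
    expect_equal(betweenness(w), 2 * unname(bi) / ((9 - 1) * (9 - 2)),
                 tolerance = 1e-8)
  }
})

test_that("relabelling nodes permutes nodal metrics and fixes global ones", {
  set.seed(27)
  w <- rand_weighted_graph(10, p_edge = 0.5)
  perm <- sample(10)
  wp <- w[perm, perm]
  expect_equal(global_efficiency(wp), global_efficiency(w), tolerance = 1e-12)
  expect_equal(clustering_coefficient(wp), clustering_coefficient(w),
               tolerance = 1e-12)
  expect_equal(nodal_efficiency(wp), nodal_efficiency(w)[perm],
               tolerance = 1e-12)
  expect_equal(betweenness(wp), betweenness(w)[perm], tolerance = 1e-12)
  expect_equal(nodal_degree(wp), nodal_degree(w)[perm])
})

test_that("degrees satisfy the handshake identity", {
  set.seed(28)
  w <- rand_weighted_graph(12, 0.5)
  expect_equal(sum(nodal_degree(w)), 2 * sum(w[upper.tri(w)] > 0))
})

test_that("global efficiency is non-decreasing in density; L_p monotone", {
  set.seed(29)
  z <- matrix(rnorm(30 * 30, 0.2), 30, 30)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  grid <- density_grid(0.10, 0.34, 0.04)
  mc <- metric_curves(z, grid, metrics = c("e_glob", "l_p"))
  eg <- mc$global[, "e_glob"]
  expect_true(all(diff(eg) >= -1e-12))
  # adding an edge never increases L_p on fixed weights
  w <- rand_weighted_graph(8, 0.5)
  absent <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
  if (nrow(absent)) {
    i <- absent[1, 1]; j <- absent[1, 2]
    w2 <- w
    w2[i, j] <- w2[j, i] <- 0.8
    if (is.finite(oracle_lp(w)))
      expect_lte(as.numeric(characteristic_path_length(w2)),
                 as.numeric(characteristic_path_length(w)) + 1e-12)
  }
})

test_that("mean nodal efficiency equals global efficiency", {
  set.seed(30)
  for (rep in 1:10) {
    w <- rand_weighted_graph(9, 0.6)
    if (all(w == 0)) next
    expect_equal(mean(nodal_efficiency(w)), global_efficiency(w),
                 tolerance = 1e-12)
  }
})

test_that("metric curves have the grid's shape and log disconnection", {
  set.seed(31)
  z <- matrix(rnorm(400, 0.2), 20, 20)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  mc <- metric_curves(z, density_grid())
  expect_equal(dim(mc$global), c(25, 4))
  expect_equal(dim(mc$nodal$degree), c(20, 25))
  expect_length(mc$n_disconnected, 25)
  # single-density curves equal single-threshold metrics
  mc1 <- metric_curves(z, 0.2, metrics = c("e_glob", "c_p"))
  g <- proportional_threshold(z, 0.2)
  expect_equal(unname(mc1$global[1, "e_glob"]), global_efficiency(g))
  expect_equal(unname(mc1$global[1, "c_p"]), clustering_coefficient(g))
})

test_that("curve computation equals per-density thresholding exactly", {
  set.seed(34)
  z <- matrix(rnorm(625, 0.2), 25, 25)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  grid <- density_grid(0.10, 0.34, 0.03)
  mc <- metric_curves(z, grid)
  for (i in seq_along(grid)) {
    g <- proportional_threshold(z, as.numeric(grid)[i])
    expect_equal(unname(mc$global[i, "e_glob"]), global_efficiency(g))
    expect_equal(unname(mc$global[i, "e_loc"]), local_efficiency(g))
    expect_equal(unname(mc$global[i, "c_p"]), clustering_coefficient(g))
    expect_equal(unname(mc$global[i, "l_p"]),
                 as.numeric(characteristic_path_length(g)))
    expect_equal(mc$nodal$degree[, i], nodal_degree(g))
    expect_equal(mc$nodal$e_nodal[, i], nodal_efficiency(g))
    expect_equal(mc$nodal$betweenness[, i], betweenness(g))
  }
})

test_that("AUC: rectangle rule, hand trapezoid, linearity", {
  grid <- density_grid()
  const <- rep(3, 25)
  expect_equal(auc(const, grid), 0.24 * 3, tolerance = 1e-12)
  grid2 <- density_grid(0.1, 0.3, 0.1)
  expect_equal(auc(as.numeric(grid2), grid2), 0.04, tolerance = 1e-12)
  set.seed(32)
  a <- rnorm(25)
  b <- rnorm(25)
  expect_equal(auc(a + b, grid), auc(a, grid) + auc(b, grid),
               tolerance = 1e-12)
  expect_error(auc(1:10, grid), "length")
})

test_that("efficiencies stay in [0, 1] on normalized thresholded graphs", {
  set.seed(33)
  z <- matrix(rnorm(625, 0.2), 25, 25)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  for (kappa in c(0.1, 0.2, 0.34)) {
    g <- proportional_threshold(z, kappa, normalize = TRUE)
    expect_true(global_efficiency(g) >= 0 && global_efficiency(g) <= 1)
    expect_true(local_efficiency(g) >= 0 && local_efficiency(g) <= 1)
    expect_true(all(nodal_efficiency(g) >= 0 & nodal_efficiency(g) <= 1))
    expect_true(all(nodal_degree(g) <= 24))
  }
})
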