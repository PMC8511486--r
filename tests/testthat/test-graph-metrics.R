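k_complete <- function(n) make_bg(matrix(1, n, n) - diag(n))
star <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, -1] <- 1
  make_bg(A)
}
path_graph <- function(n) {
  A <- matrix(0, n, n)
  A[cbind(1:(n - 1), 2:n)] <- 1
  make_bg(A)
}

test_that("clustering coefficient matches hand-enumerated values", {
  expect_equal(clustering_coefficient(k_complete(3))$mean, 1)
  expect_equal(unname(clustering_coefficient(star(3))$per_node), rep(0, 4))
  A <- matrix(1, 4, 4) - diag(4)
  A[3, 4] <- A[4, 3] <- 0 # K4 minus one edge
  cc <- clustering_coefficient(make_bg(A))
  expect_equal(unname(cc$per_node), c(2 / 3, 2 / 3, 1, 1))
  expect_equal(cc$mean, 5 / 6)
})

test_that("path length follows the connected-pairs policy", {
  expect_equal(characteristic_path_length(k_complete(4)), 1)
  expect_equal(characteristic_path_length(path_graph(4)), 10 / 6)
  two_edges <- make_bg(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                             c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_equal(characteristic_path_length(two_edges), 1)
  expect_error(characteristic_path_length(two_edges, disconnected = "error"),
               "disconnected")
  empty <- make_bg(matrix(0, 3, 3))
  expect_error(characteristic_path_length(empty), "no connected")
})

test_that("global efficiency handles completeness and disconnection", {
  expect_equal(global_efficiency(k_complete(5)), 1)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  expect_equal(global_efficiency(make_bg(matrix(0, 4, 4))), 0)
  # Eglob = 1 iff complete
  almost <- matrix(1, 5, 5) - diag(5)
  almost[1, 2] <- almost[2, 1] <- 0
  expect_lt(global_efficiency(make_bg(almost)), 1)
})

test_that("local efficiency equals the neighbor-subgraph definition", {
  expect_equal(local_efficiency(k_complete(4))$mean, 1)
  expect_equal(local_efficiency(star(4))$mean, 0)
  A <- matrix(1, 4, 4) - diag(4)
  A[3, 4] <- A[4, 3] <- 0
  expect_equal(unname(local_efficiency(make_bg(A))$per_node),
               o_eloc(A)$per_node)
})

test_that("betweenness matches path enumeration and normalizes by the mean", {
  s <- betweenness_centrality(star(4))
  expect_equal(unname(s$betweenness_raw), c(6, 0, 0, 0, 0))
  expect_equal(unname(s$betweenness_norm), c(5, 0, 0, 0, 0))
  expect_false(s$zero_mean_flag)

  k5 <- betweenness_centrality(k_complete(5))
  expect_equal(unname(k5$betweenness_raw), rep(0, 5))
  expect_equal(unname(k5$betweenness_norm), rep(0, 5))
  expect_true(k5$zero_mean_flag)

  p3 <- betweenness_centrality(path_graph(3))
  expect_equal(unname(p3$betweenness_raw), c(0, 1, 0))
})

test_that("metrics agree with brute-force oracles on random 20-node graphs", {
  dens <- seq(0.1, 0.6, length.out = 10)
  for (seed in 1:10) {
    A <- rand_adj(20, dens[seed], seed)
    g <- make_bg(A)
    expect_equal(clustering_coefficient(g)$per_node,
                 stats::setNames(o_cp(A)$per_node, g$region_labels),
                 tolerance = 1e-10)
    lp <- o_lp(A)
    if (is.na(lp)) expect_error(characteristic_path_length(g))
    else expect_equal(characteristic_path_length(g), lp, tolerance = 1e-10)
    expect_equal(global_efficiency(g), o_eglob(A), tolerance = 1e-10)
    expect_equal(local_efficiency(g)$per_node,
                 stats::setNames(o_eloc(A)$per_node, g$region_labels),
                 tolerance = 1e-10)
    expect_equal(betweenness_centrality(g)$betweenness_raw,
                 stats::setNames(o_betweenness(A), g$region_labels),
                 tolerance = 1e-10)
  }
})

test_that("rewiring preserves the degree sequence and is reproducible", {
  set.seed(2)
  g <- make_bg(rand_adj(30, 0.3, 5))
  r1 <- rewire_matched_random(g, seed = 42)
  r2 <- rewire_matched_random(g, seed = 42)
  expect_identical(r1$adjacency, r2$adjacency)
  expect_equal(sort(rowSums(r1$adjacency)), sort(rowSums(g$adjacency)))
  expect_equal(rowSums(r1$adjacency), rowSums(g$adjacency)) # per-node, not just sorted
  r3 <- rewire_matched_random(g, seed = 43)
  expect_false(identical(r1$adjacency, r3$adjacency))
  # a single-edge graph admits no swap
  one <- make_bg(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_warning(out <- rewire_matched_random(one), "no degree-preserving swap")
  expect_identical(out$adjacency, one$adjacency)
})

test_that("rewiring destroys modular clustering", {
  r <- make_modular_correlation(60, rep(1:4, each = 15), 0.7, 0.05)
  net <- structure(list(r = r, region_labels = sprintf("R%03d", 1:60), n_subjects = 50),
                   class = "covariance_network")
  g <- binarize_at_density(net, 0.2)
  cp_g <- clustering_coefficient(g)$mean
  cp_rand <- mean(vapply(1:20, function(i) {
    clustering_coefficient(rewire_matched_random(g, seed = i))$mean
  }, numeric(1)))
  expect_gt(cp_g, 2 * cp_rand)
})

test_that("small-world indices are near 1 for an already-random graph", {
  g <- make_bg(rand_adj(60, 0.25, 31))
  sw <- small_world_indices(g, n_random = 60, seed = 1)
  expect_equal(sw$sigma, 1, tolerance = 0.1)
  expect_equal(sw$gamma, 1, tolerance = 0.1)
  expect_equal(sw$lambda, 1, tolerance = 0.05)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
  # deterministic given the seed, even with n_random = 1
  a <- small_world_indices(g, n_random = 1, seed = 9)
  b <- small_world_indices(g, n_random = 1, seed = 9)
  expect_identical(a, b)
})

test_that("AUC over densities matches closed forms and a summation oracle", {
  grid <- default_density_grid()
  expect_equal(auc_over_densities(rep(1, 46), grid), 0.45)
  lin <- 2 * grid + 1 # trapezoid exact for linear curves
  expect_equal(auc_over_densities(lin, grid), 0.45 * (2 * 0.275 + 1) / 1 * 1,
               tolerance = 1e-12)
  set.seed(6)
  v <- rnorm(46)
  oracle <- 0
  for (i in 1:45) oracle <- oracle + (grid[i + 1] - grid[i]) * (v[i] + v[i + 1]) / 2
  expect_equal(auc_over_densities(v, grid), oracle, tolerance = 1e-12)
  expect_error(auc_over_densities(v[1:10], grid), "46 densities")
})

test_that("global efficiency is non-decreasing over a nested density stack", {
  ch <- tiny_cohort()
  res <- residualize(ch$table)
  net <- group_correlation(res, which(ch$table$group == "control"))
  stack <- build_stack(net, seq(0.1, 0.5, by = 0.05))
  eg <- vapply(stack$graphs, global_efficiency, numeric(1))
  expect_true(all(diff(eg) >= 0))
})

test_that("metric curves are tidy and complete", {
  ch <- tiny_cohort()
  res <- residualize(ch$table)
  net <- group_correlation(res, which(ch$table$group == "control"))
  stack <- build_stack(net, seq(0.2, 0.4, by = 0.1))
  cv <- metric_curves(stack, c("Cp", "Eglob", "sigma"), n_random = 5, seed = 2)
  expect_equal(nrow(cv), 3 * 3)
  expect_setequal(unique(cv$metric), c("Cp", "Eglob", "sigma"))
  expect_true(all(is.finite(cv$value)))
})
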