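# Independent brute-force graph oracles used to validate the package's metric
# implementations. Deliberately written from first principles (Floyd-Warshall
# distances, explicit triangle and geodesic enumeration) and kept free of
# igraph and of the package's own code paths.

o_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

o_cp <- function(A) {
  n <- nrow(A)
  per <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    per[v] <- if (k < 2) 0 else sum(A[nb, nb]) / (k * (k - 1))
  }
  list(per_node = per, mean = mean(per))
}

o_lp <- function(A) {
  D <- o_distances(A)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

o_eglob <- function(A) {
  if (nrow(A) < 2) return(0)
  D <- o_distances(A)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

o_eloc <- function(A) {
  n <- nrow(A)
  per <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    per[v] <- if (length(nb) < 2) 0 else o_eglob(A[nb, nb, drop = FALSE])
  }
  list(per_node = per, mean = mean(per))
}

# Betweenness by explicit geodesic counting: number of shortest s-t paths via
# dynamic programming over nodes ordered by distance from s, then fractional
# credit to every intermediate node.
o_betweenness <- function(A) {
  n <- nrow(A)
  D <- o_distances(A)
  npath <- matrix(0, n, n)
  for (s in seq_len(n)) {
    npath[s, s] <- 1
    for (j in order(D[s, ])) {
      if (j == s || !is.finite(D[s, j])) next
      preds <- which(A[, j] == 1 & D[s, ] == D[s, j] - 1)
      npath[s, j] <- sum(npath[s, preds])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + npath[s, v] * npath[v, t] / npath[s, t]
      }
    }
  }
  btw
}

# Construct a binary_graph object directly from an adjacency matrix.
make_bg <- function(A, labels = sprintf("N%02d", seq_len(nrow(A)))) {
  A <- (A + t(A) > 0) * 1
  diag(A) <- 0
  dimnames(A) <- list(labels, labels)
  npairs <- nrow(A) * (nrow(A) - 1) / 2
  structure(list(adjacency = A, density = sum(A) / 2 / npairs,
                 density_achieved = sum(A) / 2 / npairs,
                 region_labels = labels),
            class = "binary_graph")
}

# Erdos-Renyi-style random adjacency matrix.
rand_adj <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# All non-isomorphic simple graphs on <= 6 nodes, as adjacency matrices
# (graph atlas indices 0..208; index 0 is the empty 0-node graph, skipped).
atlas_graphs_le6 <- function() {
  lapply(1:208, function(i) {
    g <- igraph::graph_from_atlas(i)
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  })
}

# Small two-group cohort for fast pipeline-level tests.
tiny_cohort <- function(n_regions = 20, n = c(control = 12, patient = 12),
                        n_modules = 4, within_r = c(control = 0.6, patient = 0.4),
                        seed = 11) {
  generate_cohort(cohort_spec(n_regions = n_regions, n_per_group = n,
                              n_modules = n_modules, within_r = within_r,
                              seed = seed))
}
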