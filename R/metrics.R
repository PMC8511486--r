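#' @importFrom igraph graph_from_adjacency_matrix distances betweenness
#'   rewire keeping_degseq gsize as_adjacency_matrix
NULL

as_igraph <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected", diag = FALSE)
}

#' Clustering coefficient
#'
#' Per node, the fraction of possible edges among its direct neighbors that
#' actually exist (nodes with fewer than 2 neighbors score 0); the network
#' value is the unweighted mean over all nodes. Computed by adjacency matrix
#' algebra (`diag(A^3) / k(k-1)`), which keeps the permutation machinery fast.
#'
#' @param g A `binary_graph`.
#' @return List with `per_node` (named numeric) and `mean`.
#' @export
clustering_coefficient <- function(g) {
  A <- g$adjacency
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) # 2 x number of triangles through each node
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  names(ci) <- g$region_labels
  list(per_node = ci, mean = mean(ci))
}

graph_distances <- function(g) igraph::distances(as_igraph(g))

#' Characteristic path length
#'
#' Mean shortest-path length (in hops) over node pairs. With
#' `disconnected = "connected_pairs"` (default) the mean is taken over
#' connected pairs only, which keeps the low-density end of the curve
#' defined; `disconnected = "error"` gives a strict mode that rejects any
#' disconnected graph.
#'
#' @param g A `binary_graph`.
#' @param disconnected Policy for disconnected node pairs.
#' @return Scalar path length.
#' @export
characteristic_path_length <- function(g, disconnected = c("connected_pairs", "error")) {
  disconnected <- match.arg(disconnected)
  if (nrow(g$adjacency) < 2) stopf("path length needs at least 2 nodes")
  D <- graph_distances(g)
  d <- D[upper.tri(D)]
  if (disconnected == "error" && any(is.infinite(d))) {
    stopf("graph is disconnected and strict path-length mode was requested")
  }
  d <- d[is.finite(d)]
  if (!length(d)) stopf("path length undefined: no connected node pairs")
  mean(d)
}

#' Global efficiency
#'
#' Mean over all node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0. Equals 1 exactly for a complete graph.
#'
#' @param g A `binary_graph`.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  n <- nrow(g$adjacency)
  if (n < 2) return(0)
  D <- graph_distances(g)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

# All-pairs hop distances of a small adjacency matrix by repeated boolean
# matrix products (breadth-first reachability); O(diameter) dense matmuls.
adj_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  reach <- A > 0
  diag(reach) <- TRUE
  t <- 1
  while (t <= n) {
    wider <- (reach %*% A) > 0 | reach
    newly <- wider & !reach
    if (!any(newly)) break
    t <- t + 1
    D[newly] <- t
    reach <- wider
  }
  D
}

pairwise_efficiency <- function(D) {
  d <- D[upper.tri(D)]
  if (!length(d)) return(0)
  mean(ifelse(is.finite(d), 1 / d, 0))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on that node's
#' neighbors — shortest paths are confined to the neighborhood itself (nodes
#' with fewer than 2 neighbors score 0). The network value is the mean over
#' all nodes.
#'
#' @param g A `binary_graph`.
#' @return List with `per_node` and `mean`.
#' @export
local_efficiency <- function(g) {
  A <- g$adjacency
  le <- vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    pairwise_efficiency(adj_distances(A[nb, nb, drop = FALSE]))
  }, numeric(1))
  names(le) <- g$region_labels
  list(per_node = le, mean = mean(le))
}

#' Nodal betweenness centrality
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node (Brandes counting over unordered pairs, fractional credit for multiple
#' geodesics), plus the version normalized by the network mean used for group
#' comparison. If the mean raw betweenness is zero (e.g. a complete graph) the
#' normalized values are defined as all-zero and flagged.
#'
#' @param g A `binary_graph`.
#' @return Object of class `nodal_metrics`: list with `betweenness_raw`,
#'   `betweenness_norm`, `region_labels`, `zero_mean_flag`.
#' @export
betweenness_centrality <- function(g) {
  raw <- igraph::betweenness(as_igraph(g), directed = FALSE)
  names(raw) <- g$region_labels
  m <- mean(raw)
  if (m > 0) {
    norm <- raw / m
    flag <- FALSE
  } else {
    norm <- raw * 0
    flag <- TRUE
  }
  structure(list(betweenness_raw = raw, betweenness_norm = norm,
                 region_labels = g$region_labels, zero_mean_flag = flag),
            class = "nodal_metrics")
}

#' Degree-matched rewired random network
#'
#' Degree-preserving randomization by Maslov–Sneppen double-edge swaps
#' (rejecting self-loops and multi-edges), the field-standard "matched random
#' network" null for small-world indices. The returned graph has exactly the
#' same degree sequence (hence density) as the input.
#'
#' @param g A `binary_graph`.
#' @param n_swap_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed; output is reproducible.
#' @return A `binary_graph`; if the graph admits no valid swap (fewer than 2
#'   independent edges) it is returned unchanged with attribute
#'   `rewire_failed = TRUE` and a warning.
#' @export
rewire_matched_random <- function(g, n_swap_per_edge = 10, seed = 1L) {
  ig <- as_igraph(g)
  m <- igraph::gsize(ig)
  if (m < 2) {
    warning("graph admits no degree-preserving swap; returned unchanged")
    attr(g, "rewire_failed") <- TRUE
    return(g)
  }
  rg <- with_seed(seed, igraph::rewire(ig, igraph::keeping_degseq(niter = n_swap_per_edge * m)))
  A <- as.matrix(igraph::as_adjacency_matrix(rg, type = "both", sparse = FALSE))
  dimnames(A) <- list(g$region_labels, g$region_labels)
  structure(list(adjacency = A, density = g$density,
                 density_achieved = g$density_achieved,
                 region_labels = g$region_labels),
            class = "binary_graph")
}

#' Small-world indices against a rewired random ensemble
#'
#' gamma = Cp(g) / mean Cp of the ensemble; lambda = Lp(g) / mean Lp of the
#' ensemble; sigma = gamma / lambda. A sigma above 1 is the hallmark of
#' small-world organization. The conventional ensemble size is 1000 matched
#' random networks; smaller ensembles only widen the Monte-Carlo error of the
#' ensemble means.
#'
#' @param g A `binary_graph`.
#' @param n_random Ensemble size (>= 1).
#' @param seed Integer seed driving the whole ensemble.
#' @param n_swap_per_edge Swaps per edge for each rewired network.
#' @return List with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `n_random_used`.
#' @export
small_world_indices <- function(g, n_random = 1000, seed = 1L, n_swap_per_edge = 10) {
  if (n_random < 1) stopf("n_random must be >= 1")
  cp <- clustering_coefficient(g)$mean
  lp <- characteristic_path_length(g)
  cps <- numeric(n_random)
  lps <- numeric(n_random)
  for (i in seq_len(n_random)) {
    rg <- rewire_matched_random(g, n_swap_per_edge, seed = mix_seed(seed, i))
    cps[i] <- clustering_coefficient(rg)$mean
    lps[i] <- characteristic_path_length(rg)
  }
  if (mean(cps) <= 0 || mean(lps) <= 0) {
    stopf("degenerate graph: random-ensemble mean Cp or Lp is zero")
  }
  gamma <- cp / mean(cps)
  lambda <- lp / mean(lps)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = cp, Lp = lp, n_random_used = n_random)
}

#' All global metrics of one graph
#'
#' Cp, Lp, Eglob and Eloc, plus gamma/lambda/sigma when `n_random > 0`.
#'
#' @inheritParams small_world_indices
#' @return Named list of metric values.
#' @export
global_metrics <- function(g, n_random = 0, seed = 1L) {
  out <- list(Cp = clustering_coefficient(g)$mean,
              Lp = characteristic_path_length(g),
              Eglob = global_efficiency(g),
              Eloc = local_efficiency(g)$mean)
  if (n_random > 0) {
    sw <- small_world_indices(g, n_random = n_random, seed = seed)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
    out$sigma <- sw$sigma
  }
  out
}

sw_metrics <- c("gamma", "lambda", "sigma")
basic_metrics <- c("Cp", "Lp", "Eglob", "Eloc")

# Value of one named global metric on one graph; small-world metrics need an
# ensemble (n_random, seed).
metric_value <- function(g, metric, n_random = 100, seed = 1L) {
  switch(metric,
    Cp = clustering_coefficient(g)$mean,
    Lp = characteristic_path_length(g),
    Eglob = global_efficiency(g),
    Eloc = local_efficiency(g)$mean,
    gamma = small_world_indices(g, n_random, seed)$gamma,
    lambda = small_world_indices(g, n_random, seed)$lambda,
    sigma = small_world_indices(g, n_random, seed)$sigma,
    stopf("unknown metric '%s'", metric)
  )
}

#' Global metric curves over a density stack
#'
#' Evaluates global metrics at every density of a stack, returning a tidy
#' table suitable for plotting or AUC summarization.
#'
#' @param stack A `density_graph_stack`.
#' @param metrics Character vector among Cp, Lp, Eglob, Eloc, gamma, lambda,
#'   sigma.
#' @param n_random Ensemble size used for gamma/lambda/sigma (ignored
#'   otherwise).
#' @param seed Seed for the random ensembles.
#' @return `data.frame` with columns `density`, `metric`, `value`.
#' @export
metric_curves <- function(stack, metrics = basic_metrics, n_random = 100, seed = 1L) {
  stopifnot(inherits(stack, "density_graph_stack"))
  need_sw <- any(metrics %in% sw_metrics)
  rows <- lapply(seq_along(stack$densities), function(di) {
    g <- stack$graphs[[di]]
    sw <- if (need_sw) small_world_indices(g, n_random, seed = mix_seed(seed, di)) else NULL
    vals <- vapply(metrics, function(m) {
      if (m %in% sw_metrics) sw[[m]] else metric_value(g, m)
    }, numeric(1))
    data.frame(density = stack$densities[di], metric = metrics, value = unname(vals))
  })
  do.call(rbind, rows)
}

#' Trapezoidal area under a metric-versus-density curve
#'
#' Threshold-free summary of a metric across the density grid; exact for
#' piecewise-linear curves.
#'
#' @param values Metric values, one per grid density.
#' @param densities The density grid (strictly increasing, same length).
#' @return Scalar area.
#' @export
auc_over_densities <- function(values, densities) {
  if (length(values) != length(densities)) {
    stopf("curve has %d values but grid has %d densities",
          length(values), length(densities))
  }
  if (length(values) < 2) stopf("need at least 2 grid points for an AUC")
  sum(diff(densities) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
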