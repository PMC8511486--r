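#' Permutation-test settings
#'
#' @param n_perm Number of permutations (>= 1); 1000 is the conventional
#'   choice for group comparisons of network metrics.
#' @param alpha Significance level in (0, 1); also sets the null confidence
#'   band level (1 - alpha).
#' @param sidedness `"two_sided"` (default), `"greater"` or `"less"`.
#' @param seed Integer seed; every permutation is reproducible given
#'   `(seed, index)`.
#' @param n_random Rewired-ensemble size used when a permuted statistic needs
#'   gamma/lambda/sigma. Kept deliberately small by default: a full
#'   1000-permutation x 1000-network ensemble is cluster-scale, and the
#'   ensemble size only affects Monte-Carlo noise of the null means.
#' @return Object of class `permutation_spec`.
#' @export
permutation_spec <- function(n_perm = 1000, alpha = 0.05,
                             sidedness = c("two_sided", "greater", "less"),
                             seed = 1L, n_random = 20) {
  sidedness <- match.arg(sidedness)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 sidedness = sidedness, seed = as.integer(seed),
                 n_random = as.integer(n_random)),
            class = "permutation_spec")
}

#' Random reassignment of subjects into two groups
#'
#' Draws a uniformly random partition of the pooled subjects into two groups
#' of the original sizes — the exchangeability null for group-level covariance
#' networks. Reproducible given `(seed, index)`, so permutation `i` can be
#' regenerated in isolation.
#'
#' @param residuals A `residual_matrix` (defines the subject roster).
#' @param group_sizes Pair of group sizes; must sum to the pool size.
#' @param seed,index Integers identifying the permutation.
#' @param pool Optional vector of row indices to permute over (defaults to all
#'   subjects of `residuals`).
#' @return List with integer index vectors `a` and `b`.
#' @export
permute_groups <- function(residuals, group_sizes, seed = 1L, index = 1L, pool = NULL) {
  if (is.null(pool)) pool <- seq_along(residuals$subject_ids)
  if (sum(group_sizes) != length(pool)) {
    stopf("group sizes (%d + %d) must sum to the pooled subject count (%d)",
          group_sizes[1], group_sizes[2], length(pool))
  }
  perm <- with_seed(mix_seed(seed, index), sample(pool, length(pool)))
  list(a = perm[seq_len(group_sizes[1])],
       b = perm[(group_sizes[1] + 1):length(perm)])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), with input
#' validation on the permutation-p scale (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length.
#' @export
fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Valid permutation p-value with the +1 convention (never exactly 0).
perm_pvalue <- function(obs, null, sidedness) {
  null <- null[!is.na(null)]
  if (is.na(obs) || !length(null)) return(NA_real_)
  hits <- switch(sidedness,
    two_sided = sum(abs(null) >= abs(obs)),
    greater = sum(null >= obs),
    less = sum(null <= obs))
  (1 + hits) / (length(null) + 1)
}

group_indices <- function(residuals, subjects) {
  if (is.character(subjects)) {
    idx <- match(subjects, residuals$subject_ids)
    if (anyNA(idx)) stopf("unknown subject id(s): %s",
                          paste(subjects[is.na(idx)], collapse = ", "))
    idx
  } else if (is.logical(subjects)) {
    which(subjects)
  } else {
    as.integer(subjects)
  }
}

# One group's metric curve over the grid, straight from a subject subset of
# the residual matrix; failures at a density (e.g. undefined Lp) yield NA and
# are flagged by the caller. Calls the same exported metric functions as the
# direct path, so the observed statistic cannot drift from metrics-module
# output.
subset_metric_curve <- function(V, idx, grid, metric, edge_rank, n_random, seed) {
  r <- suppressWarnings(stats::cor(V[idx, , drop = FALSE]))
  if (anyNA(r)) return(rep(NA_real_, length(grid)))
  diag(r) <- 1
  ord <- edge_order(r, edge_rank)
  vapply(seq_along(grid), function(di) {
    g <- graph_from_edge_order(ord, grid[di], colnames(V))
    tryCatch(metric_value(g, metric, n_random = n_random, seed = mix_seed(seed, di)),
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Permutation test of a global-metric difference curve
#'
#' Compares groups A and B on one global network metric at every density of
#' the grid. The observed statistic is the A - B difference of the group
#' metric curves; the null distribution is built by randomly reassigning the
#' pooled (already-residualized) subjects into two groups of the original
#' sizes and rebuilding BOTH group networks at every density in each
#' permutation. Reports raw permutation p-values (with the +1 convention),
#' Benjamini-Hochberg adjustment across densities, and the empirical
#' `1 - alpha` null confidence band per density.
#'
#' @param residuals A `residual_matrix` (pooled, residualized once).
#' @param group_a,group_b Subject subsets (ids, indices or logical).
#' @param grid Density grid.
#' @param metric_name One of Cp, Lp, Eglob, Eloc, gamma, lambda, sigma.
#' @param spec A [permutation_spec()].
#' @param edge_rank Edge ranking convention for binarization.
#' @return Object of class `permutation_result` with elements `observed`,
#'   `null_samples` (n_perm x n_density), `p_raw`, `p_fdr`, `ci_low`,
#'   `ci_high`, `at` (densities), `flagged` (densities where a metric failed),
#'   `statistic_name`.
#' @export
global_metric_difference_test <- function(residuals, group_a, group_b,
                                          grid = default_density_grid(),
                                          metric_name = "Cp",
                                          spec = permutation_spec(),
                                          edge_rank = c("signed", "absolute")) {
  stopifnot(inherits(residuals, "residual_matrix"),
            inherits(spec, "permutation_spec"))
  edge_rank <- match.arg(edge_rank)
  if (!metric_name %in% c(basic_metrics, sw_metrics)) {
    stopf("unknown metric '%s'", metric_name)
  }
  V <- residuals$values
  ia <- group_indices(residuals, group_a)
  ib <- group_indices(residuals, group_b)
  pool <- c(ia, ib)
  sizes <- c(length(ia), length(ib))

  curve_of <- function(idx, seed) {
    subset_metric_curve(V, idx, grid, metric_name, edge_rank, spec$n_random, seed)
  }
  observed <- curve_of(ia, mix_seed(spec$seed, 0)) - curve_of(ib, mix_seed(spec$seed, 1))

  null <- matrix(NA_real_, spec$n_perm, length(grid))
  for (i in seq_len(spec$n_perm)) {
    part <- permute_groups(residuals, sizes, seed = spec$seed, index = i, pool = pool)
    si <- mix_seed(spec$seed, 1000000 + i)
    null[i, ] <- curve_of(part$a, si) - curve_of(part$b, mix_seed(si, 1))
  }

  p_raw <- vapply(seq_along(grid), function(di) {
    perm_pvalue(observed[di], null[, di], spec$sidedness)
  }, numeric(1))
  ok <- !is.na(p_raw)
  p_fdr <- rep(NA_real_, length(grid))
  if (any(ok)) p_fdr[ok] <- fdr_bh(p_raw[ok])
  ci <- apply(null, 2, stats::quantile,
              probs = c(spec$alpha / 2, 1 - spec$alpha / 2), na.rm = TRUE)
  flagged <- is.na(observed) | apply(null, 2, anyNA)
  structure(list(observed = observed, null_samples = null,
                 p_raw = p_raw, p_fdr = p_fdr,
                 ci_low = ci[1, ], ci_high = ci[2, ],
                 at = grid, flagged = flagged,
                 statistic_name = sprintf("%s difference (A - B)", metric_name),
                 spec = spec),
            class = "permutation_result")
}

# Per-node AUC over the grid of mean-normalized betweenness for one subject
# subset.
subset_betweenness_auc <- function(V, idx, grid, edge_rank) {
  r <- suppressWarnings(stats::cor(V[idx, , drop = FALSE]))
  if (anyNA(r)) return(rep(NA_real_, ncol(V)))
  diag(r) <- 1
  ord <- edge_order(r, edge_rank)
  bn <- vapply(grid, function(d) {
    g <- graph_from_edge_order(ord, d, colnames(V))
    betweenness_centrality(g)$betweenness_norm
  }, numeric(ncol(V)))
  apply(bn, 1, auc_over_densities, densities = grid)
}

#' Permutation test of nodal betweenness (AUC over densities)
#'
#' Per-node statistic: the trapezoidal AUC over the density grid of the
#' mean-normalized betweenness centrality. Observed A - B differences are
#' referred to the subject-relabelling null; Benjamini-Hochberg correction is
#' applied across nodes (the multiple-comparison family of a regional map).
#'
#' @inheritParams global_metric_difference_test
#' @return A `permutation_result` with one entry per region (`at` holds
#'   region labels).
#' @export
nodal_betweenness_test <- function(residuals, group_a, group_b,
                                   grid = default_density_grid(),
                                   spec = permutation_spec(),
                                   edge_rank = c("signed", "absolute")) {
  stopifnot(inherits(residuals, "residual_matrix"),
            inherits(spec, "permutation_spec"))
  edge_rank <- match.arg(edge_rank)
  V <- residuals$values
  ia <- group_indices(residuals, group_a)
  ib <- group_indices(residuals, group_b)
  pool <- c(ia, ib)
  sizes <- c(length(ia), length(ib))
  labels <- residuals$region_labels

  observed <- subset_betweenness_auc(V, ia, grid, edge_rank) -
    subset_betweenness_auc(V, ib, grid, edge_rank)
  null <- matrix(NA_real_, spec$n_perm, length(labels))
  for (i in seq_len(spec$n_perm)) {
    part <- permute_groups(residuals, sizes, seed = spec$seed, index = i, pool = pool)
    null[i, ] <- subset_betweenness_auc(V, part$a, grid, edge_rank) -
      subset_betweenness_auc(V, part$b, grid, edge_rank)
  }
  p_raw <- vapply(seq_along(labels), function(j) {
    perm_pvalue(observed[j], null[, j], spec$sidedness)
  }, numeric(1))
  ok <- !is.na(p_raw)
  p_fdr <- rep(NA_real_, length(labels))
  if (any(ok)) p_fdr[ok] <- fdr_bh(p_raw[ok])
  ci <- apply(null, 2, stats::quantile,
              probs = c(spec$alpha / 2, 1 - spec$alpha / 2), na.rm = TRUE)
  structure(list(observed = stats::setNames(observed, labels),
                 null_samples = null,
                 p_raw = stats::setNames(p_raw, labels),
                 p_fdr = stats::setNames(p_fdr, labels),
                 ci_low = ci[1, ], ci_high = ci[2, ],
                 at = labels, flagged = is.na(observed),
                 statistic_name = "normalized-betweenness AUC difference (A - B)",
                 spec = spec),
            class = "permutation_result")
}

#' Tidy a permutation result
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return `data.frame` with columns `at`, `observed`, `p_raw`, `p_fdr`,
#'   `ci_low`, `ci_high`, `flagged`.
#' @export
as.data.frame.permutation_result <- function(x, ...) {
  data.frame(at = x$at, observed = unname(x$observed),
             p_raw = unname(x$p_raw), p_fdr = unname(x$p_fdr),
             ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
             flagged = unname(x$flagged))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %s over %d positions, %d permutations\n",
              x$statistic_name, length(x$at), nrow(x$null_samples)))
  cat(sprintf("  p < %g at %d position(s) raw, %d after FDR\n", x$spec$alpha,
              sum(x$p_raw < x$spec$alpha, na.rm = TRUE),
              sum(x$p_fdr < x$spec$alpha, na.rm = TRUE)))
  invisible(x)
}
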