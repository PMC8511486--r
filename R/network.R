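#' Group-level Pearson correlation network
#'
#' Computes the region-by-region Pearson correlation matrix of the
#' covariate-corrected volumes across a subset of subjects (one study group).
#'
#' @param residuals A `residual_matrix` from [residualize()].
#' @param subjects Subject subset: character subject ids, integer row indices,
#'   or a logical vector; `NULL` uses all subjects.
#' @return Object of class `covariance_network`: list with `r` (correlation
#'   matrix, unit diagonal), `region_labels`, `n_subjects`.
#' @export
group_correlation <- function(residuals, subjects = NULL) {
  stopifnot(inherits(residuals, "residual_matrix"))
  V <- residuals$values
  if (!is.null(subjects)) {
    if (is.character(subjects)) subjects <- match(subjects, residuals$subject_ids)
    V <- V[subjects, , drop = FALSE]
  }
  if (nrow(V) < 3) stopf("need at least 3 subjects to correlate (got %d)", nrow(V))
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("correlation undefined: constant residual column for region(s) %s",
          paste(colnames(V)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(V)
  diag(r) <- 1
  structure(list(r = r, region_labels = colnames(V), n_subjects = nrow(V)),
            class = "covariance_network")
}

#' Default edge-density grid
#'
#' Densities from 0.05 to 0.50 in steps of 0.01 (46 values), the standard
#' thresholding range for group structural covariance networks.
#' @return Numeric vector of densities.
#' @export
default_density_grid <- function() seq(0.05, 0.50, by = 0.01)

# Deterministic edge ranking of the upper triangle: by signed correlation
# (default) or |r|, ties broken lexicographically by (i, j).
edge_order <- function(r, edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  n <- nrow(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[ut]
  key <- if (edge_rank == "absolute") abs(vals) else vals
  ord <- order(-key, ut[, 1], ut[, 2])
  list(i = ut[ord, 1], j = ut[ord, 2], n = n)
}

#' Binarize a correlation network at a target edge density
#'
#' Keeps exactly `round(density * N(N-1)/2)` edges (rounding half away from
#' zero), chosen as the largest off-diagonal correlations. By default edges
#' are ranked by signed correlation value — the dominant convention for
#' gray-matter covariance networks — with `edge_rank = "absolute"` available.
#' Ties are broken deterministically in lexicographic region order.
#'
#' @param net A `covariance_network`.
#' @param density Target edge density in (0, 1].
#' @param edge_rank `"signed"` (default) or `"absolute"`.
#' @return Object of class `binary_graph`: list with `adjacency` (symmetric
#'   0/1 matrix, zero diagonal), `density` (requested), `density_achieved`,
#'   `region_labels`.
#' @export
binarize_at_density <- function(net, density, edge_rank = c("signed", "absolute")) {
  stopifnot(inherits(net, "covariance_network"))
  edge_rank <- match.arg(edge_rank)
  if (!(density > 0 && density <= 1)) stopf("density must be in (0, 1]")
  ord <- edge_order(net$r, edge_rank)
  graph_from_edge_order(ord, density, net$region_labels)
}

graph_from_edge_order <- function(ord, density, labels) {
  n <- ord$n
  npairs <- n * (n - 1) / 2
  E <- round_half_away(density * npairs)
  if (E < 1) stopf("density %g yields 0 edges on %d regions (degenerate graph)", density, n)
  E <- min(E, npairs)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  ii <- ord$i[seq_len(E)]
  jj <- ord$j[seq_len(E)]
  A[cbind(ii, jj)] <- 1
  A[cbind(jj, ii)] <- 1
  structure(list(adjacency = A, density = density,
                 density_achieved = E / npairs, region_labels = labels),
            class = "binary_graph")
}

#' Binarize a network across a whole density grid
#'
#' The correlation ranking is computed once, so the edge sets are nested by
#' construction: the graph at density d is a subgraph of the graph at any
#' larger density.
#'
#' @inheritParams binarize_at_density
#' @param grid Strictly increasing vector of densities (see
#'   [default_density_grid()]).
#' @return Object of class `density_graph_stack`: list with `graphs` (one
#'   `binary_graph` per density, named by density), `densities`, `source`.
#' @export
build_stack <- function(net, grid = default_density_grid(),
                        edge_rank = c("signed", "absolute")) {
  stopifnot(inherits(net, "covariance_network"))
  edge_rank <- match.arg(edge_rank)
  if (any(diff(grid) <= 0)) stopf("density grid must be strictly increasing")
  ord <- edge_order(net$r, edge_rank)
  graphs <- lapply(grid, function(d) graph_from_edge_order(ord, d, net$region_labels))
  names(graphs) <- format_density(grid)
  structure(list(graphs = graphs, densities = grid, source = net),
            class = "density_graph_stack")
}

format_density <- function(d) sprintf("%.2f", d)

#' Write a labeled correlation matrix as CSV
#' @param net A `covariance_network`.
#' @param path Output file path.
#' @export
write_correlation_csv <- function(net, path) {
  df <- as.data.frame(net$r)
  utils::write.csv(cbind(region = net$region_labels, df), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.covariance_network <- function(x, ...) {
  cat(sprintf("covariance_network: %d regions, %d subjects, mean off-diagonal r = %.3f\n",
              nrow(x$r), x$n_subjects, mean(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary_graph: %d regions, %d edges (density %.3f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density_achieved))
  invisible(x)
}
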