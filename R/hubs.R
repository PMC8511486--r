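#' Identify network hubs by the mean + 1 SD betweenness rule
#'
#' A region is a hub when its betweenness centrality is at least one standard
#' deviation above the network mean (inclusive threshold; sample n-1 standard
#' deviation). The recommended basis is the AUC of normalized betweenness over
#' the full density grid, a threshold-free summary; a single-density basis can
#' be recorded instead.
#'
#' @param values Named per-region betweenness values (raw, normalized, or AUC).
#' @param region_labels Region names; defaults to `names(values)`.
#' @param basis Character tag recording what `values` are, e.g.
#'   `"auc_over_grid"` (default) or `"single_density:0.15"`.
#' @param group_name Optional group label carried into the report.
#' @return Object of class `hub_report`: list with `group_name`,
#'   `hub_regions`, `betweenness_values`, `threshold`, `basis`,
#'   `zero_variance_flag`.
#' @export
detect_hubs <- function(values, region_labels = names(values),
                        basis = "auc_over_grid", group_name = NULL) {
  if (is.null(region_labels)) stopf("region labels required (name the values)")
  values <- stats::setNames(as.numeric(values), region_labels)
  if (sum(is.finite(values)) < 2) stopf("need at least 2 regions with finite values")
  s <- stats::sd(values)
  thr <- mean(values) + s
  if (s == 0) {
    hubs <- character(0)
    flag <- TRUE
  } else {
    hubs <- region_labels[values >= thr]
    flag <- FALSE
  }
  structure(list(group_name = group_name, hub_regions = hubs,
                 betweenness_values = values, threshold = thr,
                 basis = basis, zero_variance_flag = flag),
            class = "hub_report")
}

#' Compare hub sets between two groups
#'
#' @param a,b `hub_report`s over the same region universe.
#' @return List with character vectors `common`, `only_a`, `only_b`.
#' @export
compare_hubs <- function(a, b) {
  stopifnot(inherits(a, "hub_report"), inherits(b, "hub_report"))
  if (!setequal(names(a$betweenness_values), names(b$betweenness_values))) {
    stopf("hub reports cover different region sets")
  }
  list(common = sort(intersect(a$hub_regions, b$hub_regions)),
       only_a = sort(setdiff(a$hub_regions, b$hub_regions)),
       only_b = sort(setdiff(b$hub_regions, a$hub_regions)))
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub_report%s: %d hub(s) of %d regions (threshold %.4g, basis %s)\n",
              if (is.null(x$group_name)) "" else paste0(" [", x$group_name, "]"),
              length(x$hub_regions), length(x$betweenness_values),
              x$threshold, x$basis))
  if (length(x$hub_regions)) cat("  ", paste(x$hub_regions, collapse = ", "), "\n")
  invisible(x)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

#' Write a BrainNet Viewer .node file
#'
#' Whitespace-delimited rows `x y z color size label`, one per region; hub
#' regions can be highlighted through the color column.
#'
#' @param path Output path.
#' @param coordinates `data.frame` with columns `region`, `x`, `y`, `z`
#'   covering every region.
#' @param values Per-region node sizes (e.g. betweenness), named by region.
#' @param hubs Optional character vector of hub regions; hubs get color code
#'   2, others 1.
#' @return `path`, invisibly.
#' @export
write_brainnet_node <- function(path, coordinates, values, hubs = character(0)) {
  labels <- names(values)
  miss <- setdiff(labels, coordinates$region)
  if (length(miss)) stopf("missing coordinates for region(s): %s",
                          paste(miss, collapse = ", "))
  co <- coordinates[match(labels, coordinates$region), ]
  lines <- sprintf("%s\t%s\t%s\t%d\t%s\t%s",
                   fmt_num(co$x), fmt_num(co$y), fmt_num(co$z),
                   ifelse(labels %in% hubs, 2L, 1L),
                   fmt_num(as.numeric(values)), labels)
  writeLines(lines, path)
  invisible(path)
}

#' Write a BrainNet Viewer .edge file (full symmetric matrix)
#'
#' @param path Output path.
#' @param matrix Symmetric numeric region-by-region matrix (adjacency or
#'   correlation).
#' @return `path`, invisibly.
#' @export
write_brainnet_edge <- function(path, matrix) {
  lines <- apply(matrix, 1, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BrainNet Viewer .edge file back into a matrix
#' @param path File written by [write_brainnet_edge()].
#' @return Numeric matrix.
#' @export
read_brainnet_edge <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
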