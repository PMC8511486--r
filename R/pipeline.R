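#' Read a subject-by-region volume table
#'
#' Reads CSV (or TSV, sniffed from the `.tsv` extension) with the columns
#' `subject_id`, `group`, `age`, `sex`, `education` followed by one numeric
#' column per region. All validation problems (missing columns, duplicate
#' subject ids, missing or non-numeric volume cells) are collected and
#' reported together with row/column coordinates.
#'
#' @param path Input file.
#' @return A validated subject table `data.frame`.
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  problems <- character(0)
  miss <- setdiff(core_columns, names(tab))
  if (length(miss)) {
    problems <- c(problems, sprintf("missing required column(s): %s",
                                    paste(miss, collapse = ", ")))
  }
  if (!length(miss)) {
    dup <- tab$subject_id[duplicated(tab$subject_id)]
    if (length(dup)) {
      problems <- c(problems, sprintf("duplicated subject_id(s): %s",
                                      paste(unique(dup), collapse = ", ")))
    }
    regs <- setdiff(names(tab), core_columns)
    if (!length(regs)) problems <- c(problems, "no region volume columns found")
    for (rc in regs) {
      col <- tab[[rc]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
        problems <- c(problems, sprintf("non-numeric volume in column '%s' (row %s)",
                                        rc, paste(bad, collapse = ", ")))
      }
      nas <- which(is.na(suppressWarnings(as.numeric(col))) | is.na(col))
      if (length(nas) && is.numeric(col)) {
        problems <- c(problems, sprintf("missing volume at (row %s, column '%s')",
                                        paste(nas, collapse = ", "), rc))
      }
    }
  }
  if (length(problems)) {
    stopf("invalid subject table '%s':\n  - %s", path,
          paste(problems, collapse = "\n  - "))
  }
  tab
}

#' Write a subject table as CSV
#' @param table Subject table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Configure an end-to-end structural covariance network run
#'
#' @param input Path to a subject table CSV/TSV, or a [cohort_spec()] to
#'   simulate one.
#' @param out_dir Output directory (created if absent).
#' @param covariates Covariate columns to residualize on.
#' @param include_mean_volume Append mean overall volume as a covariate.
#' @param grid Density grid.
#' @param edge_rank `"signed"` or `"absolute"` edge ranking.
#' @param metrics Global metrics for curves.
#' @param perm_metrics Global metrics to permutation-test (small-world
#'   metrics are costly inside permutations and off by default).
#' @param n_perm Permutations for the group tests.
#' @param n_random Rewired-ensemble size for gamma/lambda/sigma curves.
#' @param alpha Significance level.
#' @param seed Master seed; per-stage seeds are derived from it by a fixed
#'   counter scheme so stages are independently reproducible.
#' @param coordinates Optional `data.frame` (`region`, `x`, `y`, `z`) enabling
#'   BrainNet Viewer exports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, out_dir,
                       covariates = c("age", "sex", "education"),
                       include_mean_volume = TRUE,
                       grid = default_density_grid(),
                       edge_rank = c("signed", "absolute"),
                       metrics = c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma"),
                       perm_metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                       n_perm = 1000, n_random = 100, alpha = 0.05,
                       seed = 1L, coordinates = NULL) {
  edge_rank <- match.arg(edge_rank)
  if (!(is.character(input) || inherits(input, "cohort_spec"))) {
    stopf("input must be a file path or a cohort_spec")
  }
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (n_random < 1) stopf("n_random must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    stopf("density grid must be strictly increasing within (0, 1]")
  }
  structure(list(input = input, out_dir = out_dir, covariates = covariates,
                 include_mean_volume = include_mean_volume, grid = grid,
                 edge_rank = edge_rank, metrics = metrics,
                 perm_metrics = perm_metrics,
                 n_perm = as.integer(n_perm), n_random = as.integer(n_random),
                 alpha = alpha, seed = as.integer(seed),
                 coordinates = coordinates),
            class = "run_config")
}

config_json <- function(config) {
  x <- unclass(config)
  x$coordinates <- NULL
  x$out_dir <- NULL # recorded by location; keeps bundles comparable across dirs
  if (inherits(x$input, "cohort_spec")) x$input <- unclass(x$input)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Fixed stage counter for seed derivation.
stage_seeds <- function(seed) {
  stages <- c("simulate", "curves", "perm_global", "perm_nodal")
  stats::setNames(lapply(seq_along(stages), function(i) mix_seed(seed, i)), stages)
}

#' Run the full structural covariance network pipeline
#'
#' Executes: read or simulate the cohort; residualize pooled volumes; build
#' each group's correlation network and density stack; compute global metric
#' curves; permutation-test the configured global metrics and the nodal
#' betweenness AUC; detect and compare hubs. All outputs are written under
#' `config$out_dir` (tidy CSV tables, labeled matrix CSVs, JSON summaries, a
#' serialized config, and a plain-text log). Identical configs produce
#' identical bundles (the log line carrying the wall-clock timestamp aside).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory objects (table,
#'   residuals, networks, curves, test results, hub reports, output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  log_lines <- c(sprintf("scnet %s | run started %s",
                         as.character(utils::packageVersion("scnet")),
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                 sprintf("seed: %d", config$seed))
  seeds <- stage_seeds(config$seed)
  writeLines(config_json(config), out("config.json"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name, conditionMessage(e))),
                 out("log.txt"))
      writeLines("incomplete", out("INCOMPLETE"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- input ----------------------------------------------------------------
  truth <- NULL
  table <- stage("input", {
    if (inherits(config$input, "cohort_spec")) {
      sim <- generate_cohort(config$input)
      truth <- sim$truth
      write_subject_table(sim$table, out("subject_table.csv"))
      jsonlite::write_json(
        list(module_assignment = as.list(truth$module_assignment),
             planted_covariate_effects = as.list(truth$planted_covariate_effects),
             within_r = as.list(truth$spec$within_r),
             between_r = truth$spec$between_r),
        out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
      sim$table
    } else {
      read_subject_table(config$input)
    }
  })
  groups <- unique(table$group)
  if (length(groups) != 2) stopf("pipeline expects exactly 2 groups (found: %s)",
                                 paste(groups, collapse = ", "))
  n_by_group <- vapply(groups, function(gr) sum(table$group == gr), 0L)
  log_lines <- c(log_lines, sprintf("subjects: %d (%s)", nrow(table),
                                    paste(sprintf("%s=%d", groups, n_by_group),
                                          collapse = ", ")))

  # -- residualization (pooled, once) --------------------------------------
  resid <- stage("residualize",
                 residualize(table, config$covariates, config$include_mean_volume))
  utils::write.csv(data.frame(subject_id = resid$subject_ids,
                              group = resid$group,
                              resid$values, check.names = FALSE),
                   out("residuals.csv"), row.names = FALSE)

  idx <- lapply(groups, function(gr) which(table$group == gr))
  names(idx) <- groups

  # -- networks & curves ----------------------------------------------------
  nets <- stage("networks", lapply(idx, function(i) group_correlation(resid, i)))
  stacks <- lapply(nets, build_stack, grid = config$grid, edge_rank = config$edge_rank)
  for (gr in groups) {
    write_correlation_csv(nets[[gr]], out(sprintf("correlation_%s.csv", gr)))
    write_brainnet_edge(out(sprintf("correlation_%s.edge", gr)), nets[[gr]]$r)
  }
  curves <- stage("curves", {
    do.call(rbind, lapply(groups, function(gr) {
      cbind(group = gr,
            metric_curves(stacks[[gr]], config$metrics,
                          n_random = config$n_random, seed = seeds$curves))
    }))
  })
  utils::write.csv(curves, out("curves.csv"), row.names = FALSE)

  # -- permutation tests -----------------------------------------------------
  pspec <- permutation_spec(n_perm = config$n_perm, alpha = config$alpha,
                            seed = seeds$perm_global, n_random = config$n_random)
  global_tests <- stage("perm_global", {
    res <- lapply(config$perm_metrics, function(m) {
      global_metric_difference_test(resid, idx[[1]], idx[[2]], config$grid,
                                    m, pspec, config$edge_rank)
    })
    names(res) <- config$perm_metrics
    res
  })
  gt_tab <- do.call(rbind, lapply(config$perm_metrics, function(m) {
    cbind(metric = m, as.data.frame(global_tests[[m]]))
  }))
  utils::write.csv(gt_tab, out("global_tests.csv"), row.names = FALSE)
  # per-density significance markers (uncorrected and FDR side by side)
  markers <- gt_tab[, c("metric", "at", "observed", "p_raw", "p_fdr")]
  markers$sig_uncorrected <- markers$p_raw < config$alpha
  markers$sig_fdr <- markers$p_fdr < config$alpha
  utils::write.csv(markers, out("significance_markers.csv"), row.names = FALSE)

  nspec <- permutation_spec(n_perm = config$n_perm, alpha = config$alpha,
                            seed = seeds$perm_nodal, n_random = config$n_random)
  nodal_test <- stage("perm_nodal", {
    nodal_betweenness_test(resid, idx[[1]], idx[[2]], config$grid, nspec,
                           config$edge_rank)
  })
  utils::write.csv(cbind(region = nodal_test$at, as.data.frame(nodal_test)[-1]),
                   out("nodal_tests.csv"), row.names = FALSE)

  # -- hubs ------------------------------------------------------------------
  hub_reports <- stage("hubs", {
    hr <- lapply(groups, function(gr) {
      auc <- subset_betweenness_auc(resid$values, idx[[gr]], config$grid,
                                    config$edge_rank)
      detect_hubs(stats::setNames(auc, resid$region_labels),
                  basis = "auc_over_grid", group_name = gr)
    })
    names(hr) <- groups
    hr
  })
  cmp <- compare_hubs(hub_reports[[1]], hub_reports[[2]])
  jsonlite::write_json(
    list(groups = lapply(hub_reports, function(h) {
           list(group = h$group_name, hubs = h$hub_regions,
                threshold = h$threshold, basis = h$basis)
         }),
         common = cmp$common, only_first = cmp$only_a, only_second = cmp$only_b),
    out("hubs.json"), auto_unbox = TRUE, digits = NA)
  hub_tab <- do.call(rbind, lapply(hub_reports, function(h) {
    data.frame(group = h$group_name, region = names(h$betweenness_values),
               betweenness_auc = unname(h$betweenness_values),
               is_hub = names(h$betweenness_values) %in% h$hub_regions,
               threshold = h$threshold)
  }))
  utils::write.csv(hub_tab, out("hubs.csv"), row.names = FALSE)
  if (!is.null(config$coordinates)) {
    for (gr in groups) {
      write_brainnet_node(out(sprintf("hubs_%s.node", gr)), config$coordinates,
                          hub_reports[[gr]]$betweenness_values,
                          hubs = hub_reports[[gr]]$hub_regions)
    }
  }

  log_lines <- c(log_lines, "stages completed: input, residualize, networks, curves, perm_global, perm_nodal, hubs")
  writeLines(log_lines, out("log.txt"))
  invisible(list(table = table, truth = truth, residuals = resid,
                 networks = nets, stacks = stacks, curves = curves,
                 global_tests = global_tests, nodal_test = nodal_test,
                 hubs = hub_reports, hub_comparison = cmp,
                 out_dir = config$out_dir))
}
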