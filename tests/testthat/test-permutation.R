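small_resid <- function(n_regions = 20, n = c(15, 15), within = c(0.6, 0.6),
                        seed = 3) {
  ch <- generate_cohort(cohort_spec(n_regions = n_regions,
                                    n_per_group = c(control = n[1], patient = n[2]),
                                    n_modules = 4,
                                    within_r = c(control = within[1], patient = within[2]),
                                    seed = seed))
  list(resid = residualize(ch$table),
       ia = which(ch$table$group == "control"),
       ib = which(ch$table$group == "patient"),
       truth = ch$truth)
}

test_that("permuted partitions preserve sizes, cover the pool, and are reproducible", {
  d <- small_resid(n = c(32, 38))
  p1 <- permute_groups(d$resid, c(32, 38), seed = 5, index = 1)
  expect_length(p1$a, 32)
  expect_length(p1$b, 38)
  expect_length(intersect(p1$a, p1$b), 0)
  expect_setequal(c(p1$a, p1$b), seq_len(70))
  p2 <- permute_groups(d$resid, c(32, 38), seed = 5, index = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, permute_groups(d$resid, c(32, 38), seed = 5, index = 2)))
  expect_error(permute_groups(d$resid, c(30, 30), seed = 1, index = 1), "sum")
})

test_that("partitions of a 4+4 cohort are uniform over the 70 possibilities", {
  d <- small_resid(n_regions = 8, n = c(4, 4))
  keys <- vapply(1:10000, function(i) {
    paste(sort(permute_groups(d$resid, c(4, 4), seed = 1, index = i)$a),
          collapse = ",")
  }, character(1))
  counts <- table(keys)
  expect_length(counts, 70)
  chisq <- sum((counts - 10000 / 70)^2 / (10000 / 70))
  expect_gt(stats::pchisq(chisq, df = 69, lower.tail = FALSE), 0.001)
})

test_that("Benjamini-Hochberg adjustment matches hand-computed values", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_error(fdr_bh(c(0.1, 0)), "p-values")
  expect_error(fdr_bh(c(0.1, 1.2)), "p-values")
})

test_that("identical groups give zero observed difference and p = 1", {
  d <- small_resid(n = c(10, 10))
  grid <- c(0.2, 0.35)
  spec <- permutation_spec(n_perm = 49, seed = 7)
  res <- global_metric_difference_test(d$resid, d$ia, d$ia, grid, "Cp", spec)
  expect_equal(unname(res$observed), c(0, 0))
  expect_equal(unname(res$p_raw), c(1, 1))
  nod <- nodal_betweenness_test(d$resid, d$ia, d$ia, grid, spec)
  expect_true(all(nod$p_raw == 1))
  expect_true(all(abs(nod$observed) < 1e-12))
})

test_that("observed statistic equals the metrics-module computation (no drift)", {
  d <- small_resid()
  grid <- c(0.15, 0.3)
  spec <- permutation_spec(n_perm = 19, seed = 11)
  res <- global_metric_difference_test(d$resid, d$ia, d$ib, grid, "Eglob", spec)
  direct <- vapply(grid, function(dd) {
    ga <- binarize_at_density(group_correlation(d$resid, d$ia), dd)
    gb <- binarize_at_density(group_correlation(d$resid, d$ib), dd)
    global_efficiency(ga) - global_efficiency(gb)
  }, numeric(1))
  expect_equal(unname(res$observed), direct, tolerance = 1e-12)
})

test_that("permutation results are fully deterministic given (data, spec, seed)", {
  d <- small_resid()
  spec <- permutation_spec(n_perm = 29, seed = 13)
  a <- global_metric_difference_test(d$resid, d$ia, d$ib, c(0.2, 0.3), "Cp", spec)
  b <- global_metric_difference_test(d$resid, d$ia, d$ib, c(0.2, 0.3), "Cp", spec)
  expect_identical(a, b)
  # p-values respect the +1 convention and the CI bounds are ordered
  expect_true(all(a$p_raw >= 1 / 30))
  expect_true(all(a$p_fdr >= a$p_raw - 1e-15))
  expect_true(all(a$ci_low <= a$ci_high))
})

test_that("null p-values are (super-)uniform under exchangeability", {
  # 150 null cohorts, Cp at one density, 99 permutations each
  ps <- vapply(1:150, function(rep_i) {
    d <- small_resid(n_regions = 16, n = c(12, 12), seed = 1000 + rep_i)
    spec <- permutation_spec(n_perm = 99, seed = rep_i)
    global_metric_difference_test(d$resid, d$ia, d$ib, 0.25, "Cp", spec)$p_raw
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / 150)
    expect_lte(mean(ps <= alpha), alpha + 3 * se)
    expect_gte(mean(ps <= alpha), max(0, alpha - 3 * se))
  }
})

test_that("planted connector regions are localized by the nodal betweenness statistic", {
  # Factor-model cohorts: 3 modules of 10 regions; in group A, regions 1-3 are
  # rewired into cross-module connectors (loading on a global factor), the
  # classic generative recipe for high-betweenness bridge nodes. Group B keeps
  # them as ordinary module members.
  mods <- rep(1:3, each = 10)
  sim_group <- function(n, connector, seed) {
    set.seed(seed)
    f <- matrix(rnorm(n * 3), n)
    a <- sqrt(0.45)
    V <- matrix(rnorm(n * 30), n) * sqrt(1 - a^2)
    for (m in 1:3) V[, mods == m] <- V[, mods == m] + a * f[, m]
    if (connector) {
      g <- rowSums(f) / sqrt(3)
      b <- 0.85
      for (v in 1:3) V[, v] <- b * g + sqrt(1 - b^2) * rnorm(n)
    }
    colnames(V) <- sprintf("R%03d", 1:30)
    V
  }
  grid <- seq(0.08, 0.24, by = 0.04)
  n_per <- 80

  # betweenness AUC contrast, averaged over replicate cohorts, peaks at the
  # planted connectors
  obs_sum <- numeric(30)
  for (r in 1:8) {
    a_auc <- subset_betweenness_auc(sim_group(n_per, TRUE, 100 + r),
                                    1:n_per, grid, "signed")
    b_auc <- subset_betweenness_auc(sim_group(n_per, FALSE, 200 + r),
                                    1:n_per, grid, "signed")
    obs_sum <- obs_sum + abs(a_auc - b_auc)
  }
  expect_gte(sum(rank(-obs_sum)[1:3] <= 5), 2)
  expect_gt(mean(obs_sum[1:3]), 2 * mean(obs_sum[-(1:3)]))

  # single-cohort permutation p-values place a connector ahead of the
  # non-connector background
  V <- rbind(sim_group(n_per, TRUE, 101), sim_group(n_per, FALSE, 201))
  resid <- structure(list(values = scale(V, scale = FALSE),
                          subject_ids = sprintf("S%03d", seq_len(2 * n_per)),
                          region_labels = colnames(V),
                          covariates_used = character(0),
                          group = rep(c("a", "b"), each = n_per)),
                     class = "residual_matrix")
  res <- nodal_betweenness_test(resid, seq_len(n_per), n_per + seq_len(n_per),
                                grid, permutation_spec(n_perm = 99, seed = 2))
  expect_lt(min(res$p_raw[1:3]), stats::median(res$p_raw[-(1:3)]))
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
})
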