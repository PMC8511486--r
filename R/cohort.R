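#' Specify a synthetic morphometric cohort
#'
#' Defines the generating model for a two-group cohort of regional gray-matter
#' volumes with a modular inter-regional correlation structure, linear
#' covariate effects, and (optionally) a planted group difference in
#' within-module correlation strength. Defaults emulate a small clinical
#' structural-covariance study: 38 controls and 32 patients, 90 regions in 6
#' modules, and a weaker within-module covariance in the patient group.
#'
#' @param n_regions Number of brain regions (parcels).
#' @param n_per_group Named pair `c(control = , patient = )` of group sizes.
#'   Each size must be 0 (group absent) or at least 3; at least one group must
#'   be nonempty.
#' @param n_modules Number of covariance modules; regions are partitioned as
#'   evenly as possible and every module must contain at least 2 regions.
#' @param within_r Named pair of within-module correlation targets in `[0, 1)`,
#'   one per group.
#' @param between_r Between-module correlation target; must satisfy
#'   `0 <= between_r <= min(within_r) < 1`.
#' @param covariate_effects Named numeric vector of linear slopes on volume for
#'   `age` (per year), `sex` (male indicator) and `education` (per year).
#' @param noise_sd Standard deviation of the correlated residual volume noise
#'   (volume units).
#' @param baseline_volume Mean regional volume (volume units).
#' @param age_range,education_range Uniform sampling ranges for the age and
#'   education covariates (years).
#' @param sex_prob Probability that a subject is male.
#' @param seed Integer seed; the generator is bit-reproducible given the spec.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [make_modular_correlation()]
#' @export
cohort_spec <- function(n_regions = 90,
                        n_per_group = c(control = 38, patient = 32),
                        n_modules = 6,
                        within_r = c(control = 0.6, patient = 0.4),
                        between_r = 0.1,
                        covariate_effects = c(age = -0.05, sex = 0.5, education = 0.02),
                        noise_sd = 1,
                        baseline_volume = 10,
                        age_range = c(55, 80),
                        education_range = c(6, 16),
                        sex_prob = 0.5,
                        seed = 1L) {
  if (length(n_per_group) != 2) stopf("n_per_group must be a pair of counts")
  if (is.null(names(n_per_group))) names(n_per_group) <- c("control", "patient")
  if (length(within_r) != 2) stopf("within_r must be a pair of correlations")
  if (is.null(names(within_r))) names(within_r) <- names(n_per_group)
  bad <- n_per_group != 0 & n_per_group < 3
  if (any(bad)) {
    stopf("group sizes must be 0 or >= 3 (got %s = %d)",
          names(n_per_group)[bad][1], n_per_group[bad][1])
  }
  if (sum(n_per_group) == 0) stopf("at least one group must be nonempty")
  active <- n_per_group > 0
  if (!(between_r >= 0 && between_r <= min(within_r[active]) &&
        max(within_r[active]) < 1)) {
    stopf("require 0 <= between_r <= min(within_r) < 1 (between_r = %g, within_r = %s)",
          between_r, paste(within_r, collapse = ", "))
  }
  sizes <- module_partition(n_regions, n_modules)
  if (min(sizes) < 2) {
    stopf("module partition of %d regions into %d modules leaves a module with < 2 regions",
          n_regions, n_modules)
  }
  for (nm in c("age", "sex", "education")) {
    if (!nm %in% names(covariate_effects)) {
      stopf("covariate_effects must name '%s'", nm)
    }
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(
    list(n_regions = as.integer(n_regions),
         n_per_group = as.integer(round(n_per_group)) |> stats::setNames(names(n_per_group)),
         n_modules = as.integer(n_modules),
         within_r = within_r, between_r = between_r,
         covariate_effects = covariate_effects,
         noise_sd = noise_sd, baseline_volume = baseline_volume,
         age_range = age_range, education_range = education_range,
         sex_prob = sex_prob, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Partition n_regions into n_modules contiguous blocks as evenly as possible.
module_partition <- function(n_regions, n_modules) {
  sizes <- rep(n_regions %/% n_modules, n_modules)
  extra <- n_regions %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Build a block-structured (modular) correlation matrix
#'
#' Entries are 1 on the diagonal, `within_r` for region pairs in the same
#' module and `between_r` otherwise. This is the correlation matrix implied by
#' a two-level factor model (one global factor plus one factor per module), so
#' it is positive semi-definite whenever `0 <= between_r <= within_r < 1`;
#' the result is verified by eigendecomposition and rejected otherwise.
#'
#' @param n_regions Number of regions.
#' @param module_assignment Integer vector of length `n_regions` mapping each
#'   region to a module index.
#' @param within_r,between_r Correlation targets, `0 <= between_r <= within_r < 1`.
#' @return A symmetric `n_regions x n_regions` correlation matrix.
#' @export
make_modular_correlation <- function(n_regions, module_assignment, within_r, between_r) {
  if (length(module_assignment) != n_regions) {
    stopf("module_assignment must have length n_regions = %d", n_regions)
  }
  if (!(between_r >= 0 && between_r <= within_r && within_r < 1)) {
    stopf("require 0 <= between_r <= within_r < 1 (within_r = %g, between_r = %g)",
          within_r, between_r)
  }
  same <- outer(module_assignment, module_assignment, "==")
  r <- matrix(between_r, n_regions, n_regions)
  r[same] <- within_r
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stopf("target correlation matrix is not positive semi-definite (within_r = %g, between_r = %g, min eigenvalue = %g)",
          within_r, between_r, min(ev))
  }
  r
}

# Symmetric PSD square root via eigendecomposition; population correlation of
# L %*% z (z standard normal) equals `r` exactly.
psd_sqrt <- function(r) {
  e <- eigen(r, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic subject-by-region volume table
#'
#' Draws, for each subject, covariates (age uniform, sex Bernoulli, education
#' uniform) followed by a correlated noise vector, in a fixed per-subject
#' stream order, so extending a group appends draws without perturbing earlier
#' subjects. Volumes are
#' `baseline_volume + covariate_effects . covariates + noise_sd * L z`,
#' where `L` is the symmetric square root of the group's target correlation
#' matrix and `z` is standard normal, so the population correlation of the
#' covariate-free volumes equals the planted target.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components `table` (a `data.frame` with columns
#'   `subject_id`, `group`, `age`, `sex`, `education` and one column per
#'   region) and `truth` (class `ground_truth`: the per-group target
#'   correlation matrices, the module assignment and the planted covariate
#'   effects).
#' @examples
#' ch <- generate_cohort(cohort_spec(n_regions = 12, n_per_group = c(6, 6),
#'                                   n_modules = 3, seed = 42))
#' dim(ch$table)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  labels <- region_label_seq(spec$n_regions)
  sizes <- module_partition(spec$n_regions, spec$n_modules)
  modules <- rep(seq_along(sizes), sizes)
  groups <- names(spec$n_per_group)
  targets <- lapply(seq_along(groups), function(gi) {
    if (spec$n_per_group[gi] == 0) return(NULL)
    make_modular_correlation(spec$n_regions, modules, spec$within_r[gi], spec$between_r)
  })
  names(targets) <- groups
  roots <- lapply(targets, function(r) if (is.null(r)) NULL else psd_sqrt(r))

  eff <- spec$covariate_effects
  rows <- vector("list", sum(spec$n_per_group))
  k <- 0L
  with_seed(spec$seed, {
    for (gi in seq_along(groups)) {
      ng <- spec$n_per_group[gi]
      if (ng == 0) next
      L <- roots[[gi]]
      for (s in seq_len(ng)) {
        # documented stream order: covariates first, then the noise vector
        age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
        sex <- stats::rbinom(1, 1, spec$sex_prob)
        edu <- stats::runif(1, spec$education_range[1], spec$education_range[2])
        z <- stats::rnorm(spec$n_regions)
        vol <- spec$baseline_volume +
          eff[["age"]] * age + eff[["sex"]] * sex + eff[["education"]] * edu +
          spec$noise_sd * drop(L %*% z)
        k <- k + 1L
        rows[[k]] <- list(group = groups[gi], age = age, sex = sex,
                          education = edu, vol = vol)
      }
    }
  })
  n <- k
  tab <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = vapply(rows, `[[`, "", "group"),
    age = vapply(rows, `[[`, 0, "age"),
    sex = ifelse(vapply(rows, `[[`, 0, "sex") == 1, "male", "female"),
    education = vapply(rows, `[[`, 0, "education"),
    stringsAsFactors = FALSE
  )
  vols <- do.call(rbind, lapply(rows, `[[`, "vol"))
  colnames(vols) <- labels
  tab <- cbind(tab, as.data.frame(vols))
  truth <- structure(
    list(target_correlation = targets,
         module_assignment = stats::setNames(modules, labels),
         planted_covariate_effects = eff,
         spec = spec),
    class = "ground_truth"
  )
  list(table = tab, truth = truth)
}

region_label_seq <- function(n) sprintf("R%03d", seq_len(n))

# Columns of a subject table that are regional volumes (everything after the
# fixed demographic block).
core_columns <- c("subject_id", "group", "age", "sex", "education")

#' Region labels of a subject table
#' @param table A subject table as returned by [generate_cohort()] or
#'   [read_subject_table()].
#' @return Character vector of region column names, in table order.
#' @export
region_labels <- function(table) setdiff(names(table), core_columns)

#' Extract the subjects-by-regions volume matrix from a subject table
#' @inheritParams region_labels
#' @return Numeric matrix, rownames = subject ids, colnames = region labels.
#' @export
volume_matrix <- function(table) {
  regs <- region_labels(table)
  m <- as.matrix(table[, regs, drop = FALSE])
  if (!is.numeric(m)) stopf("region volume columns must be numeric")
  rownames(m) <- table$subject_id
  m
}
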