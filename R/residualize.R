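#' Remove covariate effects from regional volumes
#'
#' Fits, for every region independently, an ordinary least-squares regression
#' of volume on an intercept plus the named covariates and (by default) the
#' subject's mean overall gray-matter volume, and returns the residuals. Sex
#' (or any factor covariate) is expanded to treatment-coded indicators.
#' Residualization is performed once on the full table, before any group
#' split, which is what makes the subject-relabelling permutation scheme
#' downstream well defined.
#'
#' @param table A subject table (see [generate_cohort()], [read_subject_table()]).
#' @param covariates Ordered character vector of covariate column names;
#'   default `c("age", "sex", "education")`.
#' @param include_mean_volume If `TRUE` (default), the per-subject mean of the
#'   regional volumes is appended as an additional covariate, mirroring the
#'   correction for overall gray-matter volume used in structural-covariance
#'   studies.
#' @return An object of class `residual_matrix`: list with `values`
#'   (subjects x regions residual matrix), `subject_ids`, `region_labels`,
#'   `covariates_used`, and the subjects' `group` labels carried through.
#' @export
residualize <- function(table, covariates = c("age", "sex", "education"),
                        include_mean_volume = TRUE) {
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov)) {
    stopf("covariate(s) not found in table: %s", paste(missing_cov, collapse = ", "))
  }
  Y <- volume_matrix(table)
  X <- stats::model.matrix(stats::reformulate(covariates), data = table)
  if (include_mean_volume) {
    X <- cbind(X, mean_volume = rowMeans(Y))
  }
  if (nrow(X) < ncol(X) + 1) {
    stopf("need at least %d subjects to fit %d parameters (got %d)",
          ncol(X) + 1, ncol(X), nrow(X))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("rank-deficient covariate design; offending column(s): %s",
          paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qx, Y)
  dimnames(res) <- dimnames(Y)
  structure(
    list(values = res,
         subject_ids = table$subject_id,
         region_labels = colnames(Y),
         covariates_used = setdiff(colnames(X), "(Intercept)"),
         group = table$group),
    class = "residual_matrix"
  )
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("residual_matrix: %d subjects x %d regions (covariates: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$covariates_used, collapse = ", ")))
  invisible(x)
}
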