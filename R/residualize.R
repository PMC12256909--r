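#' Residualize phenotype and PGS on adjustment covariates
#'
#' Projects the adjustment covariates (plus an implicit intercept) out of
#' both the phenotype and the PGS by ordinary least squares, then rescales
#' both residual vectors to mean 0 and variance 1 (sample, n-1
#' denominator).  This reduces quantile regression to a univariate problem
#' and puts the OLS slope on the correlation scale; quantile-specific
#' effects for the covariates themselves are deliberately not modelled.
#'
#' @param cohort a [cohort_table()].
#' @param covariate_names covariate columns to project out; defaults to all
#'   stored covariates.  `character(0)` projects onto the intercept only
#'   (centering + scaling).
#' @return object of class `residual_pair` with fields `y_star`, `g_star`,
#'   `n`, and `covariate_names`.
#' @export
residualize <- function(cohort,
                        covariate_names = colnames(cohort$covariates)) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(covariate_names)) covariate_names <- character(0)
  n <- cohort$n

  if (length(covariate_names) > 0L) {
    missing_cols <- setdiff(covariate_names, colnames(cohort$covariates))
    if (length(missing_cols) > 0L) {
      stop("unknown covariate(s): ", paste(missing_cols, collapse = ", "))
    }
    C <- cohort$covariates[, covariate_names, drop = FALSE]
    X <- cbind(`(Intercept)` = 1, C)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(
      "covariate design is rank-deficient; collinear column(s): ",
      paste(bad, collapse = ", ")
    )
  }

  y_res <- qr.resid(qrX, cohort$phenotype)
  g_res <- qr.resid(qrX, cohort$pgs)

  vy <- stats::var(y_res)
  vg <- stats::var(g_res)
  if (vy <= 1e-12) stop("phenotype has zero residual variance after projection")
  if (vg <= 1e-12) stop("pgs has zero residual variance after projection")

  structure(
    list(
      y_star = as.numeric(y_res / sqrt(vy)),
      g_star = as.numeric(g_res / sqrt(vg)),
      n = n,
      covariate_names = covariate_names
    ),
    class = "residual_pair"
  )
}

#' @export
print.residual_pair <- function(x, ...) {
  cat(
    "<residual_pair> n =", x$n, "| covariates projected out:",
    if (length(x$covariate_names)) paste(x$covariate_names, collapse = ", ") else "(intercept only)",
    "\n"
  )
  invisible(x)
}
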