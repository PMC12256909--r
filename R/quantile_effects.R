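#' Quantile grid
#'
#' Strictly increasing quantile levels in the open unit interval.  The
#' default is the 19-point grid 0.05, 0.10, ..., 0.95.
#'
#' @param taus numeric vector of quantile levels.
#' @return object of class `quantile_grid`.
#' @export
quantile_grid <- function(taus = seq(0.05, 0.95, by = 0.05)) {
  taus <- as.numeric(taus)
  if (length(taus) < 1L) stop("empty quantile grid")
  if (any(taus <= 0) || any(taus >= 1)) stop("quantile levels must lie in (0, 1)")
  if (any(diff(taus) <= 0)) stop("quantile levels must be strictly increasing")
  structure(list(taus = taus, K = length(taus)), class = "quantile_grid")
}

#' Quantile-regression check loss
#'
#' \eqn{\sum_i \rho_\tau(r_i)} with \eqn{\rho_\tau(r) = r(\tau - 1\{r<0\})}.
#'
#' @param residuals numeric vector.
#' @param tau quantile level in (0, 1).
#' @return nonnegative scalar; zero iff all residuals are zero.
#' @export
check_loss <- function(residuals, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  cpp_check_loss(as.numeric(residuals), tau)
}

#' OLS effect size of residual trait on residual PGS
#'
#' Least-squares slope of `y_star` on `[1, g_star]`.  Because both vectors
#' are standardized, this equals their Pearson correlation and its square
#' is the predictive R-squared of the score.
#'
#' @param pair a `residual_pair` from [residualize()].
#' @return scalar slope (correlation scale).
#' @export
fit_ols <- function(pair) {
  stopifnot(inherits(pair, "residual_pair"))
  if (pair$n < 3L) stop("need at least 3 observations")
  g <- pair$g_star
  y <- pair$y_star
  gc_ <- g - mean(g)
  sum(gc_ * (y - mean(y))) / sum(gc_ * gc_)
}

#' Quantile-regression fit on raw vectors
#'
#' Minimizes the check loss of `y - a - b g` over `(a, b)`.  The solver
#' profiles out the intercept (exactly, as a tau-th order statistic of the
#' slope-adjusted residuals) and minimizes the convex profiled objective in
#' the slope by bracketed golden-section search; the contract is objective
#' optimality (within 1e-6 relative of the global minimum), with any
#' minimizer acceptable when the optimum is non-unique.  Exists primarily
#' for testing; the screening pipeline always residualizes and
#' standardizes first and calls [fit_qr()].
#'
#' @param y,g numeric vectors of equal length.
#' @param tau quantile level in (0, 1).
#' @return list with `intercept`, `slope`, `objective`, `tau`, `converged`.
#' @export
fit_qr_raw <- function(y, g, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  y <- as.numeric(y)
  g <- as.numeric(g)
  if (length(y) != length(g)) stop("y and g lengths differ")
  if (length(y) < 3L) stop("need at least 3 observations")
  fit <- cpp_qr_fit(y, g, tau)
  if (!isTRUE(fit$converged)) {
    stop(
      "quantile-regression solver failed to converge at tau = ", tau,
      " (objective ", format(fit$objective), ")"
    )
  }
  fit$tau <- tau
  fit
}

#' Quantile-regression fit on a residual pair
#'
#' @param pair a `residual_pair` from [residualize()].
#' @param tau quantile level in (0, 1).
#' @return list with `intercept`, `slope`, `objective`, `tau`, `converged`.
#' @export
fit_qr <- function(pair, tau) {
  stopifnot(inherits(pair, "residual_pair"))
  fit_qr_raw(pair$y_star, pair$g_star, tau)
}

#' Effect profile over a quantile grid
#'
#' Fits the OLS effect and the quantile-specific effects at every level of
#' the grid.  Quantiles with `n * min(tau, 1 - tau) < 20` are marked
#' `unstable_tau`: extreme quantiles of small samples rest on a handful of
#' observations and their fits can be erratic.
#'
#' @param pair a `residual_pair` from [residualize()].
#' @param grid a [quantile_grid()].
#' @return object of class `effect_profile` with fields `beta_ols`,
#'   `intercept_tau`, `beta_tau`, `objective_tau`, `r2_ols`, `r2_tau`,
#'   `unstable_tau`, `grid`, `n`.
#' @export
fit_profile <- function(pair, grid = quantile_grid()) {
  stopifnot(inherits(pair, "residual_pair"), inherits(grid, "quantile_grid"))
  beta_ols <- fit_ols(pair)
  fits <- cpp_qr_grid(pair$y_star, pair$g_star, grid$taus)
  if (any(fits[, 4] != 1)) {
    stop(
      "quantile-regression solver failed to converge at tau = ",
      paste(grid$taus[fits[, 4] != 1], collapse = ", ")
    )
  }
  structure(
    list(
      beta_ols = beta_ols,
      intercept_tau = fits[, 1],
      beta_tau = fits[, 2],
      objective_tau = fits[, 3],
      r2_ols = beta_ols^2,
      r2_tau = fits[, 2]^2,
      unstable_tau = pair$n * pmin(grid$taus, 1 - grid$taus) < 20,
      grid = grid,
      n = pair$n
    ),
    class = "effect_profile"
  )
}

#' @export
print.effect_profile <- function(x, ...) {
  cat(
    "<effect_profile> n =", x$n, "| beta_ols =", format(x$beta_ols, digits = 4),
    "| beta_tau range [", format(min(x$beta_tau), digits = 4), ",",
    format(max(x$beta_tau), digits = 4), "] over", x$grid$K, "quantiles\n"
  )
  invisible(x)
}
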