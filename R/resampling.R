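#' Default m-of-n bootstrap resample size
#'
#' `min(10000, n)`: resamples of at most 10,000 rows keep quantile
#' regression refits cheap at biobank sample sizes while the m/n rescaling
#' recovers the full-sample covariance.
#'
#' @param n number of observations.
#' @return integer resample size.
#' @export
default_m <- function(n) {
  if (n < 1L) stop("n must be positive")
  as.integer(min(10000L, n))
}

#' m-of-n bootstrap covariance of OLS and quantile effects
#'
#' Draws `B` resamples of `m` rows with replacement from the paired
#' residual data, refits the OLS slope and every quantile slope jointly on
#' each resample (same indices for all, so the full (K+1)-dimensional
#' covariance is coherent), and rescales the empirical replicate
#' covariance by `m/n`.  Standard errors of the ratios `beta_tau/beta_ols`
#' are computed from the replicate ratios, rescaled by `sqrt(m/n)`.
#' Resampling operates on the residualized pair; the covariate projection
#' is not refit per replicate (its variability is second order at the
#' sample sizes this screen targets).
#'
#' Replicates whose resampled score is constant are redrawn (up to a retry
#' cap); replicates with `|beta_ols| < 1e-8` are dropped from the ratio
#' statistics with a logged count.
#'
#' @param pair a `residual_pair` from [residualize()].
#' @param grid a [quantile_grid()].
#' @param m resample size, `3 <= m <= n`; default [default_m()].
#' @param B number of bootstrap replicates (default 200).
#' @param seed integer seed; results are bitwise reproducible from it.
#' @return object of class `bootstrap_covariance` with fields `m`, `n`,
#'   `B`, `seed`, `cov` ((K+1) x (K+1), OLS first), `beta_se`, `ratio_se`,
#'   `ratio_mean`, `n_dropped_ratio`, `grid`.
#' @export
mofn_bootstrap <- function(pair, grid = quantile_grid(), m = default_m(pair$n),
                           B = 200L, seed = 1L) {
  stopifnot(inherits(pair, "residual_pair"), inherits(grid, "quantile_grid"))
  n <- pair$n
  m <- as.integer(m)
  B <- as.integer(B)
  if (m < 3L || m > n) stop("need 3 <= m <= n")
  if (B < 2L) stop("need at least 2 bootstrap replicates")

  est <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, m * B, replace = TRUE), nrow = m, ncol = B)
    # redraw replicates whose resampled score is constant
    for (retry in seq_len(100L)) {
      bad <- which(apply(idx, 2L, function(j) {
        stats::var(pair$g_star[j]) <= 0
      }))
      if (length(bad) == 0L) break
      message("mofn_bootstrap: redrawing ", length(bad), " degenerate replicate(s)")
      idx[, bad] <- sample.int(n, m * length(bad), replace = TRUE)
      if (retry == 100L) stop("could not draw non-degenerate bootstrap replicates")
    }
    cpp_boot_fit(pair$y_star, pair$g_star, grid$taus, idx)
  })

  scale <- m / n
  cov_hat <- scale * stats::cov(est)
  cov_hat <- (cov_hat + t(cov_hat)) / 2
  dimnames(cov_hat) <- rep(list(c("ols", paste0("tau", grid$taus))), 2L)

  ok <- abs(est[, 1L]) >= 1e-8
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(
      "mofn_bootstrap: dropped ", n_dropped,
      " replicate(s) with near-zero OLS slope from ratio statistics"
    )
  }
  if (sum(ok) < 2L) stop("too few usable replicates for ratio statistics")
  ratios <- est[ok, -1L, drop = FALSE] / est[ok, 1L]
  ratio_se <- sqrt(scale) * apply(ratios, 2L, stats::sd)

  structure(
    list(
      m = m, n = n, B = B, seed = as.integer(seed),
      cov = cov_hat,
      beta_se = sqrt(pmax(diag(cov_hat), 0)),
      ratio_se = as.numeric(ratio_se),
      ratio_mean = as.numeric(colMeans(ratios)),
      n_dropped_ratio = n_dropped,
      grid = grid
    ),
    class = "bootstrap_covariance"
  )
}

#' @export
print.bootstrap_covariance <- function(x, ...) {
  cat(
    "<bootstrap_covariance> m =", x$m, "of n =", x$n, ", B =", x$B,
    "replicates, seed =", x$seed, "\n"
  )
  invisible(x)
}
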