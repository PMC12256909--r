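#' Ratio profile of quantile-specific to OLS effect sizes
#'
#' Forms the ratios `beta_tau / beta_ols` from the point estimates and
#' pairs them with the bootstrap standard errors of the replicate ratios.
#' Ratios are only interpretable for scores with a positive and clearly
#' significant OLS effect, so the function aborts unless
#' `beta_ols / se_analytic > z_threshold` with the large-sample
#' correlation standard error `(1 - r^2) / sqrt(n)`.
#'
#' @param profile an `effect_profile` from [fit_profile()].
#' @param boot a `bootstrap_covariance` from [mofn_bootstrap()] on the same
#'   grid.
#' @param z_threshold significance gate on the OLS effect (default 4).
#' @return list with `ratios` and `ratio_se` (length K each).
#' @export
ratio_profile <- function(profile, boot, z_threshold = 4) {
  stopifnot(
    inherits(profile, "effect_profile"),
    inherits(boot, "bootstrap_covariance")
  )
  if (!isTRUE(all.equal(profile$grid$taus, boot$grid$taus))) {
    stop("profile and bootstrap quantile grids differ")
  }
  r <- profile$beta_ols
  se_analytic <- (1 - r^2) / sqrt(profile$n)
  if (r <= 0 || r / se_analytic <= z_threshold) {
    stop(
      "ratio screening requires a positive, statistically significant OLS ",
      "effect (beta_ols = ", format(r, digits = 4), ", z = ",
      format(r / se_analytic, digits = 4), "); not met"
    )
  }
  list(ratios = profile$beta_tau / r, ratio_se = boot$ratio_se)
}

#' Non-equivalence (minimum-effects) test on effect-size ratios
#'
#' Quantile k is flagged when the two-sided `(1 - alpha/2)`
#' normal-approximation confidence interval `ratios[k] +/- z * ratio_se[k]`
#' lies entirely outside the equivalence band `(1/lam, lam)`; because both
#' band edges are in play, this corresponds to a minimum-effects test of
#' level `alpha`.  With the default `alpha = 0.10` this is the familiar
#' 95% CI with z = 1.959964.
#'
#' @param ratios,ratio_se length-K numeric vectors (see [ratio_profile()]).
#' @param lam equivalence-band parameter, `lam > 1`.
#' @param alpha test level in (0, 1); default 0.10.
#' @param taus optional quantile levels carried into the report.
#' @return object of class `noneq_report` with fields `lam`, `alpha`,
#'   `ratios`, `ci_low`, `ci_high`, `flags`, `n_flagged`, `taus`.
#' @export
non_equivalence_test <- function(ratios, ratio_se, lam = 1.2, alpha = 0.10,
                                 taus = NULL) {
  if (lam <= 1) stop("equivalence-band parameter lam must exceed 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(ratio_se < 0)) stop("ratio_se must be nonnegative")
  if (length(ratios) != length(ratio_se)) stop("ratios/ratio_se length mismatch")
  z <- ci_z(alpha)
  ci_low <- ratios - z * ratio_se
  ci_high <- ratios + z * ratio_se
  flags <- (ci_high < 1 / lam) | (ci_low > lam)
  structure(
    list(
      lam = lam, alpha = alpha,
      ratios = as.numeric(ratios),
      ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
      flags = as.logical(flags), n_flagged = sum(flags),
      taus = taus
    ),
    class = "noneq_report"
  )
}

#' @export
print.noneq_report <- function(x, ...) {
  cat(
    "<noneq_report> lambda =", x$lam, ", alpha =", x$alpha, ":",
    x$n_flagged, "of", length(x$flags), "quantiles flagged\n"
  )
  invisible(x)
}

#' Flag counts over a ladder of equivalence bands
#'
#' Runs [non_equivalence_test()] at each lambda in `lam_list`; the bands
#' are nested, so flag counts are non-increasing in lambda.
#'
#' @param profile an `effect_profile`.
#' @param boot a matching `bootstrap_covariance`.
#' @param lam_list lambda ladder (default 1.05, 1.1, 1.2, 1.5, 2).
#' @param alpha test level (default 0.10).
#' @param z_threshold passed to [ratio_profile()].
#' @return list with `table` (data.frame lambda, n_flagged) and `reports`
#'   (named list of `noneq_report`s).
#' @export
count_flags_over_lambdas <- function(profile, boot,
                                     lam_list = c(1.05, 1.1, 1.2, 1.5, 2),
                                     alpha = 0.10, z_threshold = 4) {
  if (any(lam_list <= 1)) stop("all lambda values must exceed 1")
  rp <- ratio_profile(profile, boot, z_threshold = z_threshold)
  reports <- lapply(lam_list, function(lam) {
    non_equivalence_test(rp$ratios, rp$ratio_se,
      lam = lam, alpha = alpha,
      taus = profile$grid$taus
    )
  })
  names(reports) <- as.character(lam_list)
  list(
    table = data.frame(
      lambda = lam_list,
      n_flagged = vapply(reports, function(r) r$n_flagged, integer(1))
    ),
    reports = reports
  )
}

# z-quantile of the (1 - alpha/2) two-sided CI used by the level-alpha
# minimum-effects test (alpha = 0.10 -> the 95% CI, z = 1.959964)
ci_z <- function(alpha) stats::qnorm(1 - alpha / 4)

# generalized least squares of beta on design X with error covariance
# Sigma; returns coefficients, their covariance, and the GLS deviance
# (residual quadratic form), ridging Sigma if it is numerically singular
gls_fit <- function(beta, X, Sigma) {
  K <- length(beta)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular bootstrap covariance; applying diagonal ridge")
    Sigma <- Sigma + diag(1e-8 * sum(diag(Sigma)) / K, K)
    ch <- tryCatch(chol(Sigma), error = function(e) {
      stop("bootstrap covariance singular even after ridge stabilization")
    })
  }
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, beta, transpose = TRUE)
  XtX <- crossprod(Xi)
  coefs <- solve(XtX, crossprod(Xi, yi))
  vcov <- solve(XtX)
  resid <- yi - Xi %*% coefs
  list(
    coef = as.numeric(coefs), vcov = vcov,
    deviance = as.numeric(crossprod(resid))
  )
}

#' Linear and quadratic trend tests on the quantile effect profile
#'
#' Generalized-least-squares meta-regressions of the quantile-specific
#' effects on `[1, tau]` and `[1, tau, tau^2]`, using the bootstrap
#' covariance of the effects as the (fixed, known) error covariance.  The
#' linear p-value is a two-sided Wald test on the tau slope, the quadratic
#' joint p-value a Wald chi-square on (tau, tau^2), and `lrt_p` a
#' chi-square(1) likelihood-ratio comparison of the quadratic versus
#' linear fits via their GLS deviances.
#'
#' @param profile an `effect_profile`.
#' @param boot a matching `bootstrap_covariance`.
#' @return object of class `trend_report`: `linear` (slope, slope_se, p),
#'   `quadratic` (coef_tau, coef_tau2, p_joint), `lrt_p`.
#' @export
trend_tests <- function(profile, boot) {
  stopifnot(
    inherits(profile, "effect_profile"),
    inherits(boot, "bootstrap_covariance")
  )
  if (!isTRUE(all.equal(profile$grid$taus, boot$grid$taus))) {
    stop("profile and bootstrap quantile grids differ")
  }
  taus <- profile$grid$taus
  beta <- profile$beta_tau
  Sigma <- boot$cov[-1L, -1L, drop = FALSE]

  lin <- gls_fit(beta, cbind(1, taus), Sigma)
  quad <- gls_fit(beta, cbind(1, taus, taus^2), Sigma)

  slope <- lin$coef[2L]
  slope_se <- sqrt(lin$vcov[2L, 2L])
  p_lin <- 2 * stats::pnorm(-abs(slope / slope_se))

  cq <- quad$coef[2:3]
  Vq <- quad$vcov[2:3, 2:3]
  wald_q <- as.numeric(t(cq) %*% solve(Vq, cq))
  p_joint <- stats::pchisq(wald_q, df = 2, lower.tail = FALSE)

  lrt_stat <- max(lin$deviance - quad$deviance, 0)
  lrt_p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)

  structure(
    list(
      linear = list(slope = slope, slope_se = slope_se, p = p_lin),
      quadratic = list(
        coef_tau = cq[1L], coef_tau2 = cq[2L],
        p_joint = p_joint
      ),
      lrt_stat = lrt_stat,
      lrt_p = lrt_p
    ),
    class = "trend_report"
  )
}

#' @export
print.trend_report <- function(x, ...) {
  cat(
    "<trend_report> linear slope =", format(x$linear$slope, digits = 4),
    "(p =", format(x$linear$p, digits = 3),
    "); quadratic-vs-linear LRT p =", format(x$lrt_p, digits = 3), "\n"
  )
  invisible(x)
}

#' Crossing quantile of the effect profile
#'
#' Locates where the quantile-specific effect curve crosses the OLS
#' effect.  Under a coordinated gene-by-environment interaction with a
#' dichotomous exposure carrying a main effect, the crossing quantile
#' approximates the exposure prevalence (or its complement), making it an
#' interpretive clue to an unmeasured stratifying exposure.  When several
#' sign changes exist, the dominant one -- the crossing flanked by the
#' largest total |beta_tau - beta_ols| mass over the adjacent
#' constant-sign runs -- is reported.  Profiles that are essentially flat
#' (max |ratio - 1| < `flat_tol`) report no crossing.
#'
#' @param profile an `effect_profile`.
#' @param flat_tol flatness guard on the ratio scale (default 0.05).
#' @return list with `tau_cross` (interpolated quantile, or `NA`) and
#'   `direction` (`"rising"`, `"falling"`, or `"none"`).
#' @export
crossing_quantile <- function(profile, flat_tol = 0.05) {
  stopifnot(inherits(profile, "effect_profile"))
  taus <- profile$grid$taus
  d <- profile$beta_tau - profile$beta_ols
  none <- list(tau_cross = NA_real_, direction = "none")
  if (profile$beta_ols != 0 &&
    max(abs(profile$beta_tau / profile$beta_ols - 1)) < flat_tol) {
    return(none)
  }
  s <- sign(d)
  cross_at <- which(s[-length(s)] * s[-1L] < 0)
  exact <- which(s == 0)
  if (length(cross_at) == 0L && length(exact) == 0L) {
    return(none)
  }

  # |d| mass of the maximal constant-sign runs flanking each crossing
  run_id <- cumsum(c(1L, diff(s) != 0))
  run_mass <- tapply(abs(d), run_id, sum)
  score <- function(k) run_mass[[run_id[k]]] + run_mass[[run_id[k + 1L]]]

  if (length(cross_at) > 0L) {
    k <- cross_at[which.max(vapply(cross_at, score, numeric(1)))]
    frac <- d[k] / (d[k] - d[k + 1L])
    tau_cross <- taus[k] + frac * (taus[k + 1L] - taus[k])
    direction <- if (d[k] < 0) "rising" else "falling"
  } else {
    k <- exact[1L]
    tau_cross <- taus[k]
    direction <- if (k > 1L && d[k - 1L] < 0) "rising" else "falling"
  }
  list(tau_cross = as.numeric(tau_cross), direction = direction)
}
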