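#' Screening configuration
#'
#' Default settings reproduce the reference analysis: the 19-point
#' quantile grid 0.05..0.95, equivalence-band ladder
#' lambda = 1.05, 1.1, 1.2, 1.5, 2 with primary lambda 1.2, test level
#' alpha = 0.10 (95% ratio CIs), m-of-n bootstrap with m = min(10000, n)
#' and B = 200 replicates.
#'
#' @param tau_start,tau_stop,tau_step quantile grid specification.
#' @param lam_list equivalence-band ladder.
#' @param lambda primary lambda for the flat per-quantile report.
#' @param alpha non-equivalence test level.
#' @param boot_m bootstrap resample size; `NULL` means [default_m()].
#' @param boot_B bootstrap replicate count.
#' @param seed integer seed for the bootstrap.
#' @param z_threshold OLS-significance gate for ratio formation.
#' @param max_distinct,max_tie_fraction suitability thresholds, see
#'   [check_trait_suitability()].
#' @return list of class `screen_config`.
#' @export
screen_config <- function(tau_start = 0.05, tau_stop = 0.95, tau_step = 0.05,
                          lam_list = c(1.05, 1.1, 1.2, 1.5, 2), lambda = 1.2,
                          alpha = 0.10, boot_m = NULL, boot_B = 200L,
                          seed = 1L, z_threshold = 4, max_distinct = 20,
                          max_tie_fraction = 0.10) {
  if (!lambda %in% lam_list) lam_list <- sort(c(lam_list, lambda))
  structure(
    list(
      taus = seq(tau_start, tau_stop, by = tau_step),
      lam_list = lam_list, lambda = lambda, alpha = alpha,
      boot_m = boot_m, boot_B = as.integer(boot_B), seed = as.integer(seed),
      z_threshold = z_threshold, max_distinct = max_distinct,
      max_tie_fraction = max_tie_fraction
    ),
    class = "screen_config"
  )
}

#' Screen a cohort for quantile-specific heterogeneity of PGS effects
#'
#' The full pipeline: trait-suitability diagnostics, covariate
#' residualization, OLS + quantile-regression effect profile, m-of-n
#' bootstrap covariance, ratio confidence intervals and non-equivalence
#' tests over the lambda ladder, linear/quadratic trend meta-regressions,
#' and the crossing-quantile summary.
#'
#' @param cohort a [cohort_table()].
#' @param covariate_names covariates to project out (default: all stored).
#' @param config a [screen_config()].
#' @param quiet suppress stage-level log messages.
#' @return object of class `screen_report`.
#' @export
screen_cohort <- function(cohort, covariate_names = colnames(cohort$covariates),
                          config = screen_config(), quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "screen_config"))
  log_stage <- function(...) if (!quiet) message("screen: ", ...)

  suit <- check_trait_suitability(
    cohort,
    max_distinct = config$max_distinct,
    max_tie_fraction = config$max_tie_fraction
  )
  if (suit$verdict != "ok") {
    warning(
      "trait suitability verdict '", suit$verdict, "' (", suit$n_distinct,
      " distinct values); quantile-regression results may be uninformative"
    )
  }

  log_stage("residualizing ", cohort$n, " rows on ",
    length(covariate_names %||% character(0)), " covariate(s)")
  pair <- residualize(cohort, covariate_names %||% character(0))

  grid <- quantile_grid(config$taus)
  log_stage("fitting OLS + QR profile over ", grid$K, " quantiles")
  profile <- fit_profile(pair, grid)

  m <- config$boot_m %||% default_m(pair$n)
  log_stage("m-of-n bootstrap: m = ", m, ", B = ", config$boot_B)
  boot <- mofn_bootstrap(pair, grid,
    m = m, B = config$boot_B,
    seed = config$seed
  )

  log_stage("non-equivalence tests over lambda ladder")
  flags <- count_flags_over_lambdas(profile, boot,
    lam_list = config$lam_list, alpha = config$alpha,
    z_threshold = config$z_threshold
  )
  rp <- ratio_profile(profile, boot, z_threshold = config$z_threshold)

  log_stage("trend tests and crossing quantile")
  trend <- trend_tests(profile, boot)
  crossing <- crossing_quantile(profile)

  structure(
    list(
      n = cohort$n,
      suitability = suit,
      profile = profile,
      boot = boot,
      ratios = rp$ratios,
      noneq = flags$reports,
      flag_table = flags$table,
      trend = trend,
      crossing = crossing,
      config = unclass(config)
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> n =", x$n, "| beta_ols =",
    format(x$profile$beta_ols, digits = 4), "\n")
  cat("  suitability:", x$suitability$verdict, "\n")
  cat("  flags per lambda:\n")
  print(x$flag_table, row.names = FALSE)
  cat(
    "  linear trend p =", format(x$trend$linear$p, digits = 3),
    "| quadratic-vs-linear LRT p =", format(x$trend$lrt_p, digits = 3), "\n"
  )
  cat(
    "  crossing quantile:",
    if (is.na(x$crossing$tau_cross)) "none" else
      paste0(format(x$crossing$tau_cross, digits = 3), " (", x$crossing$direction, ")"),
    "\n"
  )
  invisible(x)
}

#' File-level screening workflow
#'
#' Reads a cohort table, runs [screen_cohort()], and writes the JSON + TSV
#' report (and optionally the profile plot).
#'
#' @param cohort_path delimited text file, see [read_cohort()].
#' @param column_spec column mapping, see [read_cohort()].
#' @param config a [screen_config()].
#' @param out_prefix output path prefix; `NULL` skips writing.
#' @param plot also write `<out_prefix>_profile.png`.
#' @param quiet suppress log messages.
#' @return the `screen_report`, invisibly.
#' @export
pgs_screen <- function(cohort_path, column_spec, config = screen_config(),
                       out_prefix = NULL, plot = FALSE, quiet = FALSE) {
  cohort <- read_cohort(cohort_path, column_spec, quiet = quiet)
  report <- screen_cohort(cohort,
    covariate_names = column_spec$covariates %||% character(0),
    config = config, quiet = quiet
  )
  if (!is.null(out_prefix)) {
    write_report(report, out_prefix)
    if (plot) plot_profile(report, paste0(out_prefix, "_profile.png"))
  }
  invisible(report)
}

#' File-level simulation workflow
#'
#' Runs [run_scenario()] and writes the held-out cohort as TSV plus a JSON
#' provenance file; optionally screens the written cohort immediately.
#'
#' @param preset scenario name, see [scenario_names()].
#' @param seed integer seed.
#' @param out_prefix output path prefix.
#' @param overrides named list of [sim_params()] overrides.
#' @param adjust_exposure,stratify passed to [run_scenario()].
#' @param screen_after run [pgs_screen()] on the written cohort.
#' @param config screening configuration used when `screen_after`.
#' @param quiet suppress log messages.
#' @return list with the scenario result and (if requested) the report.
#' @export
pgs_simulate <- function(preset, seed = 1L, out_prefix, overrides = list(),
                         adjust_exposure = FALSE, stratify = "none",
                         screen_after = FALSE, config = screen_config(),
                         quiet = FALSE) {
  res <- run_scenario(preset,
    seed = seed, overrides = overrides,
    adjust_exposure = adjust_exposure, stratify = stratify
  )
  cohort_path <- paste0(out_prefix, "_cohort.tsv")
  write_cohort_tsv(res$cohort, cohort_path)
  jsonlite::write_json(
    res$provenance, paste0(out_prefix, "_provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  report <- NULL
  if (screen_after) {
    covars <- colnames(res$cohort$covariates)
    report <- pgs_screen(
      cohort_path,
      column_spec = list(
        phenotype = "phenotype", pgs = "pgs", covariates = covars,
        id = "sample_id"
      ),
      config = config, out_prefix = paste0(out_prefix, "_screen"),
      quiet = quiet
    )
  }
  invisible(list(scenario = res, report = report))
}

#' Two-panel effect-profile plot
#'
#' Left: quantile-specific effects with confidence intervals against the
#' OLS band.  Right: ratios with confidence intervals against the
#' equivalence band `(1/lambda, lambda)`; flagged quantiles are drawn in
#' red.
#'
#' @param report a `screen_report`.
#' @param path output image path (PNG).
#' @param lambda band to display; defaults to the report's primary lambda.
#' @return invisibly, the path.
#' @export
plot_profile <- function(report, path, lambda = report$config$lambda) {
  stopifnot(inherits(report, "screen_report"))
  prof <- report$profile
  taus <- prof$grid$taus
  noneq <- report$noneq[[as.character(lambda)]]
  if (is.null(noneq)) {
    rp <- list(ratios = report$ratios, ratio_se = report$boot$ratio_se)
    noneq <- non_equivalence_test(rp$ratios, rp$ratio_se,
      lam = lambda,
      alpha = report$config$alpha, taus = taus
    )
  }
  z <- ci_z(report$config$alpha)
  beta_se <- report$boot$beta_se[-1L]
  ols_se <- report$boot$beta_se[1L]
  cols <- ifelse(noneq$flags, "red", "black")

  grDevices::png(path, width = 1400, height = 600, res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))

  ylim <- range(
    prof$beta_tau - z * beta_se, prof$beta_tau + z * beta_se,
    prof$beta_ols
  )
  graphics::plot(taus, prof$beta_tau,
    pch = 19, col = cols, ylim = ylim,
    xlab = expression(tau), ylab = expression(hat(beta)[tau]),
    main = "Quantile-specific effect sizes"
  )
  graphics::abline(h = prof$beta_ols, col = "grey40")
  graphics::abline(h = prof$beta_ols + c(-z, z) * ols_se, col = "grey60", lty = 2)
  graphics::segments(taus, prof$beta_tau - z * beta_se,
    taus, prof$beta_tau + z * beta_se,
    col = cols
  )

  ylim2 <- range(noneq$ci_low, noneq$ci_high, 1 / lambda, lambda)
  graphics::plot(taus, noneq$ratios,
    pch = 19, col = cols, ylim = ylim2,
    xlab = expression(tau), ylab = expression(hat(beta)[tau] / hat(beta)[OLS]),
    main = sprintf("Ratios vs equivalence band (1/%.2f, %.2f)", lambda, lambda)
  )
  graphics::abline(h = c(1 / lambda, lambda), col = "grey40")
  graphics::abline(h = 1, col = "grey80", lty = 3)
  graphics::segments(taus, noneq$ci_low, taus, noneq$ci_high, col = cols)

  invisible(path)
}
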