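#' Simulation parameters for the gene-by-environment cohort generator
#'
#' The generating model is
#' `y = C alpha + beta_scale * G + gamma * E + delta * (G * E) + eps`
#' with `G = X beta` an aggregate genetic factor from standardized
#' independent SNPs, `E` a dichotomous exposure, and `eps` Gaussian noise.
#' The common covariate effect `alpha` is calibrated in closed form so
#' that `Var(C alpha) / Var(y)` equals `covariate_var_frac`.
#'
#' @param n_total cohort size before the two-half split (default 40,000).
#' @param n_snps number of independent SNPs (default 2,000).
#' @param frac_causal fraction of SNPs with nonzero effects (default 0.10).
#' @param sigma_g2 genetic variance of `G` (default 0.3).
#' @param sigma_eps2 noise variance (default 0.4).
#' @param n_covariates number of standard-normal covariates (default 10).
#' @param covariate_var_frac target share of `Var(y)` from `C alpha`
#'   (default 0.30).
#' @param pr_e exposure probability in `[0, 1]` (default 0.25).
#' @param gamma environmental main effect (default 0).
#' @param delta coordinated gene-by-environment effect (default 0).
#' @param beta_scale multiplier on the genetic factor `G` (default 1).
#' @param maf_low,maf_high minor-allele-frequency range (defaults 0.05, 0.5).
#' @param pgs_pval_threshold GWAS p-value threshold for score construction
#'   (default 1e-4).
#' @param seed integer seed.
#' @return validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_total = 40000L, n_snps = 2000L, frac_causal = 0.10,
                       sigma_g2 = 0.3, sigma_eps2 = 0.4, n_covariates = 10L,
                       covariate_var_frac = 0.30, pr_e = 0.25, gamma = 0,
                       delta = 0, beta_scale = 1, maf_low = 0.05,
                       maf_high = 0.5, pgs_pval_threshold = 1e-4, seed = 1L) {
  p <- list(
    n_total = as.integer(n_total), n_snps = as.integer(n_snps),
    frac_causal = frac_causal, sigma_g2 = sigma_g2, sigma_eps2 = sigma_eps2,
    n_covariates = as.integer(n_covariates),
    covariate_var_frac = covariate_var_frac, pr_e = pr_e, gamma = gamma,
    delta = delta, beta_scale = beta_scale, maf_low = maf_low,
    maf_high = maf_high, pgs_pval_threshold = pgs_pval_threshold,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_total >= 2L, p$n_snps >= 1L,
    p$frac_causal >= 0, p$frac_causal <= 1,
    p$sigma_g2 >= 0, p$sigma_eps2 > 0,
    p$n_covariates >= 0L,
    p$covariate_var_frac >= 0, p$covariate_var_frac < 1,
    p$pr_e >= 0, p$pr_e <= 1,
    p$maf_low > 0, p$maf_low <= p$maf_high, p$maf_high <= 0.5,
    p$pgs_pval_threshold > 0, p$pgs_pval_threshold <= 1
  )
  mc <- round(p$n_snps * p$frac_causal)
  if (mc == 0 && p$sigma_g2 > 0) {
    stop("no causal SNPs (n_snps * frac_causal rounds to 0) with sigma_g2 > 0")
  }
  p$mc <- as.integer(mc)
  structure(p, class = "sim_params")
}

# closed-form common covariate effect size: Var(C alpha) = k * a^2 must be
# covariate_var_frac / (1 - covariate_var_frac) times the variance of the
# non-covariate terms V_rest
covariate_effect <- function(p) {
  if (p$n_covariates == 0L || p$covariate_var_frac == 0) {
    return(0)
  }
  v_rest <- p$beta_scale^2 * p$sigma_g2 +
    p$gamma^2 * p$pr_e * (1 - p$pr_e) +
    p$delta^2 * p$sigma_g2 * p$pr_e +
    2 * p$beta_scale * p$delta * p$sigma_g2 * p$pr_e +
    p$sigma_eps2
  sqrt(p$covariate_var_frac * v_rest /
    ((1 - p$covariate_var_frac) * p$n_covariates))
}

#' Simulate a gene-by-environment cohort
#'
#' Minor-allele frequencies are uniform on `[maf_low, maf_high]`;
#' genotypes are Binomial(2, maf) and column-standardized to the realized
#' sample mean/SD.  A random `mc = round(n_snps * frac_causal)` subset of
#' SNPs carries effects `N(0, sigma_g2 / mc)`; the rest are zero.  The
#' trait is assembled exactly per the generating model and the noise draw
#' is stored so the reconstruction identity holds to machine precision.
#'
#' @param params a [sim_params()].
#' @return object of class `simulated_cohort` with fields `X`, `C`, `E`,
#'   `G`, `y`, `beta_true`, `alpha_true`, `eps`, `maf`, `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, simulate_cohort_impl(params))
}

# the body, run inside an established RNG stream (so two-half designs can
# share MAFs/effects while drawing fresh individuals)
simulate_cohort_impl <- function(params, maf = NULL, beta_true = NULL,
                                 n = NULL) {
  p <- params
  n <- n %||% p$n_total
  if (is.null(maf)) maf <- runif(p$n_snps, p$maf_low, p$maf_high)

  X <- matrix(
    rbinom(n * p$n_snps, 2L, rep(maf, each = n)),
    nrow = n, ncol = p$n_snps
  )
  storage.mode(X) <- "double"
  repeat {
    sds <- matrixStats_colSds(X)
    bad <- which(sds == 0)
    if (length(bad) == 0L) break
    X[, bad] <- rbinom(n * length(bad), 2L, rep(maf[bad], each = n))
  }
  X <- sweep(X, 2L, colMeans(X), "-")
  X <- sweep(X, 2L, sds, "/")

  if (is.null(beta_true)) {
    beta_true <- numeric(p$n_snps)
    if (p$mc > 0L && p$sigma_g2 > 0) {
      causal <- sample.int(p$n_snps, p$mc)
      beta_true[causal] <- rnorm(p$mc, 0, sqrt(p$sigma_g2 / p$mc))
    }
  }
  G <- as.numeric(X %*% beta_true)

  C <- if (p$n_covariates > 0L) {
    matrix(rnorm(n * p$n_covariates), n, p$n_covariates,
      dimnames = list(NULL, paste0("cov", seq_len(p$n_covariates)))
    )
  } else {
    NULL
  }
  a <- covariate_effect(p)
  alpha_true <- rep(a, p$n_covariates)
  E <- rbinom(n, 1L, p$pr_e)
  eps <- rnorm(n, 0, sqrt(p$sigma_eps2))

  y <- p$beta_scale * G + p$gamma * E + p$delta * (G * E) + eps
  if (!is.null(C)) y <- y + as.numeric(C %*% alpha_true)

  structure(
    list(
      X = X, C = C, E = E, G = G, y = y,
      beta_true = beta_true, alpha_true = alpha_true, eps = eps,
      maf = maf, params = p
    ),
    class = "simulated_cohort"
  )
}

# column SDs without extra copies (denominator n-1, as used for
# genotype standardization)
matrixStats_colSds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - mu^2, 0) * n / (n - 1))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(
    "<simulated_cohort> n =", length(x$y), ",", ncol(x$X), "SNPs (",
    sum(x$beta_true != 0), "causal ), PrE =", x$params$pr_e, "\n"
  )
  invisible(x)
}

#' Covariate-adjusted per-SNP association scan
#'
#' Per-SNP least squares of `y` on `[1, SNP, C]` (optionally also the
#' exposure), computed by residualizing `y` and every SNP on the covariate
#' block (Frisch-Waugh-Lovell), which reproduces the full-model slope,
#' standard error and two-sided t-test exactly.
#'
#' @param cohort a `simulated_cohort`.
#' @param adjust_exposure include the exposure `E` as a GWAS covariate.
#' @return data.frame of class `gwas_result` with columns `slope`, `se`,
#'   `p` (one row per SNP).
#' @export
run_gwas <- function(cohort, adjust_exposure = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  n <- length(cohort$y)
  Z <- cbind(rep(1, n), cohort$C)
  if (adjust_exposure) Z <- cbind(Z, cohort$E)
  pcov <- ncol(Z)
  if (n <= pcov + 1L) stop("too few observations for the GWAS design")

  qz <- qr(Z)
  y_res <- qr.resid(qz, cohort$y)
  X_res <- qr.resid(qz, cohort$X)

  sxx <- colSums(X_res^2)
  sxy <- as.numeric(crossprod(X_res, y_res))
  slope <- sxy / sxx
  df <- n - pcov - 1L
  rss <- sum(y_res^2) - slope^2 * sxx
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = df)

  structure(
    data.frame(slope = slope, se = se, p = p),
    class = c("gwas_result", "data.frame")
  )
}

#' Build polygenic-score weights by p-value thresholding
#'
#' @param gwas a `gwas_result` from [run_gwas()].
#' @param threshold inclusion threshold on the per-SNP p-value
#'   (default 1e-4).
#' @return object of class `pgs_weights`: `snp_indices`, `weights`
#'   (the selected slope estimates), `threshold`.
#' @export
build_pgs <- function(gwas, threshold = 1e-4) {
  stopifnot(inherits(gwas, "gwas_result"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  idx <- which(gwas$p < threshold)
  if (length(idx) == 0L) {
    warning("no SNPs pass the p-value threshold; score weights are empty")
  }
  structure(
    list(
      snp_indices = idx, weights = gwas$slope[idx],
      threshold = threshold
    ),
    class = "pgs_weights"
  )
}

#' Score individuals with polygenic-score weights
#'
#' @param X standardized genotype matrix.
#' @param weights a `pgs_weights`.
#' @return numeric score vector `X[, indices] %*% weights`.
#' @export
score_pgs <- function(X, weights) {
  stopifnot(inherits(weights, "pgs_weights"))
  if (length(weights$snp_indices) == 0L) {
    stop("empty score weights give a zero-variance PGS")
  }
  if (max(weights$snp_indices) > ncol(X)) {
    stop("weight indices exceed the genotype matrix column count")
  }
  as.numeric(X[, weights$snp_indices, drop = FALSE] %*% weights$weights)
}

#' Dichotomize a continuous liability into case-control status
#'
#' The `ceiling(top_fraction * n)` largest values become cases (1); ties
#' at the threshold are broken by stable index order.
#'
#' @param y numeric liability vector.
#' @param top_fraction fraction of cases in (0, 1).
#' @return integer 0/1 vector.
#' @export
dichotomize_liability <- function(y, top_fraction) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must lie in (0, 1)")
  }
  n <- length(y)
  k <- ceiling(top_fraction * n)
  out <- integer(n)
  out[order(-y, seq_len(n))[seq_len(k)]] <- 1L
  out
}

scenario_presets <- list(
  fig4_AB = list(beta_scale = 1, gamma = 0, delta = 0, pr_e = 0.25),
  fig4_CD = list(beta_scale = 1, gamma = 1, delta = 0, pr_e = 0.25),
  fig4_EF = list(beta_scale = 1, gamma = 0, delta = 1, pr_e = 0.25),
  fig4_GH = list(beta_scale = 1, gamma = 1, delta = 1, pr_e = 0.25),
  fig4_IJ = list(beta_scale = 1, gamma = 1, delta = 1, pr_e = 0.50),
  fig4_KL = list(beta_scale = 1, gamma = 1, delta = 1, pr_e = 0.75),
  fig4_MN = list(beta_scale = 1, gamma = 1, delta = -1, pr_e = 0.25),
  fig4_OP = list(
    beta_scale = 1, gamma = 1, delta = 1, pr_e = 0.25,
    dichotomize_top = 0.30
  ),
  fig5 = list(beta_scale = 0.5, gamma = 1, delta = 1, pr_e = 0.25)
)

#' Scenario presets for the two-half simulation design
#'
#' @return named list of preset parameter overrides.
#' @export
scenario_names <- function() names(scenario_presets)

#' Run a two-half simulation scenario
#'
#' Generates `n_total` individuals sharing one set of minor-allele
#' frequencies and true effects, splits them into two equal halves, runs
#' the covariate-adjusted GWAS and p-value-threshold score construction on
#' the first half, scores the second half, and returns the held-out half
#' as a screen-ready [cohort_table()] (phenotype, pgs, covariates, with
#' the exposure carried as an extra column).
#'
#' @param preset one of [scenario_names()].
#' @param seed integer seed.
#' @param overrides named list of [sim_params()] overrides (e.g.
#'   `list(n_total = 8000)` for a reduced run).
#' @param adjust_exposure include the exposure as a covariate in the GWAS
#'   and carry it into the screen's covariate set.
#' @param stratify `"none"`, `"exposed"`, or `"unexposed"`: restrict both
#'   halves to one exposure stratum for GWAS, score and screen.
#' @return list with `cohort` (held-out [cohort_table()]), `weights`
#'   (`pgs_weights`), and `provenance` (parameters, seed, counts).
#' @export
run_scenario <- function(preset, seed = 1L, overrides = list(),
                         adjust_exposure = FALSE,
                         stratify = c("none", "exposed", "unexposed")) {
  stratify <- match.arg(stratify)
  if (!preset %in% names(scenario_presets)) {
    stop(
      "unknown preset '", preset, "'; available: ",
      paste(names(scenario_presets), collapse = ", ")
    )
  }
  spec <- scenario_presets[[preset]]
  dichotomize_top <- spec$dichotomize_top
  spec$dichotomize_top <- NULL
  args <- utils::modifyList(spec, overrides)
  args$seed <- as.integer(seed)
  params <- do.call(sim_params, args)

  sim <- simulate_cohort(params)
  n <- params$n_total
  half1 <- seq_len(n %/% 2L)
  half2 <- setdiff(seq_len(n), half1)

  subset_sim <- function(sim, idx) {
    out <- sim
    out$X <- sim$X[idx, , drop = FALSE]
    out$C <- if (!is.null(sim$C)) sim$C[idx, , drop = FALSE] else NULL
    out$E <- sim$E[idx]
    out$G <- sim$G[idx]
    out$y <- sim$y[idx]
    out$eps <- sim$eps[idx]
    out
  }
  sim1 <- subset_sim(sim, half1)
  sim2 <- subset_sim(sim, half2)

  if (stratify != "none") {
    keep1 <- which(sim1$E == (stratify == "exposed"))
    keep2 <- which(sim2$E == (stratify == "exposed"))
    sim1 <- subset_sim(sim1, keep1)
    sim2 <- subset_sim(sim2, keep2)
  }

  gwas <- run_gwas(sim1, adjust_exposure = adjust_exposure)
  weights <- build_pgs(gwas, params$pgs_pval_threshold)
  pgs <- score_pgs(sim2$X, weights)

  phenotype <- sim2$y
  if (!is.null(dichotomize_top)) {
    phenotype <- dichotomize_liability(phenotype, dichotomize_top)
  }

  covariates <- sim2$C
  if (adjust_exposure) {
    covariates <- cbind(covariates, exposure = sim2$E)
  }
  cohort <- cohort_table(
    phenotype = phenotype, pgs = pgs, covariates = covariates,
    exposure = sim2$E
  )

  list(
    cohort = cohort,
    weights = weights,
    provenance = list(
      preset = preset, seed = as.integer(seed),
      params = unclass(params),
      adjust_exposure = adjust_exposure, stratify = stratify,
      dichotomize_top = dichotomize_top,
      n_gwas = length(sim1$y), n_screen = length(sim2$y),
      n_snps_selected = length(weights$snp_indices)
    )
  )
}

#' Write a cohort table as TSV
#'
#' Columns: sample_id, phenotype, pgs, one column per covariate, and the
#' exposure if present.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- data.frame(
    sample_id = cohort$sample_id,
    phenotype = cohort$phenotype,
    pgs = cohort$pgs
  )
  if (!is.null(cohort$covariates)) df <- cbind(df, cohort$covariates)
  if (!is.null(cohort$exposure)) df$exposure <- cohort$exposure
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
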