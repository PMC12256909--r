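small_params <- function(seed = 1, ...) {
  sim_params(n_total = 2000, n_snps = 400, seed = seed, ...)
}

test_that("simulated cohorts satisfy the reconstruction identity exactly", {
  for (seed in 1:3) {
    p <- small_params(seed = seed, gamma = 1, delta = 0.5)
    sim <- simulate_cohort(p)
    y_rebuilt <- as.numeric(sim$C %*% sim$alpha_true) +
      p$beta_scale * sim$G + p$gamma * sim$E + p$delta * (sim$G * sim$E) +
      sim$eps
    expect_equal(sim$y, y_rebuilt, tolerance = 1e-12)
    expect_equal(sim$G, as.numeric(sim$X %*% sim$beta_true), tolerance = 1e-12)
    expect_equal(sum(sim$beta_true != 0), p$mc)
    expect_equal(p$mc, round(p$n_snps * p$frac_causal))
  }
})

test_that("genotype columns are standardized and cohorts reproducible", {
  sim <- simulate_cohort(small_params(seed = 4))
  expect_lt(max(abs(colMeans(sim$X))), 1e-10)
  cv <- apply(sim$X[, 1:50], 2, var)
  expect_equal(unname(cv), rep(1, 50), tolerance = 1e-8)

  sim2 <- simulate_cohort(small_params(seed = 4))
  expect_identical(sim$y, sim2$y)
  expect_identical(sim$X[1:5, 1:5], sim2$X[1:5, 1:5])
})

test_that("variance calibration matches the generating-model targets", {
  r2 <- vg <- numeric(6)
  for (s in 1:6) {
    sim <- simulate_cohort(sim_params(
      n_total = 2000, seed = s,
      gamma = 1, delta = 1
    ))
    vg[s] <- var(sim$G)
    r2[s] <- summary(lm(sim$y ~ sim$C))$r.squared
  }
  expect_lt(abs(mean(vg) - 0.3) / 0.3, 0.10)
  se_r2 <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 0.30), 3 * se_r2 + 0.01)
})

test_that("null exposure leaves the trait independent of E", {
  sim <- simulate_cohort(small_params(seed = 6, gamma = 0, delta = 0))
  expect_lt(abs(cor(sim$y, sim$E)), 3 / sqrt(length(sim$y)))
})

test_that("run_gwas matches per-SNP least squares with covariates", {
  p <- sim_params(n_total = 200, n_snps = 20, n_covariates = 3, seed = 9)
  sim <- simulate_cohort(p)
  gwas <- run_gwas(sim)
  expect_equal(nrow(gwas), 20L)
  expect_true(all(gwas$p >= 0 & gwas$p <= 1))
  for (j in c(1, 7, 20)) {
    fit <- summary(lm(sim$y ~ sim$X[, j] + sim$C))
    expect_equal(gwas$slope[j], fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(gwas$se[j], fit$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(gwas$p[j], fit$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("single strong SNP dominates a toy GWAS", {
  set.seed(2)
  n <- 300
  x <- scale(rbinom(n, 2, 0.3))
  sim <- structure(
    list(
      X = cbind(x, scale(rbinom(n, 2, 0.4))), C = NULL, E = rep(0, n),
      y = as.numeric(5 * x + rnorm(n, 0, 0.1)), G = numeric(n),
      eps = numeric(n), beta_true = c(5, 0), alpha_true = numeric(0),
      params = small_params()
    ),
    class = "simulated_cohort"
  )
  gwas <- run_gwas(sim)
  expect_equal(gwas$slope[1], 5, tolerance = 0.05)
  expect_lt(gwas$p[1], 1e-10)
  w <- build_pgs(gwas, 1e-4)
  expect_identical(w$snp_indices, 1L)
  expect_equal(w$weights, gwas$slope[1])
})

test_that("null GWAS p-values are uniform and threshold selection is binomial", {
  sim <- simulate_cohort(sim_params(
    n_total = 1500, n_snps = 2000, sigma_g2 = 0,
    frac_causal = 0, seed = 10
  ))
  gwas <- run_gwas(sim)
  ks <- suppressWarnings(ks.test(gwas$p, "punif"))
  expect_lt(ks$statistic, 0.05)
  expect_gt(ks$p.value, 1e-4)
  # expected count at threshold t is ~ n_snps * t
  expect_lte(suppressWarnings(length(build_pgs(gwas, 1e-4)$snp_indices)), 4)
  expect_equal(length(build_pgs(gwas, 1.0)$snp_indices), 2000L)
})

test_that("score_pgs is the linear score and errors on empty weights", {
  sim <- simulate_cohort(small_params(seed = 3))
  w <- structure(
    list(snp_indices = 5L, weights = 1, threshold = 1e-4),
    class = "pgs_weights"
  )
  expect_equal(score_pgs(sim$X, w), sim$X[, 5])
  w2 <- w
  w2$weights <- 2
  expect_equal(score_pgs(sim$X, w2), 2 * score_pgs(sim$X, w))
  empty <- structure(
    list(snp_indices = integer(0), weights = numeric(0), threshold = 1e-4),
    class = "pgs_weights"
  )
  expect_error(score_pgs(sim$X, empty), "zero-variance")
})

test_that("held-out score correlation respects the heritability bound", {
  res <- run_scenario("fig4_AB", seed = 5, overrides = list(n_total = 4000))
  r <- cor(res$cohort$pgs, res$cohort$phenotype)
  expect_gt(r, 0.1)
  # attenuated below the true-G bound sqrt(sigma_g2 / Var(y))
  p <- res$provenance$params
  v_y <- (p$beta_scale^2 * p$sigma_g2 + p$sigma_eps2) / (1 - p$covariate_var_frac)
  expect_lt(r, sqrt(p$sigma_g2 / v_y))
})

test_that("dichotomize_liability thresholds the top fraction with stable ties", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(which(dichotomize_liability(y, 0.3) == 1), 8:10)
  expect_equal(sum(dichotomize_liability(rnorm(101), 0.5)), 51)
  # ties at the threshold: earlier index wins
  yt <- c(5, 3, 5, 1, 5)
  expect_equal(which(dichotomize_liability(yt, 0.4) == 1), c(1L, 3L))
  expect_error(dichotomize_liability(y, 0), "top_fraction")
  # prevalence within 1/n of the target
  z <- rnorm(337)
  expect_lt(abs(mean(dichotomize_liability(z, 0.3)) - 0.3), 1 / 337 + 1e-12)
})

test_that("run_scenario wires the two-half design and presets", {
  expect_error(run_scenario("nope"), "unknown preset")
  res <- run_scenario("fig4_GH", seed = 2, overrides = list(n_total = 3000, n_snps = 400))
  expect_s3_class(res$cohort, "cohort_table")
  expect_equal(res$cohort$n, 1500L)
  expect_equal(ncol(res$cohort$covariates), 10L)
  expect_false(is.null(res$cohort$exposure))
  expect_equal(res$provenance$params$gamma, 1)
  expect_equal(res$provenance$params$pr_e, 0.25)
  expect_equal(res$provenance$n_snps_selected, length(res$weights$snp_indices))

  # determinism: identical seed gives identical cohorts
  res2 <- run_scenario("fig4_GH", seed = 2, overrides = list(n_total = 3000, n_snps = 400))
  expect_identical(res$cohort$phenotype, res2$cohort$phenotype)
  expect_identical(res$cohort$pgs, res2$cohort$pgs)

  # overrides are recorded
  res3 <- run_scenario("fig4_IJ", seed = 1, overrides = list(n_total = 3000, n_snps = 400, pr_e = 0.6))
  expect_equal(res3$provenance$params$pr_e, 0.6)

  # dichotomized preset yields a binary phenotype at 30% prevalence
  res4 <- run_scenario("fig4_OP", seed = 1, overrides = list(n_total = 3000, n_snps = 400))
  expect_setequal(unique(res4$cohort$phenotype), c(0, 1))
  expect_equal(mean(res4$cohort$phenotype), 0.3, tolerance = 1e-3)

  # stratified runs only use one stratum
  res5 <- run_scenario("fig5", seed = 1,
    overrides = list(n_total = 3000, n_snps = 400), stratify = "exposed"
  )
  expect_true(all(res5$cohort$exposure == 1))
  expect_lt(res5$cohort$n, 600)
})
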