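# helper: hand-built profile/bootstrap pair for inferential-layer tests
fake_profile <- function(beta_tau, beta_ols, taus = seq(0.05, 0.95, 0.05),
                         n = 50000) {
  structure(
    list(
      beta_ols = beta_ols, beta_tau = beta_tau,
      intercept_tau = rep(0, length(taus)),
      objective_tau = rep(0, length(taus)),
      r2_ols = beta_ols^2, r2_tau = beta_tau^2,
      unstable_tau = rep(FALSE, length(taus)),
      grid = quantile_grid(taus), n = n
    ),
    class = "effect_profile"
  )
}

fake_boot <- function(Sigma, taus = seq(0.05, 0.95, 0.05), ratio_se = NULL,
                      beta_ols = 1) {
  K <- length(taus)
  cov <- matrix(0, K + 1, K + 1)
  cov[-1, -1] <- Sigma
  cov[1, 1] <- 1e-8
  structure(
    list(
      m = 1000L, n = 1000L, B = 200L, seed = 1L, cov = cov,
      beta_se = sqrt(diag(cov)),
      ratio_se = ratio_se %||% (sqrt(diag(Sigma)) / abs(beta_ols)),
      ratio_mean = rep(1, K), n_dropped_ratio = 0L,
      grid = quantile_grid(taus)
    ),
    class = "bootstrap_covariance"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ratio_profile forms point-estimate ratios behind the OLS gate", {
  taus <- seq(0.05, 0.95, 0.05)
  prof <- fake_profile(rep(0.35, 19), 0.35)
  boot <- fake_boot(diag(1e-4, 19), beta_ols = 0.35)
  rp <- ratio_profile(prof, boot)
  expect_equal(rp$ratios, rep(1, 19))

  # reference worked ratios: 0.60/0.35 and 0.51/0.55
  prof_bmi <- fake_profile(c(rep(0.35, 18), 0.60), 0.35)
  expect_equal(
    ratio_profile(prof_bmi, boot)$ratios[19], 0.60 / 0.35,
    tolerance = 1e-12
  )
  prof_height <- fake_profile(c(0.51, rep(0.55, 18)), 0.55)
  expect_equal(
    ratio_profile(prof_height, fake_boot(diag(1e-4, 19), beta_ols = 0.55))$ratios[1],
    0.51 / 0.55,
    tolerance = 1e-12
  )

  # gate: negative or nonsignificant OLS effect aborts
  expect_error(
    ratio_profile(fake_profile(rep(0.3, 19), -0.3), boot),
    "positive"
  )
  weak <- fake_profile(rep(0.01, 19), 0.01, n = 100)
  expect_error(ratio_profile(weak, boot), "significant")
  # grid mismatch
  boot_bad <- fake_boot(diag(1e-4, 3), taus = c(0.25, 0.5, 0.75))
  expect_error(ratio_profile(prof, boot_bad), "grids differ")
})

test_that("non-equivalence flags implement the CI-outside-band rule", {
  # inside band
  r1 <- non_equivalence_test(1.0, 0.01, lam = 1.2, alpha = 0.10)
  expect_false(r1$flags)
  # CI [1.402, 1.598] entirely above 1.2
  r2 <- non_equivalence_test(1.5, 0.05, lam = 1.2, alpha = 0.10)
  expect_true(r2$flags)
  expect_equal(r2$ci_low, 1.5 - qnorm(0.975) * 0.05, tolerance = 1e-12)
  expect_equal(r2$ci_high, 1.5 + qnorm(0.975) * 0.05, tolerance = 1e-12)
  # CI [1.152, 1.348] intersects the band -> not flagged
  r3 <- non_equivalence_test(1.25, 0.05, lam = 1.2, alpha = 0.10)
  expect_false(r3$flags)
  # low side
  r4 <- non_equivalence_test(0.6, 0.05, lam = 1.2, alpha = 0.10)
  expect_true(r4$flags)

  expect_error(non_equivalence_test(1, 0.1, lam = 1), "exceed 1")
  expect_error(non_equivalence_test(1, -0.1, lam = 1.2), "nonnegative")
})

test_that("flags equal the two one-sided tests and are monotone in lambda", {
  set.seed(5)
  for (rep in 1:50) {
    K <- 19
    ratios <- exp(rnorm(K, 0, 0.3))
    se <- runif(K, 0.01, 0.2)
    alpha <- 0.10
    z <- qnorm(1 - alpha / 4) # the (1 - alpha/2) two-sided CI quantile
    reports <- lapply(c(1.05, 1.2, 2), function(lam) {
      non_equivalence_test(ratios, se, lam = lam, alpha = alpha)
    })
    # TOST formulation: reject iff one-sided z-test at alpha/2 clears a bound
    for (rp in reports) {
      tost <- (ratios - rp$lam) / se > z | (ratios - 1 / rp$lam) / se < -z
      expect_identical(rp$flags, tost)
      expect_equal(rp$n_flagged, sum(rp$flags))
      expect_true(all(rp$ci_low <= rp$ratios & rp$ratios <= rp$ci_high))
    }
    # nesting: flags at larger lambda are a subset of flags at smaller
    expect_true(all(reports[[3]]$flags <= reports[[2]]$flags))
    expect_true(all(reports[[2]]$flags <= reports[[1]]$flags))
  }
})

test_that("count_flags_over_lambdas uses the default ladder and is non-increasing", {
  prof <- fake_profile(seq(0.2, 0.6, length.out = 19), 0.35)
  boot <- fake_boot(diag(1e-4, 19), beta_ols = 0.35)
  out <- count_flags_over_lambdas(prof, boot)
  expect_equal(out$table$lambda, c(1.05, 1.1, 1.2, 1.5, 2))
  expect_true(all(diff(out$table$n_flagged) <= 0))
  # homogeneous profile: zero flags everywhere
  out0 <- count_flags_over_lambdas(
    fake_profile(rep(0.35, 19), 0.35), boot
  )
  expect_true(all(out0$table$n_flagged == 0))
})

test_that("trend tests recover exact linear and quadratic structure", {
  taus <- seq(0.05, 0.95, 0.05)
  Sigma <- diag(1e-6, 19)

  lin_prof <- fake_profile(0.2 + 0.3 * taus, 0.35)
  tr <- trend_tests(lin_prof, fake_boot(Sigma))
  expect_equal(tr$linear$slope, 0.3, tolerance = 1e-3)
  expect_lt(tr$linear$p, 1e-10)
  expect_gt(tr$lrt_p, 0.9) # no quadratic improvement on exact linear input

  quad_prof <- fake_profile(0.3 + 2 * (taus - 0.5)^2, 0.35)
  tr2 <- trend_tests(quad_prof, fake_boot(Sigma))
  expect_lt(tr2$lrt_p, 1e-3)
  expect_lt(tr2$quadratic$p_joint, 1e-10)

  expect_true(tr$lrt_stat >= 0 && tr2$lrt_stat >= 0)
})

test_that("trend p-values are calibrated under a flat profile", {
  taus <- seq(0.05, 0.95, 0.05)
  set.seed(31)
  pvals <- replicate(500, {
    beta <- rep(0.3, 19) + rnorm(19, 0, 0.01)
    prof <- fake_profile(beta, 0.3)
    trend_tests(prof, fake_boot(diag(1e-4, 19)))$linear$p
  })
  # roughly uniform: rejection rate at 0.05 within Monte-Carlo slack
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  expect_gt(ks.test(pvals, "punif")$p.value, 1e-4)
})

test_that("reversing the quantile grid negates the slope, preserves the LRT", {
  taus <- seq(0.05, 0.95, 0.05)
  set.seed(13)
  beta <- 0.3 + 0.2 * taus + 0.5 * (taus - 0.5)^2 + rnorm(19, 0, 0.02)
  A <- matrix(rnorm(19 * 25, 0, 0.01), 19)
  Sigma <- crossprod(t(A)) / 25 + diag(1e-5, 19)

  tr <- trend_tests(fake_profile(beta, 0.35), fake_boot(Sigma))
  # tau -> 1 - tau: reverse the effect vector and permute the covariance
  rev_idx <- 19:1
  tr_rev <- trend_tests(
    fake_profile(beta[rev_idx], 0.35),
    fake_boot(Sigma[rev_idx, rev_idx])
  )
  expect_equal(tr_rev$linear$slope, -tr$linear$slope, tolerance = 1e-9)
  expect_equal(tr_rev$lrt_p, tr$lrt_p, tolerance = 1e-9)
})

test_that("crossing_quantile interpolates the dominant crossing", {
  taus <- seq(0.05, 0.95, 0.05)
  # flat: none
  flat <- fake_profile(rep(0.4, 19), 0.4)
  expect_identical(crossing_quantile(flat)$direction, "none")
  expect_true(is.na(crossing_quantile(flat)$tau_cross))

  # constructed crossing at 0.62, rising
  prof <- fake_profile(0.4 + (taus - 0.62), 0.4)
  cr <- crossing_quantile(prof)
  expect_equal(cr$tau_cross, 0.62, tolerance = 1e-10)
  expect_equal(cr$direction, "rising")

  # falling
  prof2 <- fake_profile(0.4 - (taus - 0.3), 0.4)
  expect_equal(crossing_quantile(prof2)$direction, "falling")
  expect_equal(crossing_quantile(prof2)$tau_cross, 0.3, tolerance = 1e-10)

  # small wiggle below the flatness guard: none
  wiggle <- fake_profile(0.4 * (1 + 0.03 * sin(taus * 20)), 0.4)
  expect_identical(crossing_quantile(wiggle)$direction, "none")

  # two crossings: the one flanked by more |deviation| mass dominates
  d <- c(rep(-0.01, 2), rep(0.01, 3), rep(-0.2, 10), rep(0.3, 4))
  prof3 <- fake_profile(0.4 + d, 0.4)
  cr3 <- crossing_quantile(prof3)
  expect_gt(cr3$tau_cross, 0.7) # between taus[15] = 0.75 and taus[16] = 0.80
  expect_equal(cr3$direction, "rising")
})
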