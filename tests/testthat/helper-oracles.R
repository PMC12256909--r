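# Independent oracles and fixture builders shared across the suite.
# Every oracle is a direct transcription of a definition, kept free of the
# package's own solver paths.

# elementwise check loss
oracle_check_loss <- function(r, tau) {
  s <- 0
  for (ri in r) s <- s + ri * (tau - as.numeric(ri < 0))
  s
}

# exact optimum of the univariate QR objective by finite candidate-line
# enumeration: an optimum passes through >= 2 data points (or is an
# intercept-only fit through one point).  Valid for small n only.
oracle_qr_enum <- function(y, g, tau) {
  n <- length(y)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (g[i] == g[j]) next
      b <- (y[j] - y[i]) / (g[j] - g[i])
      a <- y[i] - b * g[i]
      best <- min(best, oracle_check_loss(y - a - b * g, tau))
    }
  }
  for (i in seq_len(n)) {
    best <- min(best, oracle_check_loss(y - y[i], tau))
  }
  best
}

# least squares by explicit normal equations
oracle_lstsq <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Pearson correlation from the covariance formula
oracle_cor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# nested 2-D grid refinement of the QR objective around a starting point;
# independent of the profile/golden-section solver
oracle_qr_grid_search <- function(y, g, tau, center_a = 0, center_b = 0,
                                  half = 3, levels = 6, pts = 41) {
  obj <- function(a, b) oracle_check_loss(y - a - b * g, tau)
  a0 <- center_a
  b0 <- center_b
  ha <- hb <- half
  best <- c(a0, b0, obj(a0, b0))
  for (lev in seq_len(levels)) {
    as_ <- seq(a0 - ha, a0 + ha, length.out = pts)
    bs_ <- seq(b0 - hb, b0 + hb, length.out = pts)
    vals <- outer(as_, bs_, Vectorize(obj))
    k <- arrayInd(which.min(vals), dim(vals))
    a0 <- as_[k[1]]
    b0 <- bs_[k[2]]
    if (vals[k] < best[3]) best <- c(a0, b0, vals[k])
    ha <- ha * 2.2 / pts
    hb <- hb * 2.2 / pts
  }
  list(intercept = best[1], slope = best[2], objective = best[3])
}

# random cohort_table fixture
make_cohort <- function(n = 100, k = 3, seed = 1, rho = 0.4) {
  withr::with_seed(seed, {
    g <- rnorm(n)
    y <- rho * g + sqrt(1 - rho^2) * rnorm(n)
    C <- NULL
    if (k > 0) {
      C <- matrix(rnorm(n * k), n, k,
        dimnames = list(NULL, paste0("c", seq_len(k)))
      )
      y <- y + C %*% rnorm(k, 0, 0.5)
    }
    cohort_table(phenotype = as.numeric(y), pgs = g, covariates = C)
  })
}

# standardized residual pair built directly (no covariates)
make_pair <- function(n = 500, rho = 0.4, seed = 1) {
  cohort <- withr::with_seed(seed, {
    g <- rnorm(n)
    y <- rho * g + sqrt(1 - rho^2) * rnorm(n)
    cohort_table(y, g)
  })
  residualize(cohort, character(0))
}

# reduced-scale overrides used throughout the suite (same qualitative
# assertions as the full 40,000 / B = 200 configuration, desk-fast)
reduced_n <- list(n_total = 8000)
reduced_config <- function(seed = 1L) {
  screen_config(boot_B = 100L, seed = seed)
}

write_tiny_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
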