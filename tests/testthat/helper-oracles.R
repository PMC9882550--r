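# Independent oracles and small fixture builders shared across tests.

# Dense Bayes-linear posterior by joint multivariate-normal conditioning:
# (b, y) are jointly normal with b ~ MVN(0, s2 * Sigma_B), y = X b + e,
# e ~ MVN(0, s2 I). Conditioning y gives mean Sigma_B X' (X Sigma_B X' + I)^-1 y
# and covariance s2 {Sigma_B - Sigma_B X' (X Sigma_B X' + I)^-1 X Sigma_B}.
# This is a different computational route from the precision-form update the
# package implements.
oracle_posterior <- function(X, y, Sigma_B) {
  S_xy <- Sigma_B %*% t(X)
  S_yy <- X %*% Sigma_B %*% t(X) + diag(nrow(X))
  gain <- S_xy %*% solve(S_yy)
  list(m = drop(gain %*% y),
       V = Sigma_B - gain %*% t(S_xy))
}

# Hand OLS: residuals of y on columns of X via the normal equations,
# solved with a plain matrix inverse (small problems only).
oracle_ols_resid <- function(X, y) {
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  drop(y - X %*% beta)
}

# Small cohort with well-separated trajectory shapes for clustering tests.
separated_config <- function(n, seed, ...) {
  sim_config(n_individuals = n, seed = seed, sd_slope = 0.05, sd_noise = 0.8,
             measurements = list(min = 4, max = 40, mean = 10), ...)
}

# Full path from raw cohort to collected spline posteriors.
cohort_posteriors <- function(sc, design, prior, keep_cov = TRUE) {
  qc <- run_qc(sc$measurements)
  pre <- preprocess_residuals(qc$measurements, sc$covariates)
  fits <- fit_posteriors(pre, design, prior)
  sigma2 <- estimate_noise_variance(fits, design)
  collect_posteriors(fits, sigma2, keep_cov = keep_cov)
}

# Cross-sectional comparison trait: one randomly selected measurement per
# individual, residualised on baseline covariates and inverse-normal
# transformed.
single_measurement_trait <- function(measurements, covariates, seed) {
  set.seed(seed)
  ix <- unlist(tapply(seq_len(nrow(measurements)), measurements$id,
                      function(ii) ii[sample.int(length(ii), 1)]))
  d <- merge(measurements[ix, ], covariates, by = "id")
  x <- stats::model.matrix(~ baseline_age + I(baseline_age^2) +
                             year_of_birth + sex, data = d)
  r <- stats::lm.fit(x, d$value)$residuals
  stats::setNames(inverse_normal_transform(r), d$id)
}
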