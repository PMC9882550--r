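test_that("preprocessing standardises residuals exactly", {
  sc <- simulate_cohort(sim_config(n_individuals = 80, seed = 4))
  pre <- preprocess_residuals(sc$measurements, sc$covariates)
  expect_equal(mean(pre$resid), 0, tolerance = 1e-10)
  expect_equal(sd(pre$resid), 1, tolerance = 1e-10)
  # covariate-free: plain standardisation
  pre0 <- preprocess_residuals(sc$measurements, NULL)
  y <- sc$measurements$value
  expect_equal(pre0$resid, (y - mean(y)) / sd(y), tolerance = 1e-12)
})

test_that("preprocessing matches hand OLS on a small toy", {
  m <- data.frame(rid = 1:8, id = rep(c("a", "b", "c", "d"), each = 2),
                  trait = "bmi", value = c(25, 26, 30, 29, 22, 23, 28, 27),
                  age_years = c(40, 42, 50, 52, 45, 47, 55, 57),
                  day = rep(c(0, 730), 4), data_provider = "p1")
  cov <- data.frame(id = c("a", "b", "c", "d"), sex = "F",
                    year_of_birth = c(1940L, 1955L, 1960L, 1948L),
                    baseline_age = c(40, 50, 45, 55))
  pre <- preprocess_residuals(m, cov)
  x <- cbind(1, rep(cov$baseline_age, each = 2),
             rep(cov$baseline_age^2, each = 2),
             rep(cov$year_of_birth, each = 2))
  r <- oracle_ols_resid(x, m$value)
  # the hand normal-equations solve carries ~1e-8 of conditioning error
  expect_equal(pre$resid, (r - mean(r)) / sd(r), tolerance = 1e-6)
})

test_that("design is a clamped partition-of-unity basis with n_df-4 knots", {
  des <- build_design(T_days = 7500, n_df = 100, degree = 3)
  expect_equal(dim(des$basis), c(7501, 100))
  expect_equal(rowSums(des$basis), rep(1, 7501), tolerance = 1e-10)
  # n_df - degree - 1 = 96 evenly spaced interior knots
  interior <- des$knots[des$knots > 0 & des$knots < 7500]
  expect_equal(length(interior), 96)
  expect_equal(diff(interior), rep(7500 / 97, 95), tolerance = 1e-9)
  # clamped left boundary
  expect_equal(des$basis[1, 1], 1)
  expect_true(all(des$basis[1, -1] == 0))
  expect_error(build_design(T_days = 0), "T_days")
  expect_error(build_design(n_df = 4, degree = 3), "n_df")
})

test_that("posterior matches dense conjugate-normal oracle", {
  des <- build_design(T_days = 100, n_df = 10)
  # moderately diffuse mean component: keeps the covariance-form oracle
  # well conditioned so both routes are exact to full precision
  pri <- smoothing_prior(2.5, 0.9, sigma_mu = 5, n_df = 10)
  set.seed(5)
  for (rep in 1:5) {
    days <- sort(sample(0:100, 5))
    y <- rnorm(5)
    f <- fit_posterior(days, y, des, pri)
    orc <- oracle_posterior(des$basis[days + 1, , drop = FALSE], y,
                            pri$Sigma_B)
    expect_equal(f$m, orc$m, tolerance = 1e-8)
    expect_equal(f$V, orc$V, tolerance = 1e-8)
  }
})

test_that("posterior edge cases: no data, zero data, out-of-range days", {
  des <- build_design(T_days = 100, n_df = 10)
  pri <- smoothing_prior(n_df = 10)
  f0 <- fit_posterior(integer(0), numeric(0), des, pri)
  expect_equal(f0$m, rep(0, 10))
  expect_equal(f0$V, pri$Sigma_B)
  fz <- fit_posterior(c(0, 50, 100), c(0, 0, 0), des, pri)
  expect_equal(fz$m, rep(0, 10))
  expect_error(fit_posterior(101, 1, des, pri), "day outside")
})

test_that("posterior shrinks monotonically as observations accrue", {
  des <- build_design(T_days = 100, n_df = 10)
  pri <- smoothing_prior(n_df = 10)
  set.seed(6)
  days <- sort(sample(0:100, 8)); y <- rnorm(8)
  traces <- vapply(0:8, function(j) {
    f <- fit_posterior(days[seq_len(j)], y[seq_len(j)], des, pri)
    sum(diag(f$V))
  }, 0)
  expect_true(all(diff(traces) <= 1e-8))
})

test_that("noise variance is the median individual MLE", {
  des <- build_design(T_days = 10, n_df = 5)
  mk <- function(mse, j) list(m = rep(0, 5), V = diag(5),
                              days = seq_len(j) - 1,
                              y = rep(sqrt(mse), j))
  fits <- list(a = mk(0.1, 2), b = mk(0.4, 3), c = mk(0.9, 1))
  expect_equal(estimate_noise_variance(fits, des), 0.4)
  expect_equal(estimate_noise_variance(rev(fits), des), 0.4)
  expect_warning(estimate_noise_variance(list(mk(0, 2)), des), "degenerate")
  expect_error(estimate_noise_variance(list(list(m = rep(0, 5),
                                                 days = integer(0),
                                                 y = numeric(0))), des),
               "no individual")
})

test_that("baselining annihilates constants and zeroes the first coordinate", {
  expect_equal(baseline_posterior(rep(3, 4), diag(4), 1)$mean, rep(0, 4))
  out <- baseline_posterior(c(1, 2, 4), diag(3), 0.5)
  expect_equal(out$mean, c(0, 1, 3))
  expect_equal(out$cov[1, ], rep(0, 3))
  expect_equal(out$cov[, 1], rep(0, 3))
  # congruence preserves symmetry and PSD
  set.seed(7)
  A <- crossprod(matrix(rnorm(25), 5))
  cv <- baseline_posterior(rnorm(5), A, 2)$cov
  expect_equal(cv, t(cv))
  expect_true(all(eigen(cv, symmetric = TRUE, only.values = TRUE)$values
                  > -1e-8))
})

test_that("default prior smooths an order of magnitude beyond phi = 0", {
  des <- build_design(T_days = 1000, n_df = 30)
  set.seed(8)
  days <- sort(sample(0:1000, 20)); y <- rnorm(20)
  tv <- function(prior) {
    f <- fit_posterior(days, y, des, prior)
    sum(abs(diff(drop(des$basis %*% f$m))))
  }
  tv_smooth <- tv(smoothing_prior(2.5, 0.99, 100, n_df = 30))
  tv_rough <- tv(smoothing_prior(2.5, 0, 100, n_df = 30))
  expect_gt(tv_rough / tv_smooth, 10)
})

test_that("prior hyperparameter settings are compared in one report", {
  sc <- simulate_cohort(separated_config(250, 17))
  qc <- run_qc(sc$measurements)
  pre <- preprocess_residuals(qc$measurements, sc$covariates)
  des <- build_design(T_days = 7500, n_df = 40)
  rep <- suppressWarnings(prior_sensitivity(
    pre, des, cluster_config = cluster_config(S = 2, subsample = 250,
                                              seed = 3)))
  expect_equal(nrow(rep), 3)
  expect_equal(rep$ari_vs_reference[2], 1)
  expect_true(all(is.finite(rep$mean_silhouette)))
})
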