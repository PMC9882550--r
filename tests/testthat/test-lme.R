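test_that("noise-free deterministic data reproduces fixed effects exactly", {
  # y depends only on the fixed part: intercept 25, slope 0.3/yr
  set.seed(1)
  n <- 40
  cov <- data.frame(id = sprintf("i%02d", 1:n), sex = rep(c("F", "M"), n / 2),
                    year_of_birth = sample(1940:1970, n, replace = TRUE),
                    assessment_centre = "c1", data_provider = "p1",
                    baseline_age = runif(n, 40, 60))
  meas <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- c(0, 2, 5, 9)
    data.frame(id = cov$id[i], trait = "bmi", value = 25 + 0.3 * t,
               age_years = cov$baseline_age[i] + t, data_provider = "p1")
  }))
  fit <- suppressWarnings(fit_lme(meas, cov))
  expect_equal(unname(fit$fixef["tsince"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(fit$fixef["(Intercept)"] +
                 fit$fixef["baseline_age"] * mean(cov$baseline_age) +
                 fit$fixef["I(baseline_age^2)"] * mean(cov$baseline_age^2) +
                 fit$fixef["year_of_birth"] * mean(cov$year_of_birth)),
               25, tolerance = 1e-4)
  expect_lt(max(abs(fit$blups$u0)), 1e-4)
  expect_lt(max(abs(fit$blups$u1)), 1e-4)
})

test_that("slope BLUPs track true slopes under realistic sparsity", {
  cors <- vapply(1:2, function(s) {
    lin <- function(t) 0 * t
    cfg <- sim_config(n_individuals = 800, seed = s, sd_intercept = 1,
                      sd_slope = 0.2, sd_noise = 0.5,
                      cluster_shapes = list(lin, lin, lin, lin),
                      measurements = list(min = 2, max = 40, mean = 8))
    sc <- simulate_cohort(cfg)
    fit <- fit_lme(run_qc(sc$measurements)$measurements, sc$covariates)
    cor(fit$blups$u1, sc$truth$slope[match(fit$blups$id, sc$truth$id)])
  }, 0)
  expect_true(all(cors > 0.8))
})

test_that("sex-specific strata drop the sex covariate and subset rows", {
  sc <- simulate_cohort(sim_config(n_individuals = 120, seed = 8))
  fit_f <- fit_lme(sc$measurements, sc$covariates, stratum = "female")
  expect_false(any(grepl("sex", names(fit_f$fixef))))
  f_ids <- sc$covariates$id[sc$covariates$sex == "F"]
  expect_setequal(fit_f$blups$id, intersect(f_ids, sc$measurements$id))
})

test_that("single-measurement individuals receive shrunken BLUPs", {
  sc <- simulate_cohort(sim_config(n_individuals = 150, seed = 14,
                                   measurements = list(min = 1, max = 3,
                                                       mean = 1.3)))
  fit <- fit_lme(sc$measurements, sc$covariates)
  singles <- fit$blups$id[fit$blups$n_followups == 1]
  expect_gt(length(singles), 0)
  expect_lt(max(abs(fit$blups$u1[fit$blups$id %in% singles])),
            max(abs(fit$blups$u1)) + 1e-12)
  expect_equal(nrow(fit$blups), length(unique(sc$measurements$id)))
})

test_that("adjustment residuals match a hand OLS on a small toy", {
  cov <- data.frame(id = letters[1:8], sex = "F",
                    year_of_birth = c(1940L, 1950L, 1960L, 1945L, 1955L,
                                      1948L, 1962L, 1941L),
                    assessment_centre = "c1",
                    baseline_age = c(40, 45, 50, 55, 60, 42, 57, 48))
  fit <- structure(list(blups = data.frame(
    id = letters[1:8], u0 = c(1.2, -0.5, 0.3, 2.0, -1.1, 0.7, -0.9, 0.2),
    u1 = c(0.1, 0.0, -0.2, 0.05, 0.15, -0.07, 0.02, 0.11),
    n_followups = c(3L, 4L, 2L, 6L, 5L, 7L, 3L, 9L),
    followup_years = c(2, 8, 1, 10, 6, 4, 3, 12))), class = "lme_fit")
  out <- derive_adjusted_traits(fit, cov)
  d <- fit$blups[order(fit$blups$id), ]
  cv <- cov[order(cov$id), ]
  x0 <- cbind(1, cv$baseline_age, cv$baseline_age^2, cv$year_of_birth,
              d$n_followups, d$followup_years)
  expect_equal(out$u0_resid, oracle_ols_resid(x0, d$u0), tolerance = 1e-8)
  x1 <- cbind(x0, d$u0)
  expect_equal(out$u1_resid, oracle_ols_resid(x1, d$u1), tolerance = 1e-8)
})

test_that("slope residuals are orthogonal to the adjustment covariates", {
  set.seed(99)
  n <- 5000
  cov <- data.frame(id = sprintf("i%05d", 1:n),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    year_of_birth = sample(1940:1970, n, replace = TRUE),
                    assessment_centre = sample(paste0("c", 1:5), n,
                                               replace = TRUE),
                    baseline_age = runif(n, 40, 60))
  blups <- data.frame(id = cov$id, u0 = rnorm(n),
                      u1 = rnorm(n, 0, 0.2) + 0.05 * rnorm(n),
                      n_followups = sample(2:20, n, replace = TRUE),
                      followup_years = runif(n, 0, 20))
  blups$u1 <- blups$u1 + 0.1 * blups$u0  # leakage the adjustment removes
  fit <- structure(list(blups = blups), class = "lme_fit")
  out <- derive_adjusted_traits(fit, cov)
  expect_lt(abs(cor(out$u1_resid, blups$u0)), 0.01)
  expect_lt(abs(cor(out$u1_resid, blups$n_followups)), 0.01)
  expect_lt(abs(cor(out$u1_resid, blups$followup_years)), 0.01)
})

test_that("INT matches quantile-function oracle and is idempotent", {
  expect_equal(inverse_normal_transform(5), 0)
  # N = 3 distinct values map to the (r - 1/2)/N grid of normal quantiles
  out <- inverse_normal_transform(c(3.2, -1, 10))
  expect_equal(sort(out), qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(sort(out)[c(1, 3)], c(-0.9674, 0.9674), tolerance = 1e-4)
  x <- rnorm(100)
  expect_equal(inverse_normal_transform(inverse_normal_transform(x)),
               inverse_normal_transform(x))
  expect_identical(order(inverse_normal_transform(x)), order(x))
  expect_error(inverse_normal_transform(c(1, NA)), "finite")
  # ties get average ranks, deterministically
  expect_equal(inverse_normal_transform(c(1, 1, 2))[1:2],
               rep(qnorm(1 / 3), 2))
})

test_that("INT output is standardised at large n", {
  x <- inverse_normal_transform(rchisq(2000, 3))
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(sd(x) - 1), 0.02)
})
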