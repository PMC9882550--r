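#' Stage 1: random-intercept, random-slope mixed model
#'
#' Fits, by full maximum likelihood, the model
#' \deqn{y_{ij} = x_i^T\gamma + (\beta_0 + u_{i0}) + (\beta_1 + u_{i1})(t_{ij} - t_{i1}) + \epsilon_{ij}}
#' where time is years since each individual's first retained measurement and
#' the fixed covariates are baseline age, baseline age squared, data provider,
#' year of birth and sex (sex is dropped in sex-specific strata). Random
#' intercept and slope are independent normals (diagonal random-effects
#' covariance); `correlated_re = TRUE` relaxes this to an unstructured 2x2
#' covariance. BLUPs (empirical-Bayes predictions of u_{i0}, u_{i1}) are
#' returned for every individual with at least one retained measurement;
#' individuals with a single measurement get a slope BLUP shrunk toward 0.
#'
#' @param measurements QC'd long-format table (`id`, `trait`, `value`,
#'   `age_years`).
#' @param covariates per-individual table (`id`, `sex`, `year_of_birth`,
#'   `baseline_age`, `data_provider`).
#' @param stratum `"combined"`, `"female"` or `"male"`.
#' @param correlated_re allow intercept-slope correlation (default FALSE).
#' @return object of class `"lme_fit"`: list with `fixef`, `varcomp`
#'   (`sigma2_u0`, `sigma2_u1`, `sigma2_eps`), `blups` (data.frame `id`, `u0`,
#'   `u1`, `n_followups`, `followup_years`), `converged`, `logLik`, `stratum`.
#' @export
fit_lme <- function(measurements, covariates, stratum = "combined",
                    correlated_re = FALSE) {
  stratum <- match.arg(stratum, c("combined", "female", "male"))
  d <- merge(measurements,
             covariates[, c("id", "sex", "year_of_birth", "baseline_age")],
             by = "id")
  if (stratum != "combined")
    d <- d[d$sex == if (stratum == "female") "F" else "M", , drop = FALSE]
  if (length(unique(d$id)) < 2) stop("need at least 2 individuals")

  first_age <- stats::ave(d$age_years, d$id, FUN = min)
  d$tsince <- d$age_years - first_age
  d$data_provider <- factor(d$data_provider)
  d$sex <- factor(d$sex)

  rhs <- "baseline_age + I(baseline_age^2) + year_of_birth + tsince"
  if (nlevels(d$data_provider) > 1) rhs <- paste(rhs, "+ data_provider")
  if (stratum == "combined" && nlevels(d$sex) > 1) rhs <- paste(rhs, "+ sex")
  re <- if (correlated_re) "(1 + tsince | id)"
    else "(1 | id) + (0 + tsince | id)"
  fml <- stats::as.formula(paste("value ~", rhs, "+", re))

  fit <- lme4::lmer(fml, data = d, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged)
    warning("lme4 convergence diagnostics: ", paste(msgs, collapse = "; "))

  vc <- lme4::VarCorr(fit)
  if (correlated_re) {
    s2_u0 <- vc$id["(Intercept)", "(Intercept)"]
    s2_u1 <- vc$id["tsince", "tsince"]
  } else {
    s2_u0 <- vc$id[1, 1]
    s2_u1 <- vc$id.1[1, 1]
  }
  re_df <- lme4::ranef(fit)$id
  u0 <- re_df[, "(Intercept)"]
  u1 <- re_df[, "tsince"]
  ids <- rownames(re_df)
  nfu <- tapply(d$id, d$id, length)
  flen <- tapply(d$age_years, d$id, function(a) max(a) - min(a))
  structure(list(
    fixef = lme4::fixef(fit),
    varcomp = c(sigma2_u0 = unname(s2_u0), sigma2_u1 = unname(s2_u1),
                sigma2_eps = stats::sigma(fit)^2),
    blups = data.frame(id = ids, u0 = u0, u1 = u1,
                       n_followups = as.integer(nfu[ids]),
                       followup_years = as.numeric(flen[ids]),
                       stringsAsFactors = FALSE),
    converged = converged, logLik = as.numeric(stats::logLik(fit)),
    stratum = stratum, messages = msgs
  ), class = "lme_fit")
}

#' Rank-based inverse normal transformation
#'
#' Deterministic transform mapping values to standard-normal quantiles by
#' rank: \eqn{\Phi^{-1}\{(r_i - c)/(N - 2c + 1)\}} with offset c (default
#' 0.5). Ties receive average ranks, making the transform deterministic.
#'
#' @param values finite numeric vector.
#' @param offset the rank offset c.
#' @return transformed vector, same order as input.
#' @export
inverse_normal_transform <- function(values, offset = 0.5) {
  if (!length(values) || any(!is.finite(values)))
    stop("inverse_normal_transform requires finite inputs")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Stage 2: covariate adjustment and INT of BLUPs
#'
#' Regresses the intercept BLUP on baseline age, baseline age squared, sex,
#' year of birth, assessment centre, number of follow-ups and total follow-up
#' length; the slope BLUP on the same covariates plus the intercept BLUP
#' (removing regression-to-baseline leakage). Residuals from the two OLS fits
#' are then inverse-normal transformed ([inverse_normal_transform()]) to give
#' the GWAS-ready intercept and slope traits.
#'
#' @param fit an [fit_lme()] object.
#' @param covariates per-individual table with `id`, `sex`, `year_of_birth`,
#'   `assessment_centre`, `baseline_age`.
#' @return data.frame `id`, `u0_resid`, `u1_resid`, `u0_int`, `u1_int`,
#'   `n_followups`, `followup_years`.
#' @export
derive_adjusted_traits <- function(fit, covariates) {
  stopifnot(inherits(fit, "lme_fit"))
  d <- merge(fit$blups, covariates, by = "id")
  d <- d[order(d$id), , drop = FALSE]

  terms0 <- c("baseline_age", "I(baseline_age^2)", "year_of_birth",
              "n_followups", "followup_years")
  if (length(unique(d$sex)) > 1) terms0 <- c(terms0, "sex")
  if (length(unique(d$assessment_centre)) > 1)
    terms0 <- c(terms0, "assessment_centre")

  x0 <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms0, collapse = "+"))), data = d)
  check_full_rank(x0)
  u0_resid <- stats::lm.fit(x0, d$u0)$residuals

  x1 <- cbind(x0, u0_blup = d$u0)
  check_full_rank(x1)
  u1_resid <- stats::lm.fit(x1, d$u1)$residuals

  data.frame(id = d$id, u0_resid = u0_resid, u1_resid = u1_resid,
             u0_int = inverse_normal_transform(u0_resid),
             u1_int = inverse_normal_transform(u1_resid),
             n_followups = d$n_followups, followup_years = d$followup_years,
             stringsAsFactors = FALSE)
}

check_full_rank <- function(x) {
  q <- qr(x)
  if (q$rank < ncol(x)) {
    bad <- colnames(x)[q$pivot[(q$rank + 1):ncol(x)]]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
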