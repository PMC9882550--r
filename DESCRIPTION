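Package: trajphen
Title: Baseline and Change Phenotypes from Sparse Longitudinal Adiposity Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-individual baseline-adiposity and adiposity-change
    phenotypes from sparse, irregularly timed longitudinal measurements of the
    kind found in linked primary-care records. Implements population- and
    individual-level longitudinal quality control (plausibility bounds, outlier
    and extreme-jump filters), a two-stage random-intercept random-slope mixed
    model yielding covariate-adjusted, inverse-normal transformed intercept and
    slope traits, a closed-form Bayes linear model on a regularised cubic
    B-spline basis with an AR(1) smoothing prior for non-linear trajectories,
    heteroscedasticity-aware k-medoids soft clustering of trajectories with
    bounded-logit cluster-membership traits, and downstream covariate-adjusted
    SNP association statistics including a sex-heterogeneity Z test and a
    chi-squared power-ratio comparison. A seeded synthetic-cohort generator
    (measurements, covariates, genotypes, artifacts, ground truth) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    lme4,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
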