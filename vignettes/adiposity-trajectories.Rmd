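---
title: "Deriving baseline and change phenotypes from sparse longitudinal adiposity records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving baseline and change phenotypes from sparse longitudinal adiposity records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Primary-care records linked to biobank cohorts contain repeated adiposity
measurements (BMI, weight) that are sparse, irregularly timed, and noisy:
individuals may have anywhere from one to several dozen measurements spread
over up to two decades, and record-keeping artifacts — duplicated entries on
the same day, transcription errors, implausible values — are common.
`trajphen` turns such data into per-individual phenotypes suitable for
genetic association analysis: a *baseline* (intercept) trait, a linear
*rate-of-change* (slope) trait, and *soft trajectory-cluster membership*
traits that capture non-linear patterns (sustained gain, moderate gain,
stability, loss).

Because the motivating data sources are access-restricted, the package ships
a synthetic-cohort generator with the same statistical structure, and every
stage of the pipeline is exercised and tested against it.

## Quality control

Population-level rules run first, in a fixed order: bariatric-surgery
exclusions (rows after a known surgery date, or whole individuals when no
date is determinable), restriction to adult ages 20–80, trait plausibility
bounds (BMI within [10.9, 82.1] kg/m², weight within [27, 217] kg), and a
5 SD population outlier filter. The population SD is computed *after* the
plausibility filter so that impossible values cannot inflate it.

Individual-level rules follow. Same-day duplicates keep the record closest
to the individual's median (ties keep the chronologically earlier row — an
arbitrary but deterministic rule). Then, for each adjacent pair of
measurements, the jump statistic

$$P_{j} = \log_2\!\left\{\frac{|y_{j+1}-y_{j}|/y_{j}}{t_{j+1}-t_{j}}\right\}$$

measures relative change per year on a log scale. Pairs whose jump exceeds
the population mean by more than 3 SDs lose the member farther from the
individual's median. Three deliberate choices here:

* only the *high* side is filtered. Strongly negative jumps correspond to
  tiny changes over long gaps, which are unremarkable, not erroneous;
* zero-change pairs have an undefined ($\log 0$) jump; they are excluded
  from the jump distribution and never filtered;
* filtering is a single pass — the jump distribution is not re-estimated on
  the filtered data. Empirically a second pass changes nothing on clean
  cohorts, and a fixed-point iteration would make removal depend on
  cohort-ordering subtleties.

Whether outlier thresholds should be computed per sex stratum is not
settled; the package pools sexes, which is conservative when the strata have
similar dispersion.

## Stage 1–2: intercept and slope traits

Stage 1 fits, by full maximum likelihood (not REML — the downstream use is
empirical-Bayes prediction, and ML keeps fixed- and random-effect estimates
internally consistent),

$$y_{ij} = x_i^\top\gamma + (\beta_0 + u_{i0}) + (\beta_1 + u_{i1})(t_{ij}-t_{i1}) + \varepsilon_{ij},$$

with independent normal random intercept and slope and fixed covariates
baseline age, baseline age², data provider, year of birth, and sex. The
diagonal random-effects covariance mirrors the independent-normal model
statement; a `correlated_re` switch exposes the unstructured alternative for
sensitivity analysis. BLUPs $\hat u_{i0}, \hat u_{i1}$ are produced for
every individual, including those with a single measurement, whose slope
BLUP is shrunk toward zero; such individuals are flagged via the
`n_followups` column so analysts can exclude them from slope analyses.

Stage 2 removes structural associations from the BLUPs by OLS: the
intercept BLUP is adjusted for baseline age, baseline age², sex, year of
birth, assessment centre, number of follow-ups and total follow-up length;
the slope BLUP additionally for the intercept BLUP itself (removing
regression-to-baseline leakage). Residuals are mapped through the
deterministic rank-based inverse normal transformation

$$\tilde u_i = \Phi^{-1}\!\left(\frac{r_i - c}{N - 2c + 1}\right), \qquad c = \tfrac12,$$

with average ranks for ties, so re-running the pipeline always reproduces
identical phenotypes. At $N = 3$ distinct values the transform evaluates to
$\Phi^{-1}(1/6), 0, \Phi^{-1}(5/6) \approx \mp 0.9674$ — the
$(r - \tfrac12)/N$ grid.

## Non-linear trajectories: a Bayes linear spline model

Measurements are first pooled into one OLS on baseline age, baseline age²,
data provider, year of birth and sex, and the residuals are standardised
globally. On this scale each individual's series over integer days
$0,\dots,T$ ($T = 7500 \approx 20.5$ years) is modelled with a shared
clamped cubic B-spline basis $X_B$ with $n_{df} = 100$ basis functions
(96 evenly spaced interior knots) — deliberately over-parameterised, with
smoothness imposed by the prior rather than by knot placement:

$$y_i \mid b_i \sim \mathrm{MVN}(Z_i X_B b_i, \sigma^2 I), \qquad
  b_i \sim \mathrm{MVN}(0, \Sigma_B),$$

$$\Sigma_B = \Sigma_{AR(1)} + \sigma_\mu^2 \mathbf{1}\mathbf{1}^\top, \qquad
  [\Sigma_{AR(1)}]_{kk'} = \sigma^2_{AR}\,\phi^{|k-k'|}.$$

The AR(1) component makes adjacent coefficients — hence the fitted curve —
vary smoothly; the $\sigma_\mu^2$ component is a diffuse prior on an
individual-specific mean level. Defaults $\sigma^2_{AR} = 2.5$,
$\phi = 0.99$, $\sigma_\mu = 100$ produce trajectories smooth on the scale
of months to years; `prior_sensitivity()` re-runs the clustering under
$(0.5, 0.9, 10)$ and $(10, 0.999, 500)$ and reports allocation agreement
with the default.

The posterior is closed form,

$$V_i = (X_B^\top Z_i^\top Z_i X_B + \Sigma_B^{-1})^{-1}, \qquad
  m_i = V_i X_B^\top Z_i^\top y_i,$$

with $V_i$ on the unit-noise scale (posterior covariance $\sigma^2 V_i$);
$\Sigma_B^{-1}$ is applied once via Cholesky, and each individual's update
uses only the $J_i$ relevant basis rows, so cohorts fit in seconds and are
embarrassingly parallel. The plug-in noise variance is the median of the
per-individual maximum-likelihood estimates
$J_i^{-1}\lVert y_i - Z_i X_B m_i \rVert^2$; a zero median (perfect fit) is
flagged as degenerate. Observations beyond day $T$ are dropped with a
warning rather than extrapolated. With no observations the posterior is the
prior, exactly as the formulas read.

Downstream stages work with the *baselined* coefficients
$\tilde b_i = D b_i$, where row $j$ of $D$ is $(e_j - e_1)^\top$: the
posterior change from baseline, $\mathrm{MVN}(D m_i, \sigma^2 D V_i
D^\top)$, whose first coordinate is identically zero.

## Soft trajectory clustering

Individuals differ greatly in how precisely each coefficient is estimated,
so the training distance standardises each coordinate by its summed
posterior variances:

$$d(i,i') = \sqrt{\sum_k
  \frac{([Dm_i]_k - [Dm_{i'}]_k)^2}
       {([DV_iD^\top]_{kk} + [DV_{i'}D^\top]_{kk})\,\sigma^2}}.$$

The first (baselined) coordinate is a structural 0/0 and contributes zero;
a zero variance anywhere else signals a degenerate posterior and is an
error. The $O(n^2 n_{df})$ kernel is implemented in C++.

Training runs PAM ($k$-medoids, K = 4) S = 10 times on random subsamples of
5,000 individuals with at least L = 2 observations, from an 80% training
split. Each run is initialised from quantile bins of a 2-year fold-change
score. The natural "fold change between baseline and year M" ratio is
undefined on baselined coefficients (the denominator — the baselined day-0
value — is identically zero under a clamped basis), so the score is the
ratio of the *un-baselined* fitted value at day $\mathrm{round}(365.25 M)$
to the fitted value at day 0, which is the quantity the initialisation is
meant to rank. Each bin's medoid (the member minimising total within-bin
distance) seeds PAM; a fresh subsample gets fresh bins.

Per run, cluster means of $D m_i$ are ordered point-wise from gain to loss
and averaged across runs with point-wise SEs. On well-separated data the
curves never cross; when synthetic noise makes them cross, runs are ordered
by grid mean and flagged, rather than silently reordered.

Soft membership of individual $i$ in cluster $k$ is the posterior
probability that $\tilde b_i$ is nearest (in plain Euclidean distance —
the membership metric is intentionally unscaled, unlike the training
metric) to centroid $c_{(k)}$, approximated with 100 Monte-Carlo samples
drawn by sampling $b \sim \mathrm{MVN}(m_i, \sigma^2 V_i)$ and baselining
(exact, and avoids factorising the singular baselined covariance). Each
individual's draws are seeded by a hash of the global seed and the
individual's identifier, so results do not depend on processing order.
Memberships are empirical frequencies: they sum to one exactly, and exact
distance ties go to the lower-index (higher-gain) cluster. The three
GWAS-ready traits are cumulative bounded log odds,

$$\mathrm{boundedlogit}(\pi) = \mathrm{logit}\!\left(\frac{(S-1)\pi + 0.5}{S}\right),
  \quad S = 100,$$

of membership in the top one, two, and three clusters; $S$ matches the
Monte-Carlo resolution so the transform's bounds ($\pm 5.29$) sit half a
sample beyond the observable probabilities.

`silhouette_eval()` and `cluster_sensitivity()` reproduce the K/L/M
sensitivity sweep (K in 2..8, L in {2, 5, 10}, M in {1, 2, 5, 10});
`validate_split()` compares assigned proportions and covariate
distributions between the training split and the 20% hold-out.

## Association statistics

`linear_assoc()` is covariate-adjusted OLS per SNP with additive dosage
coding, computed by the Frisch–Waugh projection (residualise trait and
dosages on the covariates once); it reproduces the full multiple-regression
estimate, SE and Wald P exactly at a fraction of the cost. Missing dosages
are mean-imputed per SNP with a logged count. OLS, rather than a mixed
model, is the appropriate engine here because the synthetic cohorts carry
no relatedness or population structure; the result table is format-
compatible with standard summary-statistics consumers so a mixed-model
engine can be substituted for real data. Cluster-trait scans additionally
adjust for baseline trait, baseline age, baseline age², sex, year of birth,
assessment centre, follow-up count and follow-up length. Effects on the
bounded-logit traits are emitted on both the linear scale and as
$e^{\hat\beta}$ (odds-ratio convention).

Sex heterogeneity between female- and male-specific effects is tested with

$$Z = \frac{\hat\beta^{(F)} - \hat\beta^{(M)}}
           {\sqrt{SE_{(F)}^2 + SE_{(M)}^2}}, \qquad P = 2\Phi(-|Z|),$$

and the power benefit of repeat measurements is summarised by the median
per-SNP ratio of Wald $\chi^2 = \hat\beta^2/SE^2$ statistics between two
analyses, compared against the median sample-size ratio — a ratio above the
sample-size ratio is power beyond what extra individuals would buy.
`variance_explained()` reports the incremental $R^2$ of a SNP block over
the covariate-only model.

## The synthetic cohort

`simulate_cohort()` emulates what the pipeline assumes about real linked
primary-care data:

* 1–40 irregularly timed measurements per individual over at most 20.5
  years, with the expected count increasing in the individual's true
  baseline trait when `ascertainment_slope > 0` (measurement-rich
  individuals are heavier — the ascertainment seen in real GP data);
* four latent trajectory shapes (high gain / moderate gain / stable /
  loss), monotone piecewise-linear-with-plateau curves chosen to be
  non-overlapping so that centroid ordering is well defined; defaults gain
  +0.8, +0.35, 0 and −0.5 BMI units/year with plateaus at 8–10 years;
* individual random intercepts (SD 4 kg/m², a typical cross-sectional BMI
  dispersion) and slopes (SD 0.15 kg/m²/yr), measurement noise (SD 1);
* sex drawn Bernoulli(0.545 female), matching the source cohorts'
  composition; covariates (year of birth, data provider, assessment
  centre) drawn uniformly and carrying no true effect;
* biallelic SNPs in Hardy–Weinberg equilibrium, independent across loci
  (no LD), with planted per-allele effects on intercept, slope, or
  cluster log-odds, optionally sex-restricted;
* injectable artifacts — same-day duplicates, implausible values, extreme
  jumps, bariatric events — each recorded in a ledger so QC recall and
  precision are measurable. Real GP data's artifact-generating process is
  unknown; the rates here are free parameters, not estimates. Duplicates
  are placed beyond the individual's value range so that the dedup rule
  provably removes the artifact and not the clean record.

Time is generated continuously in years of age; an integer
`day = round(365.25 * (age - first age))` column feeds the spline stage,
matching the day-grid formulation (ages for the mixed model, days for the
spline).

What the generator does *not* emulate: relatedness and population structure
(PC covariates would be standard-normal noise), LD between SNPs, imputation
uncertainty, time-varying covariates (medication, smoking, illness), or
informative-dropout mechanisms beyond baseline-level ascertainment. Tests
passing on these cohorts therefore demonstrate the computational and
statistical correctness of the pipeline, not robustness to every failure
mode of real records.

## Numerical choices and problem sizes

All linear algebra goes through QR or Cholesky factorisations; no normal
equations are formed with explicit inverses. The posterior oracle
equivalence check runs at $n_{df} = 10$, $T = 100$ against a dense
joint-normal conditioning oracle; that route involves a covariance
downdate whose cancellation error grows with $\sigma_\mu^2$, so the check
uses a moderately diffuse $\sigma_\mu = 5$, where both routes agree to
machine precision. Simulation-based checks use n = 2,000 (mixed-model
recovery), n = 4,000 (cluster recovery, power ratios) and n = 20,000
(single-SNP detection and calibration) — sizes at which every Monte-Carlo
check has comfortable margin while a full test run stays in the minutes
range on one CPU.

## Known limitations

* The jump filter's sidedness and the pooled (rather than sex-stratified)
  outlier thresholds are judgment calls on ambiguous methodology.
* Fold-change initialisation uses the un-baselined fitted trajectory; a
  ratio of baselined values is structurally undefined (see above).
* Prior hyperparameters are fixed, not estimated; posterior uncertainty in
  the spline coefficients propagates into cluster memberships via the
  Monte-Carlo integral but not into the association stage's standard
  errors.
* The association engine is OLS by design; with related individuals or
  stratified cohorts, substitute a mixed-model engine and feed it the
  emitted phenotype files.
```
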