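#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()]. The generator emulates sparse, irregularly timed
#' primary-care style measurements of an adiposity trait: individuals carry a
#' latent trajectory shape (high gain / moderate gain / stable / loss), an
#' individual random intercept and slope, and i.i.d. measurement noise.
#' Heavier individuals can be made to have more measurements
#' (`ascertainment_slope`), mimicking the ascertainment seen in real
#' general-practice data. Biallelic SNPs in Hardy-Weinberg equilibrium can be
#' planted with per-allele effects on the intercept, the slope, or the
#' log-odds of membership of the highest-gain cluster, optionally restricted
#' to one sex.
#'
#' @param n_individuals number of individuals.
#' @param trait trait name, `"bmi"` or `"weight"`; sets the unit scale.
#' @param baseline_mean population mean of the trait at baseline (kg/m2 for
#'   BMI, kg for weight).
#' @param follow_up_years maximum follow-up span in years (default 20.5,
#'   i.e. 7500 days).
#' @param measurements list with `min`, `max`, `mean`: the per-individual
#'   measurement count is `min + Poisson(mean - min)`, truncated at `max`.
#' @param ascertainment_slope extra expected measurements per SD of an
#'   individual's true baseline trait (>= 0); 0 disables ascertainment.
#' @param cluster_weights probabilities of the four latent trajectory shapes;
#'   must sum to 1.
#' @param cluster_shapes list of four functions of time-in-years returning the
#'   trait change from baseline; defaults are monotone, non-overlapping
#'   piecewise-linear-with-plateau curves (gain / moderate gain / stable /
#'   loss).
#' @param sd_intercept,sd_slope,sd_noise SDs of the random intercept (trait
#'   units), random slope (trait units per year) and measurement noise.
#' @param artifact_rates named numeric vector with entries `duplicate`,
#'   `implausible`, `jump`, `bariatric`; all in `[0, 1]`. Used by
#'   [inject_artifacts()].
#' @param n_snps number of simulated SNPs (0 for none).
#' @param maf_range minor-allele-frequency interval, a sub-interval of
#'   (0, 0.5].
#' @param planted_effects list of lists with fields `snp` (index), `target`
#'   (`"intercept"`, `"slope"` or `"cluster_logodds"`), `beta` (per-allele
#'   effect in trait units, trait units/year, or log-odds) and optional `sex`
#'   (`"F"` or `"M"` to restrict the effect to one sex).
#' @param sex_p_female probability of female sex (default 0.545).
#' @param seed integer seed; identical seed + config gives identical output.
#'
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 1000,
                       trait = "bmi",
                       baseline_mean = NULL,
                       follow_up_years = 20.5,
                       measurements = list(min = 1, max = 40, mean = 8),
                       ascertainment_slope = 0,
                       cluster_weights = c(0.25, 0.25, 0.25, 0.25),
                       cluster_shapes = default_cluster_shapes(trait),
                       sd_intercept = 4,
                       sd_slope = 0.15,
                       sd_noise = 1,
                       artifact_rates = c(duplicate = 0, implausible = 0,
                                          jump = 0, bariatric = 0),
                       n_snps = 0,
                       maf_range = c(0.05, 0.5),
                       planted_effects = list(),
                       sex_p_female = 0.545,
                       seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop("invalid config field 'n_individuals': must be >= 1")
  trait <- match.arg(trait, c("bmi", "weight"))
  if (is.null(baseline_mean))
    baseline_mean <- if (trait == "bmi") 27 else 78
  if (!is.numeric(follow_up_years) || follow_up_years <= 0)
    stop("invalid config field 'follow_up_years': must be > 0")
  for (f in c("min", "max", "mean")) {
    if (is.null(measurements[[f]]))
      stop("invalid config field 'measurements': missing '", f, "'")
  }
  if (measurements$min < 1 || measurements$max < measurements$min ||
      measurements$mean < measurements$min)
    stop("invalid config field 'measurements': need 1 <= min <= mean, min <= max")
  if (ascertainment_slope < 0)
    stop("invalid config field 'ascertainment_slope': must be >= 0")
  if (length(cluster_weights) != 4L || any(cluster_weights < 0) ||
      abs(sum(cluster_weights) - 1) > 1e-8)
    stop("invalid config field 'cluster_weights': 4 probabilities summing to 1")
  if (length(cluster_shapes) != 4L || !all(vapply(cluster_shapes, is.function, TRUE)))
    stop("invalid config field 'cluster_shapes': need 4 functions")
  for (s in c(sd_intercept, sd_slope, sd_noise))
    if (!is.numeric(s) || s < 0)
      stop("invalid config field: SDs must be >= 0")
  ar <- c(duplicate = 0, implausible = 0, jump = 0, bariatric = 0)
  ar[names(artifact_rates)] <- artifact_rates
  if (any(ar < 0) || any(ar > 1))
    stop("invalid config field 'artifact_rates': rates must lie in [0, 1]")
  if (n_snps < 0)
    stop("invalid config field 'n_snps': must be >= 0")
  check_maf_range(maf_range)
  for (pe in planted_effects) {
    if (is.null(pe$snp) || is.null(pe$target) || is.null(pe$beta))
      stop("invalid config field 'planted_effects': need snp, target, beta")
    if (pe$snp < 1 || pe$snp > n_snps)
      stop("invalid config field 'planted_effects': snp index out of range")
    if (!pe$target %in% c("intercept", "slope", "cluster_logodds"))
      stop("invalid config field 'planted_effects': unknown target '",
           pe$target, "'")
    if (!is.null(pe$sex) && !pe$sex %in% c("F", "M"))
      stop("invalid config field 'planted_effects': sex must be \"F\" or \"M\"")
  }
  if (sex_p_female < 0 || sex_p_female > 1)
    stop("invalid config field 'sex_p_female': must lie in [0, 1]")
  structure(list(
    n_individuals = as.integer(n_individuals), trait = trait,
    baseline_mean = baseline_mean, follow_up_years = follow_up_years,
    measurements = measurements, ascertainment_slope = ascertainment_slope,
    cluster_weights = cluster_weights, cluster_shapes = cluster_shapes,
    sd_intercept = sd_intercept, sd_slope = sd_slope, sd_noise = sd_noise,
    artifact_rates = ar, n_snps = as.integer(n_snps), maf_range = maf_range,
    planted_effects = planted_effects, sex_p_female = sex_p_female,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be a sub-interval of (0, 0.5]")
  invisible(maf_range)
}

#' Default latent trajectory shapes
#'
#' Four monotone, non-overlapping piecewise-linear-with-plateau mean
#' trajectories over follow-up, expressed as trait change from baseline:
#' high gain, moderate gain, stable, and loss. At every t > 0 the curves are
#' strictly ordered (gain > moderate > stable > loss), so centroid ordering in
#' the clustering stage is well defined.
#'
#' @param trait `"bmi"` or `"weight"`; weight shapes are BMI shapes scaled by
#'   3 (roughly kg per BMI unit at average height).
#' @return list of 4 functions of time in years.
#' @export
default_cluster_shapes <- function(trait = "bmi") {
  scale <- if (trait == "weight") 3 else 1
  list(
    gain     = function(t) scale * 0.80 * pmin(t, 10),
    moderate = function(t) scale * 0.35 * pmin(t, 10),
    stable   = function(t) scale * 0 * t,
    loss     = function(t) scale * -0.50 * pmin(t, 8)
  )
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP's MAF is drawn uniformly from `maf_range` and genotypes are
#' binomial(2, MAF) counts of the minor allele, independent across SNPs (no
#' linkage disequilibrium).
#'
#' @param n number of individuals.
#' @param n_snps number of SNPs.
#' @param maf_range sub-interval of (0, 0.5].
#' @param seed integer seed.
#' @return list with `genotypes` (n x n_snps integer matrix of 0/1/2 dosages,
#'   columns `snp1..snpP`) and `maf` (numeric vector).
#' @export
simulate_genotypes <- function(n, n_snps, maf_range = c(0.05, 0.5), seed = 1L) {
  if (n < 1 || n_snps < 1) stop("n and n_snps must be >= 1")
  check_maf_range(maf_range)
  set.seed(as.integer(seed))
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  g <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
  g <- matrix(as.integer(g), nrow = n, ncol = n_snps)
  colnames(g) <- paste0("snp", seq_len(n_snps))
  names(maf) <- colnames(g)
  list(genotypes = g, maf = maf)
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates measurements, covariates, genotypes and ground truth under the
#' configuration built by [sim_config()]. Each individual i receives a latent
#' cluster k, a random intercept and slope, and J_i measurements at irregular
#' days over follow-up:
#' \deqn{y_{ij} = \mu + s_k(t_{ij}) + u_{i0} + u_{i1} t_{ij} + \epsilon_{ij}}
#' with t in years since the individual's first measurement. Planted SNP
#' effects enter u_{i0}, u_{i1} or the cluster-assignment log-odds. Ground
#' truth is recorded before any artifact injection.
#'
#' @param config a [sim_config()] object.
#' @return list with
#'   \item{measurements}{long-format data.frame: `rid`, `id`, `trait`,
#'     `value`, `age_years`, `day` (integer days since the individual's first
#'     measurement), `data_provider`.}
#'   \item{covariates}{one row per individual: `id`, `sex`, `year_of_birth`,
#'     `assessment_centre`, `data_provider`, `baseline_age`.}
#'   \item{genotypes}{dosage matrix (or NULL), rownames = id.}
#'   \item{maf}{per-SNP MAF (or NULL).}
#'   \item{truth}{per-individual true `intercept`, `slope`, `cluster` (1..4,
#'     1 = highest gain), plus attribute `"snp_effects"`.}
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  id <- sprintf("id%06d", seq_len(n))

  sex <- ifelse(stats::runif(n) < config$sex_p_female, "F", "M")
  year_of_birth <- sample(1940:1970, n, replace = TRUE)
  assessment_centre <- sample(paste0("centre", 1:10), n, replace = TRUE)
  data_provider <- sample(paste0("provider", 1:4), n, replace = TRUE)
  baseline_age <- stats::runif(n, 30, 80 - config$follow_up_years - 0.5)

  geno <- NULL; maf <- NULL
  if (config$n_snps > 0) {
    gs <- simulate_genotypes(n, config$n_snps, config$maf_range,
                             seed = config$seed + 104729L)
    geno <- gs$genotypes; maf <- gs$maf
    rownames(geno) <- id
  }

  eff <- function(target) {
    out <- numeric(n)
    for (pe in config$planted_effects) {
      if (pe$target != target) next
      contrib <- pe$beta * geno[, pe$snp]
      if (!is.null(pe$sex)) contrib <- contrib * (sex == pe$sex)
      out <- out + contrib
    }
    out
  }

  # cluster assignment: per-individual log-weights shifted by cluster_logodds
  # effects on the highest-gain cluster
  logw <- matrix(log(pmax(config$cluster_weights, 1e-12)),
                 nrow = n, ncol = 4, byrow = TRUE)
  logw[, 1] <- logw[, 1] + eff("cluster_logodds")
  pw <- exp(logw - apply(logw, 1, max))
  pw <- pw / rowSums(pw)
  cl_u <- stats::runif(n)
  cluster <- max.col(cl_u < t(apply(pw, 1, cumsum)), ties.method = "first")

  intercept <- stats::rnorm(n, 0, config$sd_intercept) + eff("intercept")
  slope <- stats::rnorm(n, 0, config$sd_slope) + eff("slope")

  # measurement counts, with ascertainment on the true baseline trait
  z <- if (config$sd_intercept > 0) intercept / config$sd_intercept else numeric(n)
  lambda <- pmax(config$measurements$mean - config$measurements$min +
                   config$ascertainment_slope * z, 0)
  J <- pmin(config$measurements$min + stats::rpois(n, lambda),
            config$measurements$max)

  max_day <- round(365.25 * config$follow_up_years)
  day_list <- lapply(J, function(ji) {
    if (ji > 1) sort(c(0L, sample.int(max_day, ji - 1L))) else 0L
  })
  day <- unlist(day_list)
  t_years <- day / 365.25
  cl_rep <- rep(cluster, J)
  shape <- numeric(length(day))
  for (k in 1:4) {
    sel <- cl_rep == k
    if (any(sel)) shape[sel] <- config$cluster_shapes[[k]](t_years[sel])
  }
  y <- config$baseline_mean + shape + rep(intercept, J) +
    rep(slope, J) * t_years + stats::rnorm(length(day), 0, config$sd_noise)
  measurements <- data.frame(
    rid = seq_along(day), id = rep(id, J), trait = config$trait, value = y,
    age_years = rep(baseline_age, J) + t_years, day = as.integer(day),
    data_provider = rep(data_provider, J), stringsAsFactors = FALSE
  )

  covariates <- data.frame(
    id = id, sex = sex, year_of_birth = year_of_birth,
    assessment_centre = assessment_centre, data_provider = data_provider,
    baseline_age = baseline_age, stringsAsFactors = FALSE
  )
  truth <- data.frame(id = id, intercept = intercept, slope = slope,
                      cluster = cluster, stringsAsFactors = FALSE)
  attr(truth, "snp_effects") <- config$planted_effects
  list(measurements = measurements, covariates = covariates,
       genotypes = geno, maf = maf, truth = truth)
}

#' Inject data artifacts into clean measurements
#'
#' Corrupts a clean measurement table with the error modes seen in raw
#' primary-care data: same-day duplicate records, implausible values outside
#' the trait's plausibility bounds, extreme jumps, and bariatric-surgery
#' events. Every injected artifact is recorded in a ledger so that QC recall
#' and precision are computable. Injected implausible values fall outside the
#' plausibility bounds by construction; injected duplicates are placed farther
#' from the individual's median than the original record (beyond the
#' individual's own value range), so the dedup rule removes the duplicate, not
#' the clean row.
#'
#' @param measurements clean measurement table from [simulate_cohort()].
#' @param config the [sim_config()] whose `artifact_rates` drive injection.
#' @param seed optional seed override (defaults to `config$seed + 7919`).
#' @return list with `measurements` (corrupted), `ledger` (data.frame `type`,
#'   `id`, `rid`) and `events` (bariatric event table: `id`, `age_years`,
#'   possibly NA when the date is indeterminable).
#' @export
inject_artifacts <- function(measurements, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$artifact_rates
  if (any(rates > 1)) stop("artifact rate > 1")
  set.seed(if (is.null(seed)) config$seed + 7919L else as.integer(seed))

  meas <- measurements
  ledger <- data.frame(type = character(), id = character(),
                       rid = integer(), stringsAsFactors = FALSE)
  events <- data.frame(id = character(), age_years = numeric(),
                       stringsAsFactors = FALSE)
  if (all(rates == 0))
    return(list(measurements = meas, ledger = ledger, events = events))

  bounds <- qc_limits()$bounds
  next_rid <- max(meas$rid) + 1L

  # implausible values: push the value outside the trait plausibility bounds
  imp <- which(stats::runif(nrow(meas)) < rates[["implausible"]])
  if (length(imp)) {
    for (r in imp) {
      b <- bounds[[meas$trait[r]]]
      low <- stats::runif(1) < 0.5
      meas$value[r] <- if (low) stats::runif(1, 0.2 * b[1], 0.9 * b[1])
        else stats::runif(1, 1.1 * b[2], 1.8 * b[2])
    }
    ledger <- rbind(ledger, data.frame(type = "implausible",
                                       id = meas$id[imp], rid = meas$rid[imp]))
  }

  # extreme jumps: inflate a non-first observation with a short gap to its
  # predecessor so the per-year relative change is large by construction
  ord <- order(meas$id, meas$trait, meas$day)
  om <- meas[ord, ]
  prev_same <- c(FALSE, om$id[-1] == om$id[-nrow(om)] &
                   om$trait[-1] == om$trait[-nrow(om)])
  gap <- c(NA, diff(om$age_years))
  gap[!prev_same] <- NA
  eligible <- om$rid[!is.na(gap) & gap > 0 & gap <= 1 &
                       !om$rid %in% ledger$rid]
  n_jmp <- min(stats::rbinom(1, nrow(meas), rates[["jump"]]), length(eligible))
  jmp <- if (n_jmp > 0) sample(eligible, n_jmp) else integer(0)
  if (length(jmp)) {
    idx <- match(jmp, meas$rid)
    g <- gap[match(jmp, om$rid)]
    meas$value[idx] <- meas$value[idx] * (1 + 2 * pmax(g, 0.1))
    ledger <- rbind(ledger, data.frame(type = "jump", id = meas$id[idx],
                                       rid = jmp))
  }

  # same-day duplicates: add a second record on an existing day, placed
  # beyond the individual's value range so it is always the one removed
  dup <- which(stats::runif(nrow(meas)) < rates[["duplicate"]])
  if (length(dup)) {
    add <- meas[dup, , drop = FALSE]
    for (k in seq_along(dup)) {
      iv <- meas$value[meas$id == add$id[k] & meas$trait == add$trait[k]]
      add$value[k] <- max(iv) + (max(iv) - min(iv)) + 5
    }
    add$rid <- seq.int(next_rid, length.out = nrow(add))
    next_rid <- next_rid + nrow(add)
    meas <- rbind(meas, add)
    ledger <- rbind(ledger, data.frame(type = "duplicate", id = add$id,
                                       rid = add$rid))
  }

  # bariatric surgery events; ~30% have no determinable date
  ids <- unique(meas$id)
  bar <- ids[stats::runif(length(ids)) < rates[["bariatric"]]]
  if (length(bar)) {
    ev <- data.frame(id = bar, age_years = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_along(bar)) {
      ages <- meas$age_years[meas$id == bar[k]]
      if (stats::runif(1) > 0.3)
        ev$age_years[k] <- stats::runif(1, min(ages), max(ages) + 1)
      aff <- meas$rid[meas$id == bar[k] &
                        (is.na(ev$age_years[k]) | meas$age_years > ev$age_years[k])]
      if (length(aff))
        ledger <- rbind(ledger, data.frame(type = "bariatric", id = bar[k],
                                           rid = aff))
    }
    events <- ev
  }
  rownames(meas) <- NULL
  list(measurements = meas, ledger = ledger, events = events)
}
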