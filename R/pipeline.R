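#' Pipeline configuration
#'
#' One configuration object driving [run_pipeline()] end to end: synthetic
#' cohort settings, QC limits, spline design and prior, clustering settings,
#' stage toggles, analysis strata and a single global seed from which every
#' stage derives a named sub-seed.
#'
#' @param out_dir directory for artifacts (created if needed).
#' @param sim a [sim_config()] (the input data source).
#' @param limits a [qc_limits()].
#' @param design_T,design_ndf spline design horizon (days) and dimension.
#' @param prior_args list passed to [smoothing_prior()].
#' @param clustering a [cluster_config()].
#' @param strata subset of `c("combined", "female", "male")`.
#' @param stages named logical vector toggling `qc`, `lme`, `spline`
#'   (includes clustering), `assoc`.
#' @param seed global seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("trajphen_run_"),
                            sim = sim_config(),
                            limits = qc_limits(),
                            design_T = 7500, design_ndf = 100,
                            prior_args = list(),
                            clustering = cluster_config(),
                            strata = "combined",
                            stages = c(qc = TRUE, lme = TRUE,
                                       spline = TRUE, assoc = TRUE),
                            seed = 1L) {
  strata <- match.arg(strata, c("combined", "female", "male"),
                      several.ok = TRUE)
  if (!length(strata)) stop("strata must be non-empty")
  st <- c(qc = TRUE, lme = TRUE, spline = TRUE, assoc = TRUE)
  st[names(stages)] <- stages
  structure(list(out_dir = out_dir, sim = sim, limits = limits,
                 design_T = design_T, design_ndf = design_ndf,
                 prior_args = prior_args, clustering = clustering,
                 strata = strata, stages = st, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) seed_hash(config$seed, stage)

#' Run the full phenotype-derivation pipeline
#'
#' Simulates (or accepts) a cohort, applies longitudinal QC, derives LME
#' intercept/slope traits, fits spline posteriors and trains the trajectory
#' clustering, scores soft memberships and cluster traits, and runs the SNP
#' association stage — per analysis stratum. Every artifact is written under
#' `config$out_dir` and recorded, with an MD5 checksum, in the returned
#' manifest. A failing stage halts with the stage name; artifacts written so
#' far remain on disk.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (the [simulate_cohort()] return
#'   shape); when NULL one is simulated from `config$sim`.
#' @return data.frame manifest: `stage`, `stratum`, `artifact`, `path`,
#'   `md5`, plus attribute `"log"` with per-stage row counts.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log <- list()
  emit <- function(stage, stratum, artifact, path) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, stratum = stratum, artifact = artifact, path = path,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(cohort)) {
    cohort <- run_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- stage_seed(config, "simulate")
      sc <- simulate_cohort(cfg)
      inj <- inject_artifacts(sc$measurements, cfg)
      sc$measurements <- inj$measurements
      sc$ledger <- inj$ledger
      sc$events <- inj$events
      sc
    })
    side <- list(seed = stage_seed(config, "simulate"),
                 n_individuals = config$sim$n_individuals,
                 trait = config$sim$trait)
    write_tsv_artifact(cohort$measurements,
                       file.path(config$out_dir, "measurements.tsv"), side)
    write_tsv_artifact(cohort$covariates,
                       file.path(config$out_dir, "covariates.tsv"), side)
    emit("simulate", "all", "measurements",
         file.path(config$out_dir, "measurements.tsv"))
    emit("simulate", "all", "covariates",
         file.path(config$out_dir, "covariates.tsv"))
    if (!is.null(cohort$genotypes)) {
      write_dosage(cohort$genotypes,
                   file.path(config$out_dir, "genotypes.tsv"), side)
      emit("simulate", "all", "genotypes",
           file.path(config$out_dir, "genotypes.tsv"))
    }
  }

  meas <- cohort$measurements
  log$rows_simulated <- nrow(meas)
  if (config$stages[["qc"]]) {
    qc <- run_stage("qc", run_qc(meas, cohort$events, config$limits))
    meas <- qc$measurements
    jsonlite::write_json(qc$report[c("rows_in", "rows_out", "removed",
                                     "individuals_removed")],
                         file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("qc", "all", "report", file.path(config$out_dir, "qc_report.json"))
    log$rows_after_qc <- nrow(meas)
  }

  cov <- cohort$covariates
  for (stratum in config$strata) {
    ids_str <- if (stratum == "combined") cov$id else
      cov$id[cov$sex == if (stratum == "female") "F" else "M"]
    meas_s <- meas[meas$id %in% ids_str, , drop = FALSE]
    traits <- NULL
    if (config$stages[["lme"]]) {
      fit <- run_stage("lme", fit_lme(meas_s, cov, stratum = stratum))
      traits <- run_stage("lme", derive_adjusted_traits(fit, cov))
      jsonlite::write_json(
        list(stratum = stratum, fixef = as.list(fit$fixef),
             varcomp = as.list(fit$varcomp), converged = fit$converged,
             logLik = fit$logLik),
        file.path(config$out_dir, paste0("lme_fit_", stratum, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit("lme", stratum, "fit_summary",
           file.path(config$out_dir, paste0("lme_fit_", stratum, ".json")))
      for (tr in c("u0_int", "u1_int")) {
        p <- file.path(config$out_dir,
                       paste0("pheno_", tr, "_", stratum, ".txt"))
        write_phenotype(stats::setNames(traits[[tr]], traits$id), p)
        emit("lme", stratum, tr, p)
      }
    }

    pi_mat <- NULL; ctr <- NULL
    if (config$stages[["spline"]]) {
      res <- run_stage("spline", {
        pre <- preprocess_residuals(meas_s, cov)
        design <- build_design(config$design_T, config$design_ndf)
        prior <- do.call(smoothing_prior,
                         c(config$prior_args, list(n_df = config$design_ndf)))
        fits <- fit_posteriors(pre, design, prior)
        sigma2 <- estimate_noise_variance(fits, design)
        post <- collect_posteriors(fits, sigma2)
        ccfg <- config$clustering
        ccfg$seed <- stage_seed(config, paste0("cluster_", stratum))
        set.seed(ccfg$seed)
        train_ids <- sample(post$ids,
                            round(ccfg$train_fraction * length(post$ids)))
        tr_ix <- which(post$ids %in% train_ids)
        post_train <- subset_posteriors(post, tr_ix)
        model <- train_clusters(post_train, design, ccfg)
        pi_all <- soft_memberships(post, model, seed = ccfg$seed)
        list(model = model, pi = pi_all, sigma2 = sigma2)
      })
      pi_mat <- res$pi
      ctr <- cluster_traits(pi_mat, config$clustering$n_mc)
      cpath <- file.path(config$out_dir,
                         paste0("centroids_", stratum, ".tsv"))
      write_tsv_artifact(as.data.frame(res$model$centroids), cpath,
                         sidecar = list(sigma2 = res$sigma2,
                                        K = config$clustering$K))
      emit("cluster", stratum, "centroids", cpath)
      for (tr in colnames(ctr)) {
        p <- file.path(config$out_dir,
                       paste0("pheno_cluster_", tr, "_", stratum, ".txt"))
        write_phenotype(stats::setNames(ctr[, tr], rownames(ctr)), p)
        emit("cluster", stratum, tr, p)
      }
    }

    if (config$stages[["assoc"]] && !is.null(cohort$genotypes)) {
      run_stage("assoc", {
        cov_s <- cov[match(ids_str, cov$id), , drop = FALSE]
        base_adj <- data.frame(
          baseline_age = cov_s$baseline_age,
          baseline_age2 = cov_s$baseline_age^2,
          year_of_birth = cov_s$year_of_birth)
        if (stratum == "combined" && length(unique(cov_s$sex)) > 1)
          base_adj$sex <- cov_s$sex
        if (length(unique(cov_s$assessment_centre)) > 1)
          base_adj$assessment_centre <- cov_s$assessment_centre
        todo <- list()
        if (!is.null(traits)) {
          tr_ix <- match(ids_str, traits$id)
          todo$u0_int <- traits$u0_int[tr_ix]
          todo$u1_int <- traits$u1_int[tr_ix]
        }
        if (!is.null(pi_mat)) {
          ct_ix <- match(ids_str, rownames(pi_mat))
          ctm <- cluster_traits(pi_mat, config$clustering$n_mc)
          for (tr in colnames(ctm)) todo[[paste0("cluster_", tr)]] <-
              ctm[ct_ix, tr]
        }
        first_val <- tapply(meas_s$value[order(meas_s$day)],
                            meas_s$id[order(meas_s$day)], function(v) v[1])
        for (tr in names(todo)) {
          keep <- !is.na(todo[[tr]])
          adj <- base_adj[keep, , drop = FALSE]
          if (startsWith(tr, "cluster_")) {
            adj$baseline_trait <- as.numeric(first_val[ids_str])[keep]
            if (!is.null(traits)) {
              tr_ix2 <- match(ids_str, traits$id)
              adj$n_followups <- traits$n_followups[tr_ix2][keep]
              adj$followup_years <- traits$followup_years[tr_ix2][keep]
            }
          }
          res <- linear_assoc(todo[[tr]][keep],
                              cohort$genotypes[ids_str[keep], , drop = FALSE],
                              adj, stratum = stratum)
          p <- file.path(config$out_dir,
                         paste0("sumstats_", tr, "_", stratum, ".tsv"))
          write_sumstats(res, p, maf = cohort$maf,
                         or = startsWith(tr, "cluster_"))
          emit("assoc", stratum, tr, p)
        }
      })
    }
  }
  out <- do.call(rbind, manifest)
  attr(out, "log") <- log
  out
}

#' Subset a spline_posteriors container
#'
#' @param post a [collect_posteriors()] object.
#' @param ix integer index of individuals to keep.
#' @return a `spline_posteriors` object restricted to `ix`.
#' @export
subset_posteriors <- function(post, ix) {
  structure(list(ids = post$ids[ix], M = post$M[ix, , drop = FALSE],
                 BM = post$BM[ix, , drop = FALSE],
                 BVd = post$BVd[ix, , drop = FALSE],
                 n_obs = post$n_obs[ix], sigma2 = post$sigma2,
                 Vlist = if (is.null(post$Vlist)) NULL else post$Vlist[ix]),
            class = "spline_posteriors")
}
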