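#' Collect per-individual spline posteriors into a cohort container
#'
#' Precomputes the quantities the clustering stage needs: baselined posterior
#' means D m_i, the diagonal of the baselined unit-scale covariance
#' D V_i D^T, raw means (for fold-change initialisation scores), and
#' optionally the full covariances (required for Monte-Carlo soft
#' membership).
#'
#' @param fits named list from [fit_posteriors()].
#' @param sigma2 plug-in noise variance ([estimate_noise_variance()]).
#' @param keep_cov keep full V_i matrices (memory ~ n_df^2 doubles per
#'   individual); required by [soft_memberships()].
#' @return object of class `"spline_posteriors"`: list with `ids`, `M` (raw
#'   means, n x n_df), `BM` (baselined means), `BVd` (baselined unit-scale
#'   variance diagonals), `n_obs`, `sigma2`, `Vlist` (or NULL).
#' @export
collect_posteriors <- function(fits, sigma2, keep_cov = TRUE) {
  ids <- names(fits)
  M <- t(vapply(fits, function(f) f$m, numeric(length(fits[[1]]$m))))
  BM <- M - M[, 1]
  BVd <- t(vapply(fits, function(f) {
    diag(f$V) + f$V[1, 1] - 2 * f$V[, 1]
  }, numeric(ncol(M))))
  BVd[, 1] <- 0
  BM[, 1] <- 0
  structure(list(ids = ids, M = M, BM = BM, BVd = BVd,
                 n_obs = vapply(fits, function(f) length(f$y), 0L),
                 sigma2 = sigma2,
                 Vlist = if (keep_cov) lapply(fits, `[[`, "V") else NULL),
            class = "spline_posteriors")
}

#' Scaled pairwise distance between individuals' trajectories
#'
#' Heteroscedasticity-aware Euclidean distance in baselined-coefficient
#' space:
#' \deqn{d(i,i') = \sqrt{\sum_k \frac{([Dm_i]_k - [Dm_{i'}]_k)^2}
#'   {([DV_iD^T]_{kk} + [DV_{i'}D^T]_{kk})\,\sigma^2}}}
#' Each coordinate's squared difference is standardised by the summed
#' posterior variances, so precisely estimated coefficients weigh more. The
#' first (baselined) coordinate has zero numerator and zero variance and
#' contributes 0 by definition; a zero variance at any other coordinate
#' signals a degenerate posterior and is an error.
#'
#' @param post a [collect_posteriors()] object.
#' @param subset optional integer index of individuals.
#' @return symmetric distance matrix.
#' @export
pairwise_distance <- function(post, subset = NULL) {
  stopifnot(inherits(post, "spline_posteriors"))
  BM <- post$BM; BVd <- post$BVd
  if (!is.null(subset)) {
    BM <- BM[subset, , drop = FALSE]
    BVd <- BVd[subset, , drop = FALSE]
  }
  if (ncol(BVd) > 1 && any(BVd[, -1] <= 0))
    stop("zero posterior variance at a non-baseline coefficient: ",
         "degenerate posterior")
  dist_scaled_cpp(t(BM), t(BVd * post$sigma2))
}

#' Fold-change scores and quantile-bin initialisation
#'
#' Scores each individual by the fold change of the fitted (un-baselined)
#' trajectory between baseline and year M: the ratio of the fitted value at
#' day round(365.25 M) to the fitted value at day 0. Individuals are then
#' partitioned into K bins by the empirical quantiles of the score; bin 1
#' holds the highest scores (largest gain).
#'
#' @param post a [collect_posteriors()] object.
#' @param design the shared [build_design()].
#' @param M_years initialisation horizon in years (default 2).
#' @return numeric score vector.
#' @export
fold_change_scores <- function(post, design, M_years = 2) {
  day <- round(365.25 * M_years)
  if (day > design$T_days) stop("M_years exceeds the design horizon T")
  f0 <- drop(post$M %*% design$basis[1L, ])
  fM <- drop(post$M %*% design$basis[day + 1L, ])
  fM / f0
}

#' @rdname fold_change_scores
#' @param scores numeric scores (highest = bin 1).
#' @param K number of bins.
#' @return `initialize_bins`: integer bin labels in 1..K.
#' @export
initialize_bins <- function(scores, K) {
  if (length(unique(scores)) == 1L) {
    warning("all scores equal: every individual in one bin")
    return(rep(1L, length(scores)))
  }
  r <- rank(-scores, ties.method = "average")
  as.integer(ceiling(K * r / length(scores)))
}

#' Clustering configuration
#'
#' @param K number of clusters (default 4).
#' @param L minimum number of observations to enter training (default 2).
#' @param M_years fold-change initialisation horizon (default 2).
#' @param S number of repeated training runs (default 10).
#' @param subsample per-run subsample size (default 5000; clamped with a
#'   warning if the training set is smaller).
#' @param n_mc Monte-Carlo samples for soft membership (default 100).
#' @param train_fraction training split fraction (default 0.8).
#' @param seed integer seed.
#' @return list of class `"cluster_config"`.
#' @export
cluster_config <- function(K = 4, L = 2, M_years = 2, S = 10,
                           subsample = 5000, n_mc = 100,
                           train_fraction = 0.8, seed = 1L) {
  if (K < 2) stop("K must be >= 2")
  if (L < 1) stop("L must be >= 1")
  structure(list(K = as.integer(K), L = as.integer(L), M_years = M_years,
                 S = as.integer(S), subsample = as.integer(subsample),
                 n_mc = as.integer(n_mc), train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Train averaged ordered cluster centroids by repeated PAM
#'
#' Runs PAM (k-medoids) S times, each on a random subsample (without
#' replacement) of the training individuals with at least L observations,
#' using the scaled distance ([pairwise_distance()]) and initial medoids
#' taken from the fold-change quantile bins. Each run's cluster means (the
#' averages of members' baselined coefficient vectors) are ordered
#' point-wise from highest (gain) to lowest (loss) and averaged across runs,
#' with point-wise SEs. Runs whose centroid curves cross are ordered by their
#' grid mean and flagged.
#'
#' @param post a [collect_posteriors()] object for the TRAINING individuals.
#' @param design shared [build_design()] (for initialisation scores).
#' @param config a [cluster_config()].
#' @return object of class `"cluster_model"`: `centroids` (K x n_df, row 1 =
#'   highest), `se` (K x n_df), `per_run` (list of K x n_df), `crossings`
#'   (logical per run), `config`.
#' @export
train_clusters <- function(post, design, config = cluster_config()) {
  stopifnot(inherits(post, "spline_posteriors"),
            inherits(config, "cluster_config"))
  keep <- which(post$n_obs >= config$L)
  n <- length(keep)
  if (n < config$K) stop("fewer eligible individuals than clusters")
  sub_n <- config$subsample
  if (sub_n > n) {
    warning("subsample size clamped to training-set size ", n)
    sub_n <- n
  }
  K <- config$K
  per_run <- vector("list", config$S)
  crossings <- logical(config$S)
  scores_all <- fold_change_scores(post, design, config$M_years)
  for (s in seq_len(config$S)) {
    set.seed(config$seed + 1000L * s)
    idx <- keep[sample.int(n, sub_n)]
    D <- pairwise_distance(post, idx)
    bins <- initialize_bins(scores_all[idx], K)
    med <- integer(0)
    if (length(unique(bins)) == K) {
      med <- vapply(seq_len(K), function(k) {
        members <- which(bins == k)
        members[which.min(colSums(D[members, members, drop = FALSE]))]
      }, 0L)
    }
    pm <- cluster::pam(stats::as.dist(D), k = K,
                       medoids = if (length(med)) med else NULL,
                       diss = TRUE, pamonce = 5)
    means <- t(vapply(seq_len(K), function(k) {
      colMeans(post$BM[idx[pm$clustering == k], , drop = FALSE])
    }, numeric(ncol(post$BM))))
    ord <- order(rowMeans(means), decreasing = TRUE)
    means <- means[ord, , drop = FALSE]
    # point-wise dominance check beyond the all-zero baseline coordinate
    dom <- TRUE
    for (k in seq_len(K - 1))
      dom <- dom && all(means[k, -1] >= means[k + 1, -1])
    crossings[s] <- !dom
    per_run[[s]] <- means
  }
  if (any(crossings))
    warning(sum(crossings), " run(s) had crossing centroid curves; ",
            "ordered by grid mean")
  arr <- simplify2array(per_run)            # K x n_df x S
  centroids <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(config$S)
  structure(list(centroids = centroids, se = se, per_run = per_run,
                 crossings = crossings, config = config),
            class = "cluster_model")
}

#' Monte-Carlo soft cluster membership for one individual
#'
#' Draws `n_mc` samples from the baselined coefficient posterior
#' MVN(D m_i, sigma2 D V_i D^T) (by sampling b ~ MVN(m_i, sigma2 V_i) and
#' baselining, which is exact) and returns the fraction of samples whose
#' nearest centroid in unscaled Euclidean distance is each of the K
#' centroids. Ties go to the lower cluster index. The memberships are
#' empirical frequencies and sum to 1 exactly.
#'
#' @param m,V posterior mean and unit-scale covariance.
#' @param sigma2 noise variance.
#' @param centroids K x n_df matrix of ordered centroids.
#' @param n_mc number of Monte-Carlo samples.
#' @param seed integer seed for this individual's draws.
#' @return numeric K-vector of membership probabilities.
#' @export
soft_membership <- function(m, V, sigma2, centroids, n_mc = 100, seed = 1L) {
  ch <- tryCatch(chol(V), error = function(e)
    stop("posterior covariance is not positive definite"))
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(length(m) * n_mc), nrow = length(m))
  b <- m + sqrt(sigma2) * crossprod(ch, z)       # n_df x n_mc samples of b
  bt <- sweep(b, 2, b[1, ], "-")                 # baselined samples
  # squared distances to each centroid, dropping the per-sample ||b||^2 term
  # (constant within a sample, so the argmin and its ties are unchanged)
  cc <- rowSums(centroids^2)
  d2 <- cc - 2 * centroids %*% bt
  nearest <- apply(d2, 2, which.min)             # lower index wins ties
  tabulate(nearest, nbins = nrow(centroids)) / n_mc
}

#' Soft memberships for a cohort
#'
#' Applies [soft_membership()] to every individual, seeding each
#' individual's draws from a hash of the global seed and the individual id,
#' so results do not depend on iteration order.
#'
#' @param post a [collect_posteriors()] object with `Vlist` retained.
#' @param model a [train_clusters()] model.
#' @param n_mc Monte-Carlo samples (default from model config).
#' @param seed global seed.
#' @return n x K matrix of memberships, rownames = id.
#' @export
soft_memberships <- function(post, model, n_mc = NULL, seed = 1L) {
  stopifnot(inherits(post, "spline_posteriors"),
            inherits(model, "cluster_model"))
  if (is.null(post$Vlist))
    stop("posterior covariances were not retained; ",
         "rerun collect_posteriors(keep_cov = TRUE)")
  if (is.null(n_mc)) n_mc <- model$config$n_mc
  out <- matrix(NA_real_, length(post$ids), nrow(model$centroids),
                dimnames = list(post$ids, NULL))
  for (i in seq_along(post$ids)) {
    out[i, ] <- soft_membership(post$M[i, ], post$Vlist[[i]], post$sigma2,
                                model$centroids, n_mc,
                                seed = seed_hash(seed, post$ids[i]))
  }
  out
}

# deterministic 31-bit hash of (seed, id) for order-independent per-individual
# random streams
seed_hash <- function(seed, id) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(id)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Hard (nearest-centroid) assignment of posterior means
#'
#' @param post a [collect_posteriors()] object.
#' @param centroids K x n_df centroid matrix.
#' @return integer cluster labels.
#' @export
hard_assign <- function(post, centroids) {
  d2 <- rowSums(centroids^2) - 2 * centroids %*% t(post$BM)
  as.integer(apply(d2, 2, which.min))
}

#' Bounded logit transform
#'
#' \deqn{\mathrm{boundedlogit}(\pi) = \mathrm{logit}\{((S-1)\pi + 0.5)/S\}}
#' keeps the log-odds finite at pi in {0, 1}; S is the number of Monte-Carlo
#' samples behind the membership estimate (default 100), so the transform's
#' bounds match the granularity of the estimated probabilities.
#'
#' @param p probabilities in [0, 1].
#' @param S_mc Monte-Carlo sample count.
#' @return numeric vector; odd about p = 0.5, with boundedlogit(0.5) = 0.
#' @export
bounded_logit <- function(p, S_mc = 100) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  q <- ((S_mc - 1) * p + 0.5) / S_mc
  log(q / (1 - q))
}

#' Cumulative bounded-logit cluster traits
#'
#' The three GWAS-ready cluster traits: bounded log odds of membership of the
#' highest cluster, the highest two, and the highest three.
#'
#' @param pi_mat n x K membership matrix ([soft_memberships()]).
#' @param S_mc Monte-Carlo sample count behind the memberships.
#' @return n x 3 matrix, columns `k1`, `k1_2`, `k1_3`.
#' @export
cluster_traits <- function(pi_mat, S_mc = 100) {
  if (ncol(pi_mat) < 4) stop("expected at least 4 membership columns")
  out <- cbind(
    k1 = bounded_logit(pi_mat[, 1], S_mc),
    k1_2 = bounded_logit(pi_mat[, 1] + pi_mat[, 2], S_mc),
    k1_3 = bounded_logit(pi_mat[, 1] + pi_mat[, 2] + pi_mat[, 3], S_mc)
  )
  rownames(out) <- rownames(pi_mat)
  out
}

#' Silhouette evaluation of a hard clustering
#'
#' Standard silhouette widths on the scaled distance matrix; used by the
#' sensitivity harness over K, L and M.
#'
#' @param distances symmetric distance matrix.
#' @param labels integer cluster labels.
#' @return list with `mean` and `per_cluster` (data.frame cluster, size,
#'   mean_width).
#' @export
silhouette_eval <- function(distances, labels) {
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters")
  if (all(tab == 1)) stop("all clusters are singletons")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dmatrix = as.matrix(distances))
  sw <- sil[, "sil_width"]
  per <- data.frame(cluster = as.integer(names(tab)), size = as.integer(tab),
                    mean_width = as.numeric(tapply(sw, labels, mean)))
  list(mean = mean(sw), per_cluster = per)
}

#' Sensitivity of the clustering to K, L and M
#'
#' Re-trains the clustering over a grid of cluster counts K, minimum
#' measurement filters L and initialisation horizons M, reporting the mean
#' silhouette of the resulting hard assignments.
#'
#' @param post training [collect_posteriors()].
#' @param design shared [build_design()].
#' @param K_grid,L_grid,M_grid parameter grids.
#' @param base_config base [cluster_config()] supplying S, subsample, seed.
#' @return data.frame with one row per combination.
#' @export
cluster_sensitivity <- function(post, design, K_grid = 2:8,
                                L_grid = c(2, 5, 10),
                                M_grid = c(1, 2, 5, 10),
                                base_config = cluster_config()) {
  grid <- expand.grid(K = K_grid, L = L_grid, M_years = M_grid)
  grid$mean_silhouette <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg <- cluster_config(K = grid$K[r], L = grid$L[r],
                          M_years = grid$M_years[r], S = base_config$S,
                          subsample = base_config$subsample,
                          n_mc = base_config$n_mc,
                          train_fraction = base_config$train_fraction,
                          seed = base_config$seed)
    res <- try({
      model <- train_clusters(post, design, cfg)
      keep <- which(post$n_obs >= cfg$L)
      labels <- hard_assign(post, model$centroids)[keep]
      D <- pairwise_distance(post, keep)
      silhouette_eval(D, labels)$mean
    }, silent = TRUE)
    if (!inherits(res, "try-error")) grid$mean_silhouette[r] <- res
  }
  grid
}

#' Compare cluster properties between training and hold-out splits
#'
#' Scores both splits against the same centroids (hard assignment by highest
#' membership) and tabulates, per cluster and split, the assigned proportion
#' and the distributions of sex, baseline age, number of follow-ups and
#' total follow-up length.
#'
#' @param train_pi,holdout_pi membership matrices from [soft_memberships()].
#' @param train_cov,holdout_cov covariate tables (rows matched by id to the
#'   membership rownames) with `sex`, `baseline_age`; follow-up columns
#'   `n_followups`, `followup_years` are used when present.
#' @return data.frame with 2K rows (split x cluster).
#' @export
validate_split <- function(train_pi, holdout_pi, train_cov, holdout_cov) {
  if (!nrow(train_pi) || !nrow(holdout_pi)) stop("empty split")
  one <- function(pi_mat, cov, split) {
    hard <- max.col(pi_mat, ties.method = "first")
    cov <- cov[match(rownames(pi_mat), cov$id), , drop = FALSE]
    do.call(rbind, lapply(seq_len(ncol(pi_mat)), function(k) {
      sel <- hard == k
      data.frame(split = split, cluster = k,
                 proportion = mean(sel),
                 n = sum(sel),
                 prop_female = if (any(sel)) mean(cov$sex[sel] == "F") else NA,
                 mean_baseline_age = if (any(sel))
                   mean(cov$baseline_age[sel]) else NA,
                 mean_followups = if (any(sel) && !is.null(cov$n_followups))
                   mean(cov$n_followups[sel]) else NA,
                 mean_followup_years = if (any(sel) &&
                                           !is.null(cov$followup_years))
                   mean(cov$followup_years[sel]) else NA)
    }))
  }
  rbind(one(train_pi, train_cov, "train"),
        one(holdout_pi, holdout_cov, "holdout"))
}

#' Adjusted Rand index between two clusterings
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
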