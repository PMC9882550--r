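toy_posteriors <- function(BM, BVd, sigma2 = 1) {
  n <- nrow(BM)
  structure(list(ids = sprintf("t%03d", seq_len(n)), M = BM, BM = BM,
                 BVd = BVd, n_obs = rep(5L, n), sigma2 = sigma2,
                 Vlist = NULL), class = "spline_posteriors")
}

test_that("scaled distance matches hand evaluation and its axioms", {
  BM <- rbind(c(0, 0), c(0, 3))
  BVd <- rbind(c(0, 0.5), c(0, 0.5))
  post <- toy_posteriors(BM, BVd, sigma2 = 1)
  D <- pairwise_distance(post)
  # k=1 contributes 0 (baselined); k=2: 9 / ((0.5+0.5)*1) = 9 -> d = 3
  expect_equal(D[1, 2], 3)
  expect_equal(D[2, 1], 3)
  expect_equal(diag(D), c(0, 0))
  post_bad <- toy_posteriors(BM, rbind(c(0, 0), c(0, 0.5)))
  expect_error(pairwise_distance(post_bad), "zero posterior variance")
})

test_that("scaled distance agrees with a direct R evaluation", {
  set.seed(10)
  n <- 15; p <- 8
  BM <- cbind(0, matrix(rnorm(n * (p - 1)), n))
  BVd <- cbind(0, matrix(abs(rnorm(n * (p - 1))) + 0.1, n))
  post <- toy_posteriors(BM, BVd, sigma2 = 0.7)
  D <- pairwise_distance(post)
  for (i in c(1, 7)) for (j in c(3, 12)) {
    ref <- sqrt(sum((BM[i, -1] - BM[j, -1])^2 /
                      ((BVd[i, -1] + BVd[j, -1]) * 0.7)))
    expect_equal(D[i, j], ref, tolerance = 1e-12)
  }
})

test_that("quantile bins partition scores with highest scores in bin 1", {
  expect_equal(initialize_bins(c(8, 7, 6, 5, 4, 3, 2, 1), K = 4),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(initialize_bins(c(1.2, 1.1, 1.0, 0.9), K = 2),
               c(1L, 1L, 2L, 2L))
  expect_warning(bins <- initialize_bins(rep(1, 6), K = 3), "one bin")
  expect_equal(bins, rep(1L, 6))
})

test_that("fold-change scores respect the design horizon", {
  des <- build_design(T_days = 400, n_df = 8)
  post <- toy_posteriors(matrix(rnorm(16), 2), matrix(0.1, 2, 8))
  expect_error(fold_change_scores(post, des, M_years = 2), "horizon")
})

test_that("training is deterministic and a single run averages to itself", {
  sc <- simulate_cohort(separated_config(300, 23))
  des <- build_design(T_days = 7500, n_df = 40)
  pri <- smoothing_prior(n_df = 40)
  post <- cohort_posteriors(sc, des, pri, keep_cov = FALSE)
  cfg <- cluster_config(S = 1, subsample = 300, seed = 5)
  m1 <- suppressWarnings(train_clusters(post, des, cfg))
  m2 <- suppressWarnings(train_clusters(post, des, cfg))
  expect_identical(m1$centroids, m2$centroids)
  expect_equal(m1$centroids, m1$per_run[[1]])
})

test_that("well-separated shapes are recovered by PAM training", {
  sc <- simulate_cohort(separated_config(600, 29))
  des <- build_design(T_days = 7500, n_df = 40)
  pri <- smoothing_prior(n_df = 40)
  post <- cohort_posteriors(sc, des, pri)
  cfg <- cluster_config(S = 3, subsample = 500, seed = 5)
  model <- train_clusters(post, des, cfg)
  pim <- soft_memberships(post, model, seed = 5)
  hard <- max.col(pim, ties.method = "first")
  truth <- sc$truth$cluster[match(rownames(pim), sc$truth$id)]
  expect_gt(adjusted_rand_index(hard, truth), 0.6)
  # centroids ordered from gain (1) down to loss (4)
  grid_means <- rowMeans(model$centroids)
  expect_true(all(diff(grid_means) < 0))
})

test_that("memberships are exact frequencies and sum to one", {
  centroids <- rbind(c(0, 2, 2), c(0, -2, -2))
  m <- c(0, 1.8, 1.9); V <- diag(3) * 0.01
  pi1 <- soft_membership(m, V, sigma2 = 1, centroids, n_mc = 100, seed = 2)
  expect_equal(sum(pi1), 1)
  expect_equal(pi1 * 100, round(pi1 * 100))
  expect_equal(pi1, c(1, 0))
  # degenerate covariance: indicator of the nearest centroid
  pi2 <- soft_membership(c(0, -1, -1), diag(3) * 1e-12, 1, centroids,
                         n_mc = 50, seed = 3)
  expect_equal(pi2, c(0, 1))
})

test_that("exact centroid ties send all mass to the lower index", {
  centroids <- rbind(c(0, 1, 0), c(0, 1, 0))  # identical: every sample ties
  pi_tie <- soft_membership(c(0, 0.4, 0), diag(3) * 1e-6, 1, centroids,
                            n_mc = 20, seed = 4)
  expect_equal(pi_tie, c(1, 0))
})

test_that("memberships are invariant to centroid relabeling + reordering", {
  set.seed(11)
  centroids <- rbind(c(0, 3, 3), c(0, 1, 1), c(0, -1, -1), c(0, -3, -3))
  m <- c(0, 0.5, 0.2); V <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  p1 <- soft_membership(m, V, 1, centroids, n_mc = 100, seed = 9)
  perm <- c(3, 1, 4, 2)
  p2 <- soft_membership(m, V, 1, centroids[perm, ], n_mc = 100, seed = 9)
  expect_equal(p2[order(perm)], p1)
})

test_that("hard assignment agrees with memberships when posteriors are tight", {
  sc <- simulate_cohort(separated_config(200, 31))
  des <- build_design(T_days = 7500, n_df = 40)
  pri <- smoothing_prior(n_df = 40)
  post <- cohort_posteriors(sc, des, pri)
  cfg <- cluster_config(S = 2, subsample = 200, seed = 6)
  model <- suppressWarnings(train_clusters(post, des, cfg))
  pim <- soft_memberships(post, model, seed = 6)
  agree <- mean(max.col(pim, ties.method = "first") ==
                  hard_assign(post, model$centroids))
  expect_gt(agree, 0.9)
})

test_that("bounded logit matches hand values and is odd about 0.5", {
  expect_equal(bounded_logit(0.5), 0)
  expect_equal(bounded_logit(0), log(0.005 / 0.995))
  expect_equal(bounded_logit(0), -5.2933, tolerance = 1e-4)
  expect_equal(bounded_logit(1), 5.2933, tolerance = 1e-4)
  p <- c(0.1, 0.3, 0.42)
  expect_equal(bounded_logit(p), -bounded_logit(1 - p))
  expect_error(bounded_logit(1.2), "0, 1")
})

test_that("cluster traits are the three cumulative bounded log odds", {
  pim <- rbind(c(0.7, 0.2, 0.1, 0), c(0.1, 0.2, 0.3, 0.4))
  ct <- cluster_traits(pim)
  expect_equal(dim(ct), c(2, 3))
  expect_equal(unname(ct[1, "k1"]), bounded_logit(0.7))
  expect_equal(unname(ct[2, "k1_3"]), bounded_logit(0.6))
  expect_true(all(is.finite(ct)))
})

test_that("silhouette separates geometry from noise", {
  set.seed(12)
  a <- matrix(rnorm(100, 0), 50); b <- matrix(rnorm(100, 10), 50)
  D <- as.matrix(dist(rbind(a, b)))
  lab <- rep(1:2, each = 50)
  expect_gt(silhouette_eval(D, lab)$mean, 0.7)
  # random labels on one cloud
  one <- matrix(rnorm(1000), 500)
  D1 <- as.matrix(dist(one))
  expect_lt(abs(silhouette_eval(D1, sample(1:2, 500, TRUE))$mean), 0.1)
  # a duplicate of a point in the other cluster has negative width
  x <- rbind(a, a[1, , drop = FALSE])
  Dx <- as.matrix(dist(x))
  labx <- c(rep(1, 50), 2)
  expect_error(silhouette_eval(Dx, labx), NA)
  expect_error(silhouette_eval(D, rep(1, 100)), "2 clusters")
})

test_that("negative silhouette for a point placed in the wrong cluster", {
  set.seed(13)
  a <- matrix(rnorm(60, 0, 0.5), 30); b <- matrix(rnorm(60, 8, 0.5), 30)
  D <- as.matrix(dist(rbind(a, b)))
  lab <- rep(1:2, each = 30)
  lab[1] <- 2  # point 1 sits in cloud a but is labelled b
  sil <- cluster::silhouette(lab, dmatrix = D)
  expect_lt(sil[1, "sil_width"], 0)
})

test_that("train/holdout comparison reports K rows per split", {
  set.seed(14)
  pim_tr <- matrix(runif(400), 100); pim_tr <- pim_tr / rowSums(pim_tr)
  rownames(pim_tr) <- sprintf("a%03d", 1:100)
  cov_tr <- data.frame(id = rownames(pim_tr),
                       sex = sample(c("F", "M"), 100, TRUE),
                       baseline_age = runif(100, 40, 60))
  rep1 <- validate_split(pim_tr, pim_tr, cov_tr, cov_tr)
  expect_equal(nrow(rep1), 8)
  tr <- rep1[rep1$split == "train", -1]; ho <- rep1[rep1$split == "holdout", -1]
  rownames(tr) <- rownames(ho) <- NULL
  expect_identical(tr, ho)
  expect_error(validate_split(pim_tr[0, , drop = FALSE], pim_tr,
                              cov_tr, cov_tr), "empty")
})

test_that("ARI matches the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(15)
  for (r in 1:5) {
    a <- sample(1:4, 60, TRUE); b <- sample(1:3, 60, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
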