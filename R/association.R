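#' Covariate-adjusted per-SNP linear association
#'
#' Ordinary least squares of a derived trait on each SNP's additive dosage,
#' adjusting for an arbitrary covariate matrix (the Frisch-Waugh projection
#' is used: trait and dosages are residualised on the covariates once, and
#' the per-SNP fit on the residuals reproduces the full multiple-regression
#' coefficient, SE and Wald P exactly, with the correct degrees of freedom).
#' Missing dosages are mean-imputed per SNP with a logged count.
#'
#' @param trait numeric trait vector (one value per individual).
#' @param genotypes n x p dosage matrix (0..2; NAs allowed).
#' @param covariates data.frame or model matrix of adjustment covariates
#'   (NULL for intercept-only adjustment).
#' @param stratum label stored in the result.
#' @return data.frame of class `"assoc_result"`: `snp`, `beta`, `se`, `p`,
#'   `n`, `n_imputed`, `stratum`. SNPs with all dosages missing or constant
#'   are skipped with a warning.
#' @export
linear_assoc <- function(trait, genotypes, covariates = NULL,
                         stratum = "combined") {
  if (is.null(dim(genotypes))) genotypes <- cbind(snp1 = genotypes)
  n <- length(trait)
  stopifnot(nrow(genotypes) == n)
  if (stats::sd(trait) == 0) stop("constant trait")
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  check_full_rank(X)
  qr_x <- qr(X)
  yr <- qr.resid(qr_x, trait)
  df <- n - ncol(X) - 1L

  snps <- colnames(genotypes)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(genotypes)))
  out <- vector("list", ncol(genotypes))
  skipped <- character(0)
  for (j in seq_len(ncol(genotypes))) {
    g <- as.numeric(genotypes[, j])
    miss <- is.na(g)
    if (all(miss)) { skipped <- c(skipped, snps[j]); next }
    if (any(miss)) g[miss] <- mean(g[!miss])
    if (stats::sd(g) == 0) { skipped <- c(skipped, snps[j]); next }
    gr <- qr.resid(qr_x, g)
    sgg <- sum(gr^2)
    beta <- sum(gr * yr) / sgg
    rss <- sum(yr^2) - beta^2 * sgg
    se <- sqrt(rss / df / sgg)
    tval <- beta / se
    out[[j]] <- data.frame(snp = snps[j], beta = beta, se = se,
                           p = 2 * stats::pt(-abs(tval), df),
                           n = n, n_imputed = sum(miss),
                           stratum = stratum, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped SNP(s) with missing or constant dosage: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp = character(), beta = numeric(), se = numeric(),
                      p = numeric(), n = integer(), n_imputed = integer(),
                      stratum = character(), stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", class(res))
  res
}

#' Sex-heterogeneity Z test
#'
#' Standardised difference between female- and male-specific effect
#' estimates of the same SNP:
#' \deqn{Z = \frac{\hat\beta^{(F)} - \hat\beta^{(M)}}
#'   {\sqrt{SE_{(F)}^2 + SE_{(M)}^2}}, \qquad P = 2\Phi(-|Z|).}
#'
#' @param beta_f,se_f female-specific effect and SE.
#' @param beta_m,se_m male-specific effect and SE.
#' @return data.frame with `z` and `p` (vectorised).
#' @export
sexhet_test <- function(beta_f, se_f, beta_m, se_m) {
  if (any(se_f <= 0) || any(se_m <= 0)) stop("standard errors must be > 0")
  z <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Median chi-squared power ratio between two analyses
#'
#' Per SNP, the Wald chi-squared is beta^2 / SE^2. Over the SNPs significant
#' in either result set at `threshold`, returns the median of
#' chi2_a / chi2_b together with the median sample-size ratio, which is the
#' ratio expected from sample size alone; a chi-squared ratio above the
#' sample-size ratio indicates a power gain beyond sample size.
#'
#' @param results_a,results_b `assoc_result` tables sharing SNP identifiers.
#' @param threshold significance threshold defining the SNP subset (default
#'   genome-wide, 5e-8).
#' @param snps optional explicit SNP subset overriding the threshold rule.
#' @return list with `median_chisq_ratio`, `median_n_ratio`, `n_snps`,
#'   `per_snp` (data.frame).
#' @export
chisq_power_ratio <- function(results_a, results_b, threshold = 5e-8,
                              snps = NULL) {
  m <- merge(results_a, results_b, by = "snp", suffixes = c("_a", "_b"))
  if (is.null(snps)) {
    m <- m[m$p_a < threshold | m$p_b < threshold, , drop = FALSE]
  } else {
    m <- m[m$snp %in% snps, , drop = FALSE]
  }
  if (!nrow(m)) stop("no SNPs in the comparison subset")
  chi_a <- (m$beta_a / m$se_a)^2
  chi_b <- (m$beta_b / m$se_b)^2
  list(median_chisq_ratio = stats::median(chi_a / chi_b),
       median_n_ratio = stats::median(m$n_a / m$n_b),
       n_snps = nrow(m),
       per_snp = data.frame(snp = m$snp, chisq_a = chi_a, chisq_b = chi_b,
                            ratio = chi_a / chi_b))
}

#' Incremental variance explained by a SNP block
#'
#' R-squared of the covariates-plus-SNPs model minus that of the
#' covariate-only model: the proportion of trait variance explained by the
#' SNPs over and above the covariates. Collinear SNP columns are dropped
#' with a warning.
#'
#' @param trait numeric trait vector.
#' @param genotypes n x p dosage matrix (missing dosages mean-imputed).
#' @param covariates optional covariate data.frame / matrix.
#' @return scalar incremental R-squared.
#' @export
variance_explained <- function(trait, genotypes, covariates = NULL) {
  if (is.null(dim(genotypes))) genotypes <- cbind(snp1 = genotypes)
  n <- length(trait)
  G <- apply(genotypes, 2, function(g) {
    g <- as.numeric(g)
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  X0 <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  X1 <- cbind(X0, G)
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    drop_ix <- q1$pivot[(q1$rank + 1):ncol(X1)]
    nm <- colnames(X1)[drop_ix]
    nm[is.na(nm) | nm == ""] <- paste0("column ", drop_ix[is.na(nm) | nm == ""])
    warning("dropping collinear SNP column(s): ", paste(nm, collapse = ", "))
    X1 <- X1[, -drop_ix, drop = FALSE]
  }
  tss <- sum((trait - mean(trait))^2)
  r2_0 <- 1 - sum(qr.resid(qr(X0), trait)^2) / tss
  r2_1 <- 1 - sum(qr.resid(qr(X1), trait)^2) / tss
  r2_1 - r2_0
}
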