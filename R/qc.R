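#' Quality-control limits for longitudinal trait measurements
#'
#' Thresholds applied by [population_qc()] and [individual_qc()]. Plausibility
#' bounds correspond to +/- 10% of typical assessment-centre extremes: BMI in
#' [10.9, 82.1] kg/m2, weight in [27, 217] kg. Population outliers are removed
#' beyond 5 SDs of the trait mean; extreme jumps beyond 3 SDs of the
#' population jump distribution.
#'
#' @param age_min,age_max adult age window in years.
#' @param bounds named list of `c(lo, hi)` plausibility bounds per trait.
#' @param outlier_sd population-level SD multiple.
#' @param jump_sd SD multiple for the jump filter.
#' @return list of class `"qc_limits"`.
#' @export
qc_limits <- function(age_min = 20, age_max = 80,
                      bounds = list(bmi = c(10.9, 82.1), weight = c(27, 217)),
                      outlier_sd = 5, jump_sd = 3) {
  if (age_min >= age_max) stop("age_min must be < age_max")
  for (b in bounds) if (b[1] >= b[2]) stop("plausibility bounds need lo < hi")
  if (outlier_sd <= 0 || jump_sd <= 0) stop("SD multiples must be > 0")
  structure(list(age_min = age_min, age_max = age_max, bounds = bounds,
                 outlier_sd = outlier_sd, jump_sd = jump_sd),
            class = "qc_limits")
}

new_qc_report <- function(rows_in, rows_out, removed, individuals_removed = 0L) {
  structure(list(rows_in = rows_in, rows_out = rows_out,
                 removed = removed, individuals_removed = individuals_removed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$rows_in, "rows in,", x$rows_out, "rows out\n")
  for (nm in names(x$removed))
    cat(sprintf("  %-12s %d\n", nm, x$removed[[nm]]))
  if (x$individuals_removed > 0)
    cat("  individuals fully removed:", x$individuals_removed, "\n")
  invisible(x)
}

#' Population-level quality control
#'
#' Applies, in order: removal of individuals with a bariatric-surgery code
#' (rows after a known surgery date are dropped; individuals with no
#' determinable date are dropped entirely), restriction to adult ages,
#' trait plausibility bounds, and a 5 SD population outlier filter whose SD is
#' computed after the preceding filters so that impossible values do not
#' inflate it.
#'
#' @param measurements long-format table with `id`, `trait`, `value`,
#'   `age_years` (a `rid` row-id column is preserved if present).
#' @param events optional bariatric event table (`id`, `age_years`; NA age
#'   means the date could not be determined).
#' @param limits a [qc_limits()] object.
#' @return list with `measurements` (cleaned) and `report` ([qc_limits()]
#'   per-rule removal counts).
#' @export
population_qc <- function(measurements, events = NULL, limits = qc_limits()) {
  stopifnot(inherits(limits, "qc_limits"))
  meas <- measurements
  rows_in <- nrow(meas)
  removed <- c(bariatric = 0L, age_window = 0L, plausibility = 0L,
               population_sd = 0L)
  individuals_removed <- 0L

  unknown <- setdiff(unique(meas$trait), names(limits$bounds))
  if (length(unknown))
    stop("no configured plausibility bounds for trait(s): ",
         paste(unknown, collapse = ", "))

  if (!is.null(events) && nrow(events)) {
    no_date <- events$id[is.na(events$age_years)]
    drop <- meas$id %in% no_date
    for (k in which(!is.na(events$age_years))) {
      drop <- drop | (meas$id == events$id[k] &
                        meas$age_years > events$age_years[k])
    }
    removed["bariatric"] <- sum(drop)
    individuals_removed <- individuals_removed +
      length(intersect(unique(meas$id), no_date))
    meas <- meas[!drop, , drop = FALSE]
  }

  drop <- meas$age_years < limits$age_min | meas$age_years > limits$age_max
  removed["age_window"] <- sum(drop)
  meas <- meas[!drop, , drop = FALSE]

  lo <- vapply(limits$bounds, `[`, 0, 1)[meas$trait]
  hi <- vapply(limits$bounds, `[`, 0, 2)[meas$trait]
  drop <- meas$value < lo | meas$value > hi
  removed["plausibility"] <- sum(drop)
  meas <- meas[!drop, , drop = FALSE]

  drop <- rep(FALSE, nrow(meas))
  for (tr in unique(meas$trait)) {
    sel <- meas$trait == tr
    m <- mean(meas$value[sel]); s <- stats::sd(meas$value[sel])
    if (is.finite(s) && s > 0)
      drop[sel] <- abs(meas$value[sel] - m) > limits$outlier_sd * s
  }
  removed["population_sd"] <- sum(drop)
  meas <- meas[!drop, , drop = FALSE]

  rownames(meas) <- NULL
  list(measurements = meas,
       report = new_qc_report(rows_in, nrow(meas), as.list(removed),
                              individuals_removed))
}

#' Per-pair jump statistic for one measurement series
#'
#' For a chronologically ordered series (y_j, t_j), j = 1..J, the jump for
#' each adjacent pair is
#' \deqn{P_j = \log_2\{ (|y_{j+1} - y_j| / y_j) / (t_{j+1} - t_j) \}}
#' i.e. the log2 relative change per year. Pairs with zero change return NA
#' (the "no-jump" sentinel), which callers exclude from the population jump
#' distribution; such pairs are never filtered.
#'
#' @param values measurement values, chronological order.
#' @param times ages (or times) in years, strictly increasing.
#' @return numeric vector of length `length(values) - 1`.
#' @export
compute_jump <- function(values, times) {
  j <- length(values)
  if (j < 2) stop("need at least 2 measurements")
  dt <- diff(times)
  if (any(dt <= 0))
    stop("non-positive time gap: same-day deduplication must run first")
  dy <- abs(diff(values))
  p <- log2((dy / values[-j]) / dt)
  p[dy == 0] <- NA_real_
  p
}

#' Individual-level quality control
#'
#' Two sequential rules, applied after [population_qc()]:
#' same-day duplicate records are collapsed by keeping the observation
#' closest to the individual's median value of the trait across all
#' time-points (ties keep the chronologically earlier record); then the jump
#' statistic ([compute_jump()]) is computed cohort-wide per trait, and for
#' every jump exceeding mean + `jump_sd` SDs of the population jump
#' distribution the member of the pair farther from the individual's median
#' is removed. Jump filtering is a single pass: the jump distribution and
#' exceedances are computed once, not iterated to convergence. Only the high
#' side is filtered (strongly negative jumps are tiny changes, not errors).
#'
#' @inheritParams population_qc
#' @return list with `measurements` and `report`.
#' @export
individual_qc <- function(measurements, limits = qc_limits()) {
  stopifnot(inherits(limits, "qc_limits"))
  meas <- measurements
  rows_in <- nrow(meas)
  removed <- c(same_day = 0L, jump = 0L)
  if (rows_in == 0)
    return(list(measurements = meas,
                report = new_qc_report(0L, 0L, as.list(removed))))

  if (is.null(meas$day)) meas$day <- round(meas$age_years * 365.25)
  ord <- order(meas$id, meas$trait, meas$day,
               if (!is.null(meas$rid)) meas$rid else seq_len(nrow(meas)))
  meas <- meas[ord, , drop = FALSE]
  key <- paste(meas$id, meas$trait, sep = "\r")

  # same-day dedup: keep the record closest to the individual's median
  med <- stats::ave(meas$value, key, FUN = stats::median)
  dist_med <- abs(meas$value - med)
  day_key <- paste(key, meas$day, sep = "\r")
  keep <- !duplicated(day_key)  # default: first row of each same-day group
  grp <- split(seq_len(nrow(meas)), day_key)
  for (g in grp) {
    if (length(g) < 2) next
    best <- g[which.min(dist_med[g])]  # which.min: earlier row wins ties
    keep[g] <- FALSE
    keep[best] <- TRUE
  }
  removed["same_day"] <- sum(!keep)
  meas <- meas[keep, , drop = FALSE]

  # cohort-wide jump distribution per trait, then single-pass filtering
  key <- paste(meas$id, meas$trait, sep = "\r")
  med <- stats::ave(meas$value, key, FUN = stats::median)
  series <- split(seq_len(nrow(meas)), key)
  jumps <- lapply(series, function(ix) {
    if (length(ix) < 2) return(NULL)
    cbind(ix[-length(ix)], ix[-1],
          compute_jump(meas$value[ix], meas$age_years[ix]))
  })
  jm <- do.call(rbind, jumps)
  drop <- rep(FALSE, nrow(meas))
  if (!is.null(jm) && nrow(jm)) {
    trait_of_pair <- meas$trait[jm[, 1]]
    for (tr in unique(trait_of_pair)) {
      sel <- trait_of_pair == tr & is.finite(jm[, 3])
      if (!sum(sel)) next
      mu <- mean(jm[sel, 3]); s <- stats::sd(jm[sel, 3])
      if (!is.finite(s) || s == 0) next
      thr <- mu + limits$jump_sd * s
      for (r in which(sel & jm[, 3] > thr)) {
        a <- jm[r, 1]; b <- jm[r, 2]
        far <- if (abs(meas$value[a] - med[a]) >= abs(meas$value[b] - med[b]))
          a else b
        drop[far] <- TRUE
      }
    }
  }
  removed["jump"] <- sum(drop)
  meas <- meas[!drop, , drop = FALSE]
  rownames(meas) <- NULL
  list(measurements = meas,
       report = new_qc_report(rows_in, nrow(meas), as.list(removed)))
}

#' Run the full longitudinal QC chain
#'
#' [population_qc()] followed by [individual_qc()], with a merged report.
#'
#' @inheritParams population_qc
#' @return list with `measurements` and `report`.
#' @export
run_qc <- function(measurements, events = NULL, limits = qc_limits()) {
  p <- population_qc(measurements, events, limits)
  i <- individual_qc(p$measurements, limits)
  rep <- new_qc_report(p$report$rows_in, i$report$rows_out,
                       c(p$report$removed, i$report$removed),
                       p$report$individuals_removed)
  list(measurements = i$measurements, report = rep)
}
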