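# Validity measures comparing replicate prevalence estimates with the true
# (census) prevalence: bias, relative bias, RMSE, range-normalized RMSE and
# the deviation-threshold proportions.

#' Monte-Carlo bias of a set of prevalence estimates
#'
#' `bias()` is the mean difference between the replicate estimates and the
#' true prevalence; `relative_bias()` divides it by the true prevalence, so
#' -1 means every estimate was 0 and values near 0 mean the design is
#' unbiased (negative = systematic underestimation). `rmse()` is the root
#' mean squared deviation of the estimates from the truth.
#'
#' @param estimates Numeric vector of replicate prevalence estimates.
#' @param p True prevalence in \[0, 1\] (`relative_bias()` requires p > 0).
#' @return A single number. `relative_bias()` lies in
#'   \[-1, (1 - p)/p\].
#' @examples
#' bias(c(0, 0.1), p = 0.04)          # 0.01
#' relative_bias(c(0, 0), p = 0.05)   # -1
#' rmse(c(0.04, 0.06), p = 0.05)      # 0.01
#' @export
bias <- function(estimates, p) {
  stopifnot(length(estimates) >= 1, p >= 0, p <= 1)
  mean(estimates) - p
}

#' @rdname bias
#' @export
relative_bias <- function(estimates, p) {
  if (p <= 0) stop("relative bias is undefined for true prevalence 0")
  bias(estimates, p) / p
}

#' @rdname bias
#' @export
rmse <- function(estimates, p) {
  stopifnot(length(estimates) >= 1, p >= 0, p <= 1)
  sqrt(mean((estimates - p)^2))
}

#' Range-normalized RMSE
#'
#' `nrmse()` divides the RMSE by the empirical range
#' `max(estimates) - min(estimates)` of the replicate estimates — the
#' normalization used throughout this framework's accuracy comparisons. The
#' denominator is an extreme-value statistic, so the measure depends on the
#' number of replicates; it is not the more common prevalence-normalized
#' variant, which is provided separately as `nrmse_prevalence()` and never
#' silently substituted.
#'
#' @inheritParams bias
#' @return A non-negative number; larger means less accurate.
#' @examples
#' nrmse(c(0, 0.1, 0.2), p = 0.1) # rmse 0.0816 / range 0.2
#' @export
nrmse <- function(estimates, p) {
  rng <- range(estimates)
  if (rng[2] <= rng[1])
    stop("all estimates identical: range-normalized RMSE is undefined")
  rmse(estimates, p) / (rng[2] - rng[1])
}

#' @rdname nrmse
#' @export
nrmse_prevalence <- function(estimates, p) {
  if (p <= 0) stop("prevalence-normalized RMSE is undefined for p = 0")
  rmse(estimates, p) / p
}

#' Proportion of replicates deviating from the truth by more than a threshold
#'
#' A replicate underestimates by more than threshold `t` when its estimate is
#' strictly below `(1 - t) * p`, and overestimates when strictly above
#' `(1 + t) * p`; estimates exactly on a boundary do not count as deviating.
#' For example at p = 5\% and t = 10\%, estimates below 4.5\% or above 5.5\%
#' deviate.
#'
#' @inheritParams bias
#' @param threshold Positive relative deviation threshold (conventional
#'   values 0.10, 0.30, 0.50).
#' @return Named numeric vector `c(under, over, total)` of replicate
#'   fractions; `total = under + over`.
#' @examples
#' deviation_fraction(c(0.02, 0.05, 0.09), p = 0.05, threshold = 0.5)
#' @export
deviation_fraction <- function(estimates, p, threshold) {
  if (p <= 0) stop("deviation fraction is undefined for true prevalence 0")
  stopifnot(threshold > 0, length(estimates) >= 1)
  # strict inequalities; 1e-9 guard keeps float ties at the band edges from
  # counting as deviations
  under <- mean(estimates < (1 - threshold) * p - 1e-9)
  over <- mean(estimates > (1 + threshold) * p + 1e-9)
  c(under = under, over = over, total = under + over)
}

#' Full validity report for one simulation run
#'
#' Computes, per indicator, the bias, relative bias, RMSE, range-normalized
#' RMSE and deviation fractions (under / over / total) at each threshold,
#' plus the unweighted across-indicator mean and standard deviation of every
#' measure. The estimate matrix must have been drawn from the supplied herd
#' (digests are compared).
#'
#' @param em An [simulate_strategy()] `estimate_matrix`.
#' @param herd The `herd` the matrix was drawn from.
#' @param thresholds Deviation thresholds (default 0.10, 0.30, 0.50).
#' @return An object of class `validity_report` with elements
#'   `per_indicator` (data frame), `aggregate` (data frame of mean and sd
#'   per measure), `true_prevalences`, `strategy` and `thresholds`.
#' @examples
#' h <- reference_herd(seed = 1)
#' em <- simulate_strategy(h, strategy_spec("S1_simple"), 500, master_seed = 2)
#' validity_report(em, h)
#' @export
validity_report <- function(em, herd, thresholds = c(0.10, 0.30, 0.50)) {
  stopifnot(inherits(em, "estimate_matrix"), inherits(herd, "herd"))
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0))
    stop("thresholds must be positive and strictly increasing")
  if (em$herd_digest != herd_digest(herd))
    stop("estimate matrix was not drawn from this herd (digest mismatch)")
  p_true <- true_prevalence(herd)
  inds <- colnames(em$counts)
  stopifnot(all(inds %in% names(p_true)))
  est <- estimates(em)

  rows <- lapply(inds, function(ind) {
    e <- est[, ind]
    p <- p_true[[ind]]
    # ratio measures are undefined at p = 0, and the range normalization at
    # zero spread (census-like runs): report NA there rather than abort
    row <- data.frame(indicator = ind, true_p = p,
                      bias = bias(e, p),
                      rb = if (p > 0) relative_bias(e, p) else NA_real_,
                      rmse = rmse(e, p),
                      nrmse = if (max(e) > min(e)) nrmse(e, p) else NA_real_)
    for (t in thresholds) {
      d <- if (p > 0) deviation_fraction(e, p, t) else
        c(under = NA_real_, over = NA_real_, total = NA_real_)
      lab <- sprintf("%d", round(100 * t))
      row[[paste0("dev_under_", lab)]] <- d[["under"]]
      row[[paste0("dev_over_", lab)]] <- d[["over"]]
      row[[paste0("dev_total_", lab)]] <- d[["total"]]
    }
    row
  })
  per_ind <- do.call(rbind, rows)
  rownames(per_ind) <- NULL

  measures <- setdiff(names(per_ind), c("indicator", "true_p"))
  aggregate <- data.frame(
    measure = measures,
    mean = vapply(measures, function(m) mean(per_ind[[m]]), numeric(1)),
    sd = vapply(measures, function(m)
      if (nrow(per_ind) > 1L) stats::sd(per_ind[[m]]) else 0, numeric(1)),
    row.names = NULL)

  structure(list(per_indicator = per_ind, aggregate = aggregate,
                 true_prevalences = p_true[inds],
                 strategy = em$strategy, thresholds = thresholds,
                 n_replicates = em$n_replicates),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, digits = 4, ...) {
  cat(sprintf("<validity_report> %s, %d replicates\n",
              x$strategy$kind, x$n_replicates))
  show <- x$per_indicator
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], round, digits)
  print(show)
  cat("\nindicator-averaged (mean, sd):\n")
  agg <- x$aggregate
  agg$mean <- round(agg$mean, digits)
  agg$sd <- round(agg$sd, digits)
  print(agg)
  invisible(x)
}

#' Write a validity report as tidy CSV and JSON
#'
#' The CSV is long format (`strategy`, `indicator`, `measure`, `value`) with
#' the across-indicator aggregates under `indicator = "(mean)"` and
#' `"(sd)"`; the JSON mirrors the report structure.
#'
#' @param report A `validity_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_validity_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "validity_report"))
  if (!is.null(csv_path)) {
    pi <- report$per_indicator
    measures <- setdiff(names(pi), "indicator")
    long <- do.call(rbind, lapply(measures, function(m)
      data.frame(strategy = report$strategy$kind, indicator = pi$indicator,
                 measure = m, value = pi[[m]])))
    agg <- report$aggregate
    long <- rbind(long,
      data.frame(strategy = report$strategy$kind, indicator = "(mean)",
                 measure = agg$measure, value = agg$mean),
      data.frame(strategy = report$strategy$kind, indicator = "(sd)",
                 measure = agg$measure, value = agg$sd))
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(strategy = report$strategy$kind,
           n_replicates = report$n_replicates,
           thresholds = report$thresholds,
           true_prevalences = as.list(report$true_prevalences),
           per_indicator = report$per_indicator,
           aggregate = report$aggregate),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
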