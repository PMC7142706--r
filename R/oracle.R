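# Exact finite-population computations for simple random sampling without
# replacement. The affected count in a simple random sample is
# hypergeometric, so every validity measure of that design has a closed or
# summable form; these are the correctness surface the Monte-Carlo engine is
# tested against.

#' Specify a finite-population sampling problem
#'
#' @param N Population (herd) size.
#' @param K Number of affected individuals in the population.
#' @param n Sample size (without replacement).
#' @return An object of class `hypergeom_spec`.
#' @examples
#' hypergeom_spec(N = 636, K = 54, n = 167)
#' @export
hypergeom_spec <- function(N, K, n) {
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n)
  if (!(K >= 0L && K <= N)) stop("need 0 <= K <= N")
  if (!(n >= 1L && n <= N)) stop("need 1 <= n <= N")
  structure(list(N = N, K = K, n = n), class = "hypergeom_spec")
}

#' @export
print.hypergeom_spec <- function(x, ...) {
  cat(sprintf("<hypergeom_spec> N = %d, K = %d (p = %.4f), n = %d\n",
              x$N, x$K, x$K / x$N, x$n))
  invisible(x)
}

#' Exact distribution of the affected count in a simple random sample
#'
#' The number of affected individuals in a without-replacement sample of
#' size n is Hypergeometric(N, K, n); the estimate is that count over n.
#' Probabilities are evaluated by `stats::dhyper()` (log-gamma based, stable
#' far beyond herd sizes of a few hundred) over the full support
#' `max(0, n - (N - K)) .. min(n, K)`.
#'
#' @param spec A [hypergeom_spec()].
#' @return Data frame with columns `count`, `estimate` (= count/n) and
#'   `prob`; the probabilities sum to 1 to within 1e-12.
#' @examples
#' exact_estimate_pmf(hypergeom_spec(2, 1, 1))
#' @export
exact_estimate_pmf <- function(spec) {
  stopifnot(inherits(spec, "hypergeom_spec"))
  x <- max(0L, spec$n - (spec$N - spec$K)):min(spec$n, spec$K)
  prob <- stats::dhyper(x, spec$K, spec$N - spec$K, spec$n)
  if (abs(sum(prob) - 1) > 1e-12)
    stop("pmf failed to normalize")
  data.frame(count = x, estimate = x / spec$n, prob = prob)
}

#' Exact RMSE of the simple-random-sampling prevalence estimator
#'
#' Closed form `sqrt(p (1 - p) / n * (N - n)/(N - 1))` with `p = K/N`: the
#' binomial standard error shrunk by the finite population correction. The
#' design is exactly unbiased, so this is also the standard deviation of
#' the estimator.
#'
#' @param spec A [hypergeom_spec()].
#' @return A non-negative number.
#' @examples
#' exact_rmse(hypergeom_spec(636, 54, 167))
#' @export
exact_rmse <- function(spec) {
  stopifnot(inherits(spec, "hypergeom_spec"))
  if (spec$n == spec$N) return(0) # census: estimator is exact
  p <- spec$K / spec$N
  sqrt(p * (1 - p) / spec$n * (spec$N - spec$n) / (spec$N - 1))
}

#' Exact deviation-threshold probabilities under simple random sampling
#'
#' Probability mass of the estimate falling strictly below `(1 - t) p` or
#' strictly above `(1 + t) p` — the exact counterpart of
#' [deviation_fraction()], by direct summation over the hypergeometric pmf.
#'
#' @param spec A [hypergeom_spec()] with `K > 0`.
#' @param threshold Positive relative threshold.
#' @return Named numeric vector `c(under, over, total)`.
#' @examples
#' exact_deviation_fraction(hypergeom_spec(636, 7, 167), 0.5)
#' @export
exact_deviation_fraction <- function(spec, threshold) {
  stopifnot(inherits(spec, "hypergeom_spec"), threshold > 0)
  if (spec$K == 0L)
    stop("deviation fraction is undefined for a population with no affected")
  pmf <- exact_estimate_pmf(spec)
  p <- spec$K / spec$N
  # strict inequalities; 1e-9 guard against float ties at the band edges
  under <- sum(pmf$prob[pmf$estimate < (1 - threshold) * p - 1e-9])
  over <- sum(pmf$prob[pmf$estimate > (1 + threshold) * p + 1e-9])
  c(under = under, over = over, total = under + over)
}

#' Exact distribution of the extreme replicate estimates
#'
#' For `reps` independent simple random samples, the minimum and maximum of
#' the replicate estimates have cdfs `1 - (1 - F(x^-))^reps` and
#' `F(x)^reps`, where F is the hypergeometric cdf of a single draw. These
#' give the exact distribution — and expectation — of the empirical range
#' that normalizes [nrmse()].
#'
#' @param spec A [hypergeom_spec()].
#' @param n_replicates Number of replicate draws.
#' @return List with data frames `min` and `max` (columns `estimate`,
#'   `prob`) and numbers `expected_min`, `expected_max`, `expected_range`.
#' @examples
#' extreme_value_cdf(hypergeom_spec(636, 54, 167), 100000)$expected_range
#' @export
extreme_value_cdf <- function(spec, n_replicates) {
  stopifnot(inherits(spec, "hypergeom_spec"), n_replicates >= 1)
  pmf <- exact_estimate_pmf(spec)
  cdf <- cumsum(pmf$prob)
  m <- length(cdf)
  # max: P(max <= x_i) = F(x_i)^reps
  cdf_max <- pmin(cdf, 1)^n_replicates
  pmf_max <- diff(c(0, cdf_max))
  # min: P(min >= x_i) = (1 - F(x_{i-1}))^reps
  p_ge <- pmax(1 - c(0, cdf[-m]), 0)^n_replicates
  pmf_min <- p_ge - c(p_ge[-1], 0)
  expected_min <- sum(pmf$estimate * pmf_min)
  expected_max <- sum(pmf$estimate * pmf_max)
  list(min = data.frame(estimate = pmf$estimate, prob = pmf_min),
       max = data.frame(estimate = pmf$estimate, prob = pmf_max),
       expected_min = expected_min,
       expected_max = expected_max,
       expected_range = expected_max - expected_min)
}

#' Expected range-normalized RMSE under simple random sampling
#'
#' First-order approximation `exact_rmse / expected_range`: at large
#' replicate counts the empirical range concentrates tightly around its
#' expectation, so the ratio of expectations tracks the expectation of the
#' ratio closely.
#'
#' @inheritParams extreme_value_cdf
#' @return A non-negative number.
#' @export
expected_nrmse <- function(spec, n_replicates) {
  exact_rmse(spec) / extreme_value_cdf(spec, n_replicates)$expected_range
}

#' Exact simple-random-sampling validity metrics for a whole herd
#'
#' Applies the hypergeometric oracle to every indicator of a herd for the
#' given sample size: exact bias (always 0), RMSE, expected range-normalized
#' RMSE at `n_replicates`, and exact deviation probabilities.
#'
#' @param herd A `herd`.
#' @param n_animals Simple-random sample size.
#' @param n_replicates Replicates assumed for the range normalization.
#' @param thresholds Deviation thresholds.
#' @return Data frame, one row per indicator.
#' @examples
#' exact_s1_report(reference_herd(), 167, 100000)
#' @export
exact_s1_report <- function(herd, n_animals = 167L, n_replicates = 100000L,
                            thresholds = c(0.10, 0.30, 0.50)) {
  N <- herd_size(herd)
  K <- colSums(indicator_states(herd))
  rows <- lapply(names(K), function(ind) {
    spec <- hypergeom_spec(N, K[[ind]], n_animals)
    row <- data.frame(indicator = ind, true_p = K[[ind]] / N,
                      bias = 0,
                      rmse = exact_rmse(spec),
                      expected_nrmse = if (K[[ind]] > 0)
                        expected_nrmse(spec, n_replicates) else NA_real_)
    for (t in thresholds) {
      lab <- sprintf("%d", round(100 * t))
      if (K[[ind]] > 0) {
        d <- exact_deviation_fraction(spec, t)
        row[[paste0("dev_under_", lab)]] <- d[["under"]]
        row[[paste0("dev_over_", lab)]] <- d[["over"]]
        row[[paste0("dev_total_", lab)]] <- d[["total"]]
      } else {
        row[[paste0("dev_under_", lab)]] <- NA_real_
        row[[paste0("dev_over_", lab)]] <- NA_real_
        row[[paste0("dev_total_", lab)]] <- NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
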