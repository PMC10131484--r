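#' Regression-based prior for per-variant standard deviations
#'
#' With only two replicates the empirical standard deviation of a score is a
#' poor estimate of its sampling error. A prior estimate is therefore
#' obtained by regressing the empirical standard deviation on the score and
#' on the log10 pre-selection read count, and predicting for every variant.
#' Predictions are floored at `sigma_floor` (negative or tiny predictions
#' are clamped and flagged).
#'
#' @param score activity scores.
#' @param s empirical standard deviations (NA allowed; rows with NA are
#'   excluded from the fit but still receive predictions).
#' @param pre_count raw pre-selection read counts (> 0 after pseudocount;
#'   zeros are offset by 0.5 for the log).
#' @param sigma_floor lower bound on the prior sd (default 0.01).
#' @param min_fit minimum variants with defined `s` required (default 50).
#' @return list: `sigma0` (per-variant prior sd), `clamped` (logical),
#'   `fit` (the `lm` object).
#' @export
fit_prior_sd <- function(score, s, pre_count, sigma_floor = 0.01,
                         min_fit = 50L) {
  stopifnot(length(score) == length(s), length(s) == length(pre_count))
  use <- !is.na(s) & !is.na(score) & !is.na(pre_count)
  if (sum(use) < min_fit)
    stop("need >= ", min_fit, " variants with defined empirical sd (have ",
         sum(use), ")")
  lc <- log10(pre_count + 0.5)
  d <- data.frame(s = s, score = score, lc = lc)
  fit <- stats::lm(s ~ score + lc, data = d[use, ])
  if (any(!is.finite(stats::coef(fit)))) stop("singular prior-sd design")
  pred <- as.vector(stats::predict(fit, newdata = d))
  clamped <- pred < sigma_floor
  list(sigma0 = pmax(pred, sigma_floor), clamped = clamped, fit = fit)
}

#' Bayesian regularization of an empirical standard deviation
#'
#' Shrinks the empirical standard deviation `s` (from `n` replicates) toward
#' the prior estimate `sigma0` carrying `v0` pseudo-degrees of freedom:
#' \deqn{\sigma^2 = \frac{v_0 \sigma_0^2 + (n-1) s^2}{v_0 + n - 2}.}
#'
#' @param s empirical standard deviation (>= 0).
#' @param sigma0 prior standard deviation (>= 0).
#' @param n number of replicates.
#' @param v0 prior degrees of freedom (default 3); `v0 + n` must exceed 2.
#' @return the regularized standard deviation `sigma`.
#' @examples
#' regularize_variance(s = 0.3, sigma0 = 0.1, n = 2, v0 = 3)  # 0.2
#' @export
regularize_variance <- function(s, sigma0, n, v0 = 3) {
  if (any(v0 + n <= 2)) stop("v0 + n must exceed 2")
  if (any(s < 0, na.rm = TRUE) || any(sigma0 < 0, na.rm = TRUE))
    stop("s and sigma0 must be nonnegative")
  sqrt((v0 * sigma0^2 + (n - 1) * s^2) / (v0 + n - 2))
}

#' Percentile bootstrap confidence interval
#'
#' @param values numeric sample.
#' @param statistic function of a numeric vector (default `mean`).
#' @param n_boot resamples (default 10000; fewer than 100 raises a warning).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for reproducibility.
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 10000L,
                         level = 0.95, seed = 1L) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty sample")
  if (n_boot < 100) warning("n_boot < 100: interval will be unstable")
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(i)
    statistic(values[sample.int(length(values), replace = TRUE)]),
    numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# vectorized percentile bootstrap of the per-variant mean across replicates;
# rows of `mat` are variants, columns replicates (NA allowed)
bootstrap_ci_rows <- function(mat, n_boot = 1000L, level = 0.95, seed = 1L) {
  set.seed(seed)
  a <- (1 - level) / 2
  t(apply(mat, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(c(NA_real_, NA_real_))
    draws <- matrix(v[sample.int(length(v), length(v) * n_boot,
                                 replace = TRUE)], nrow = n_boot)
    stats::quantile(rowMeans(draws), c(a, 1 - a), names = FALSE)
  }))
}
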