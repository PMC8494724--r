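#' Rank index of a percentile
#'
#' The rank of the p-th quantile within a sorted sample of n values, using the
#' convention index = 0.5 + p n.  With 100 values, the 2.5th percentile sits
#' at rank 0.5 + 0.025 x 100 = 3, i.e. the 3rd smallest value.
#'
#' @param p quantile as a fraction in (0, 1).
#' @param n sample size (>= 1).
#' @return The (possibly fractional) rank.
#' @examples
#' rank_index(0.025, 100)  # 3
#' @export
rank_index <- function(p, n) {
  stopifnot(n >= 1, n == round(n))
  if (any(p <= 0 | p >= 1)) data_error("p must lie strictly inside (0, 1)")
  0.5 + p * n
}

#' Nonparametric sample quantile
#'
#' Quantile of a sample by ranking: the value at [rank_index()], with two
#' conventions for fractional ranks.  `"interpolate"` (the default) takes the
#' linear interpolation between the adjacent order statistics and is identical
#' to `stats::quantile(type = 5)`; `"round"` takes the order statistic at the
#' half-up-rounded rank.  Ranks outside `[1, n]` clamp to the extreme values.
#'
#' @param values numeric vector (need not be sorted).
#' @param p quantile fraction(s) in (0, 1).
#' @param method `"interpolate"` or `"round"`.
#' @return Quantile value(s).
#' @examples
#' quantile_nonparametric(1:100, 0.025)          # 3
#' quantile_nonparametric(0:9, 0.10, "round")    # 1
#' @export
quantile_nonparametric <- function(values, p,
                                   method = c("interpolate", "round")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (!length(values)) data_error("empty sample")
  if (any(!is.finite(values))) data_error("values must be finite")
  x <- sort(values)
  n <- length(x)
  r <- rank_index(p, n)
  r <- pmin(pmax(r, 1), n)
  if (method == "round") {
    x[floor(r + 0.5)]
  } else {
    lo <- floor(r); hi <- ceiling(r)
    x[lo] + (r - lo) * (x[hi] - x[lo])
  }
}

#' Minimum sample size to separate adjacent percentiles
#'
#' The smallest number of ranked data points that distinguishes two
#' percentiles P percent apart: n = 100/P - 1.  Separating the 2.5th from the
#' 5th percentile therefore needs at least 39 points; at that size the extreme
#' values themselves become the estimated reference limits.
#'
#' @param P percentile gap in percent, 0 < P <= 100.
#' @return Integer minimum sample size (ceiling of 100/P - 1).
#' @examples
#' min_n_for_separation(2.5)  # 39
#' @export
min_n_for_separation <- function(P) {
  if (any(P <= 0 | P > 100)) data_error("P must lie in (0, 100]")
  as.integer(ceiling(100 / P - 1))
}

#' Exact order-statistic confidence interval for a quantile
#'
#' Searches rank pairs (l, u) such that the order-statistic interval
#' [x(l), x(u)] covers the p-quantile with probability at least `confidence`
#' under the binomial law, P(l <= K <= u - 1) with K ~ Bin(n, p).  Among
#' attaining pairs the smallest width is returned, ties broken by symmetry
#' about [rank_index()].  If no interior pair attains the confidence the
#' result is flagged unattainable and the extreme ranks (1, n) are returned as
#' the best available bracket.
#'
#' @param n sample size.
#' @param p quantile fraction in (0, 1).
#' @param confidence required coverage probability (default 0.90).
#' @return List with `lower`, `upper` (ranks), `coverage` (achieved
#'   probability) and `attainable` (logical).
#' @examples
#' order_statistic_ci(120, 0.025)  # ranks (1, 7)
#' @export
order_statistic_ci <- function(n, p, confidence = 0.90) {
  stopifnot(n >= 1, n == round(n), p > 0, p < 1,
            confidence >= 0, confidence < 1)
  if (n == 1L)
    return(list(lower = 1L, upper = 1L, coverage = 0, attainable = FALSE))
  ri <- rank_index(p, n)
  cdf <- stats::pbinom(0:n, n, p)   # cdf[k+1] = P(K <= k)
  cov_pair <- function(l, u) cdf[u] - cdf[l]  # P(l <= K <= u-1)
  for (w in 1:(n - 1L)) {
    l <- 1:(n - w)
    cov <- cdf[l + w] - cdf[l]
    ok <- which(cov >= confidence)
    if (length(ok)) {
      best <- ok[which.min(abs(l[ok] + w / 2 - ri))]
      return(list(lower = l[best], upper = l[best] + w,
                  coverage = cov[best], attainable = TRUE))
    }
  }
  list(lower = 1L, upper = n, coverage = cov_pair(1L, n), attainable = FALSE)
}

#' Smallest n allowing an exact nonparametric CI of a reference limit
#'
#' Searches upward for the smallest sample size at which an exact
#' order-statistic confidence interval for the p-quantile exists.  Two
#' conventions are implemented: `"equal_tailed"` requires each tail risk to be
#' at most (1 - confidence)/2 — in particular the smallest value must lie
#' below the quantile with probability at least 1 - (1-confidence)/2, the
#' convention behind the classical minimum of about 120 subjects for the 2.5th
#' percentile (the brute-force minimum is 119; 120 is the conventional round
#' figure) — while `"coverage"` only requires total coverage of the quantile,
#' which is attainable from smaller n.
#'
#' @param p quantile fraction (default 0.025).
#' @param confidence required confidence (default 0.90).
#' @param convention `"equal_tailed"` or `"coverage"`.
#' @param n_max search cap.
#' @return Smallest attaining integer n (or NA if none below `n_max`).
#' @export
min_n_exact_ci <- function(p = 0.025, confidence = 0.90,
                           convention = c("equal_tailed", "coverage"),
                           n_max = 10000L) {
  convention <- match.arg(convention)
  a <- (1 - confidence) / 2
  for (n in 2:n_max) {
    if (convention == "equal_tailed") {
      # lower rank l >= 1 needs P(K = 0) <= a; upper rank u <= n needs
      # P(K = n) <= a; then an equal-tailed pair exists
      if (stats::pbinom(0, n, p) <= a && stats::dbinom(n, n, p) <= a)
        return(n)
    } else {
      if (order_statistic_ci(n, p, confidence)$attainable) return(n)
    }
  }
  NA_integer_
}

#' Nonparametric reference limits with order-statistic confidence intervals
#'
#' The gold-standard estimator: limits are sample percentiles by
#' [quantile_nonparametric()], and each limit's 90% CI is the exact
#' order-statistic interval from [order_statistic_ci()].  One-tailed modes
#' estimate the single 5th or 95th percentile but still use the two-tailed
#' 2.5th-97.5th interval width as the denominator of the CI/RI quality ratio.
#'
#' @param values numeric vector of reference values (one per statistical
#'   unit), or a [reference_sample] (all values used as-is; see
#'   [apply_eye_strategy()] for bilateral handling).
#' @param tails `"two_tailed"` (2.5th and 97.5th percentiles), `"lower_only"`
#'   (5th) or `"upper_only"` (95th).
#' @param coverage central reference-interval coverage (default 0.95).
#' @param confidence confidence level for the limit CIs (default 0.90).
#' @param n_subjects number of subjects the values came from (defaults to the
#'   number of values).
#' @return A [reference_limit_estimate].
#' @export
nonparametric_limits <- function(values,
                                 tails = c("two_tailed", "lower_only",
                                           "upper_only"),
                                 coverage = 0.95, confidence = 0.90,
                                 n_subjects = NULL) {
  tails <- match.arg(tails)
  if (inherits(values, "reference_sample")) {
    n_subjects <- n_subjects %||% n_subjects(values)
    values <- measurement_values(values)
  }
  values <- sort(as.numeric(values))
  n <- length(values)
  if (!n) data_error("empty sample")
  n_subjects <- n_subjects %||% n
  probs <- tail_probs(tails, coverage)
  lims <- lapply(probs, function(p) {
    if (is.na(p)) return(NULL)
    ci <- order_statistic_ci(n, p, confidence)
    list(limit = quantile_nonparametric(values, p),
         ci = c(values[ci$lower], values[ci$upper]),
         ci_attainable = ci$attainable, ci_ranks = c(ci$lower, ci$upper))
  })
  new_limit_estimate(lower = lims$lower, upper = lims$upper,
                     method = "nonparametric", transform = "none",
                     tails = tails, coverage = coverage,
                     confidence = confidence,
                     n_subjects = n_subjects, n_values = n,
                     ri_width = two_tailed_ri_width(values, coverage))
}

# percentile targets per tail mode; NA marks an unmonitored tail
tail_probs <- function(tails, coverage = 0.95) {
  a <- 1 - coverage
  switch(tails,
         two_tailed = list(lower = a / 2, upper = 1 - a / 2),
         lower_only = list(lower = a, upper = NA_real_),
         upper_only = list(lower = NA_real_, upper = 1 - a))
}

# the uncertainty-ratio denominator is always the central two-tailed interval
two_tailed_ri_width <- function(values, coverage = 0.95) {
  a <- (1 - coverage) / 2
  diff(quantile_nonparametric(values, c(a, 1 - a)))
}
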