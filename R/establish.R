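#' Establish reference limits for a sample, honouring the reporting tier
#'
#' High-level entry point combining the tier policy with the estimators.
#' Fewer than 10 subjects: estimation refuses.  10-19 subjects: a ranked
#' table with the median only.  20-39: parametric limits if a normalising
#' transform passes, otherwise robust limits (biweight location +/- z x
#' IQR-based scale), with CIs marked illustrative.  40-119: subject-level
#' bootstrap limits.  120 or more: nonparametric limits with exact
#' order-statistic CIs (the default `method = "auto"` picks these; any
#' estimator can be forced).
#'
#' @param sample a [reference_sample].
#' @param method `"auto"` or one of `"nonparametric"`, `"parametric"`,
#'   `"bootstrap"`, `"robust"`.
#' @param tails,coverage,confidence as in [nonparametric_limits()].
#' @param strategy bilateral strategy, see [apply_eye_strategy()].
#' @param B bootstrap resamples.
#' @param seed RNG seed.
#' @param transform passed to [parametric_limits()].
#' @return A [reference_limit_estimate], or an object of class
#'   `ranked_table` for the 10-19 tier.
#' @export
establish_limits <- function(sample, method = c("auto", "nonparametric",
                                                "parametric", "bootstrap",
                                                "robust"),
                             tails = c("two_tailed", "lower_only",
                                       "upper_only"),
                             strategy = c("duplicate_singletons", "one_eye",
                                          "all_eyes_independent"),
                             B = 1000L, seed = NULL, coverage = 0.95,
                             confidence = 0.90, transform = "auto") {
  stopifnot(inherits(sample, "reference_sample"))
  method <- match.arg(method)
  tails <- match.arg(tails)
  strategy <- match.arg(strategy)
  ns <- n_subjects(sample)
  tier <- reporting_tier(ns)
  if (tier$tier == "refuse")
    refuse(sprintf(
      "reference data from %d subjects should not be reported (minimum 10); consider subject-based reference values",
      ns))
  if (tier$tier == "ranked_table" && method == "auto") {
    v <- sort(measurement_values(sample))
    return(structure(list(values = v, median = stats::median(v),
                          n_subjects = ns, tier = tier$tier),
                     class = "ranked_table"))
  }
  appl <- apply_eye_strategy(sample, strategy)
  if (method == "auto")
    method <- switch(tier$tier, robust_small = "robust",
                     transfer_scale = "bootstrap", full = "nonparametric")
  est <- switch(method,
    nonparametric = nonparametric_limits(appl$values, tails, coverage,
                                         confidence, n_subjects = ns),
    parametric = parametric_limits(appl$values, transform, tails, coverage,
                                   confidence, n_subjects = ns),
    bootstrap = bootstrap_limits(sample, tails, strategy, B = B, seed = seed,
                                 coverage = coverage,
                                 confidence = confidence),
    robust = robust_limits(appl$values, tails, coverage, confidence,
                           n_subjects = ns))
  est$extras$tier <- tier$tier
  est$extras$eye_strategy <- strategy
  if (tier$tier == "robust_small") {
    est$warnings <- c(est$warnings,
                      "n < 40: confidence intervals are illustrative only, not for clinical 'indeterminate' classification")
    est$extras$ci_illustrative <- TRUE
  }
  est
}

#' @export
print.ranked_table <- function(x, ...) {
  cat(sprintf("Ranked reference table (n = %d subjects; 10-19 tier)\n",
              x$n_subjects))
  cat("  median:", format(x$median), "\n")
  cat("  ranked values:", paste(format(x$values), collapse = ", "), "\n")
  cat("  reference limits are not reported at this sample size\n")
  invisible(x)
}

# robust limits for the 20-39 tier: biweight location +/- z * IQR-based scale
robust_limits <- function(values, tails = "two_tailed", coverage = 0.95,
                          confidence = 0.90, n_subjects = NULL) {
  rs <- robust_location_scale(values)
  z <- stats::qnorm(1 - (1 - coverage) / 2)
  hw <- ci_approx_halfwidth(rs$scale, length(values), coverage, confidence)
  lower <- list(limit = rs$location - z * rs$scale,
                ci = rs$location - z * rs$scale + c(-hw, hw),
                ci_attainable = NA)
  upper <- list(limit = rs$location + z * rs$scale,
                ci = rs$location + z * rs$scale + c(-hw, hw),
                ci_attainable = NA)
  probs <- tail_probs(tails, coverage)
  if (is.na(probs$lower)) lower <- NULL
  if (is.na(probs$upper)) upper <- NULL
  new_limit_estimate(lower = lower, upper = upper, method = "robust",
                     transform = "none", tails = tails, coverage = coverage,
                     confidence = confidence,
                     n_subjects = n_subjects %||% length(values),
                     n_values = length(values),
                     ri_width = 2 * z * rs$scale,
                     extras = list(location = rs$location,
                                   scale = rs$scale))
}
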