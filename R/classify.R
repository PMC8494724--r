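# classification of patient values against an estimated reference interval

#' Classify a measurement against reference limits
#'
#' A value inside the reference interval is consistent with the reference
#' population (normal); outside it is abnormal, low or high.  A value that
#' falls within the 90% CI band of a limit is additionally flagged
#' indeterminate, since the limit itself is only known to that precision.
#' One-tailed modes never emit the unmonitored tail's abnormal verdict: an
#' extreme in the unmonitored direction is reported as outside the monitored
#' tail and not assessed.
#'
#' @param value measured value.
#' @param estimate a [reference_limit_estimate].
#' @return Object of class `classification_result`: `verdict` (one of
#'   `"normal"`, `"abnormal_low"`, `"abnormal_high"`, `"indeterminate"`),
#'   `indeterminate` (logical), `distance` (signed distance from the nearer
#'   limit, positive outward), `note`.
#' @examples
#' est <- nonparametric_limits(rnorm(200))
#' classify(0, est)$verdict
#' @export
classify <- function(value, estimate) {
  stopifnot(inherits(estimate, "reference_limit_estimate"),
            is.finite(value))
  lo <- estimate$lower_limit; hi <- estimate$upper_limit
  ci_lo <- estimate$ci_lower_limit; ci_hi <- estimate$ci_upper_limit
  note <- NULL
  if (!is.na(lo) && value < lo) verdict <- "abnormal_low"
  else if (!is.na(hi) && value > hi) verdict <- "abnormal_high"
  else verdict <- "normal"
  if (estimate$tails != "two_tailed" && verdict == "normal")
    note <- "one-tailed limit: the unmonitored tail is not assessed"
  in_band <- function(ci) !any(is.na(ci)) && value >= ci[1] && value <= ci[2]
  indeterminate <- in_band(ci_lo) || in_band(ci_hi)
  if (indeterminate) verdict <- "indeterminate"
  dist <- suppressWarnings(min(abs(value - c(lo, hi)), na.rm = TRUE))
  sign_out <- verdict %in% c("abnormal_low", "abnormal_high")
  structure(list(verdict = verdict, indeterminate = indeterminate,
                 distance = if (sign_out) dist else -dist,
                 value = value,
                 limits = c(lower = lo, upper = hi), note = note),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Value %.6g: %s\n", x$value, x$verdict))
  invisible(x)
}

#' Familywise false-positive risk of multiple 95% reference intervals
#'
#' Each parameter judged against a 95% reference interval has a 1-in-20
#' chance of a false abnormal call; reporting n independent parameters
#' carries risk 1 - 0.95^n of at least one false positive.  The independence
#' assumption is explicit: correlated parameters lower the true risk, but
#' the correlations are rarely known, so the risk is reported rather than
#' corrected for.
#'
#' @param n number of parameters reported (>= 0).
#' @param coverage per-parameter reference-interval coverage (default 0.95).
#' @return Familywise false-positive probability (0 for n = 0).
#' @examples
#' familywise_risk(1)   # 0.05
#' familywise_risk(14)
#' @export
familywise_risk <- function(n, coverage = 0.95) {
  stopifnot(all(n >= 0), all(n == round(n)))
  1 - coverage^n
}
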