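# transference and verification of externally established reference intervals

#' Deming regression
#'
#' Errors-in-variables straight-line fit used for method comparison, where
#' both the old and new method carry measurement error; ordinary least
#' squares is biased toward zero slope in that setting.
#'
#' @param x,y paired measurements (old and new method).
#' @param error_ratio ratio of the error variances var(ey)/var(ex)
#'   (default 1).
#' @return List with `slope`, `intercept`.
#' @export
deming_regression <- function(x, y, error_ratio = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0 && (sxx == 0 || syy == 0))
    refuse("zero variance: Deming regression undefined")
  d <- syy - error_ratio * sxx
  slope <- (d + sqrt(d^2 + 4 * error_ratio * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Assess transference of a reference interval to a new method
#'
#' Transference adapts a previously established reference interval to an
#' updated technique (protocol, stimulus, electrode) by measuring at least 40
#' subjects with both methods.  If the paired results correlate well
#' (r^2 >= 0.7) and the regression line is close to the identity, the old
#' interval is reused unchanged; with good correlation but a clinically
#' significant slope or offset the old limits are mapped through the
#' regression (new = slope x old + intercept); with poor correlation or too
#' few subjects the interval cannot be transferred.
#'
#' @param value_old,value_new paired measurements per subject (equal length,
#'   NA pairs dropped).
#' @param old_limits numeric vector of the established limit(s), e.g.
#'   `c(lower, upper)`.
#' @param regression `"deming"` (default) or `"ols"`.
#' @param slope_tol identity-slope tolerance: |slope - 1| above this is
#'   clinically significant (default 0.05).
#' @param intercept_tol intercept tolerance as a fraction of the old
#'   reference-interval width, or of the data range when only one limit is
#'   supplied (default 0.05).
#' @param min_n minimum subject count for a transfer decision (default 40).
#' @return An object of class `transfer_report`: `n`, `r_squared`, `slope`,
#'   `intercept`, `regression`, `decision` (one of `"reuse_unchanged"`,
#'   `"adjust_limits"`, `"cannot_transfer"`), `adjusted_limits`.
#' @export
transference_assess <- function(value_old, value_new, old_limits,
                                regression = c("deming", "ols"),
                                slope_tol = 0.05, intercept_tol = 0.05,
                                min_n = 40L) {
  regression <- match.arg(regression)
  keep <- is.finite(value_old) & is.finite(value_new)
  x <- as.numeric(value_old[keep]); y <- as.numeric(value_new[keep])
  n <- length(x)
  if (n < 2) refuse("need at least two complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    refuse("zero variance in one method; transference undefined")
  fit <- if (regression == "deming") deming_regression(x, y)
         else {
           co <- stats::coef(stats::lm(y ~ x))
           list(slope = unname(co[2]), intercept = unname(co[1]))
         }
  r2 <- stats::cor(x, y)^2
  scale_ref <- if (length(old_limits) >= 2) diff(range(old_limits))
               else diff(range(x))
  sig_slope <- abs(fit$slope - 1) > slope_tol
  sig_int <- abs(fit$intercept) > intercept_tol * scale_ref
  decision <- if (n < min_n || r2 < 0.7) "cannot_transfer"
              else if (!sig_slope && !sig_int) "reuse_unchanged"
              else "adjust_limits"
  adjusted <- if (decision == "adjust_limits")
    fit$slope * old_limits + fit$intercept
  else if (decision == "reuse_unchanged") old_limits
  else NULL
  structure(list(n = n, r_squared = r2, slope = fit$slope,
                 intercept = fit$intercept, regression = regression,
                 decision = decision, old_limits = old_limits,
                 adjusted_limits = adjusted,
                 thresholds = c(slope_tol = slope_tol,
                                intercept_tol = intercept_tol,
                                min_n = min_n, r2_gate = 0.7)),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("Transference assessment (%s regression, n = %d)\n",
              x$regression, x$n))
  cat(sprintf("  r^2 = %.3f; slope = %.4g; intercept = %.4g\n",
              x$r_squared, x$slope, x$intercept))
  cat("  decision:", x$decision, "\n")
  if (!is.null(x$adjusted_limits))
    cat("  limits for the new method:",
        paste(signif(x$adjusted_limits, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage verification of an externally established reference interval
#'
#' Count-exact adoption check: 20 local reference subjects are measured and
#' the number falling outside the primary reference interval is counted.  At
#' most two outside: the interval is acceptable locally.  Three or four
#' outside: a further 20 local subjects are recruited, and the interval is
#' acceptable if at most two of the second group fall outside.  Five or more
#' at stage 1, or a failed stage 2, call for a re-examination of protocols
#' and of whether the local population differs from the primary reference
#' sample.
#'
#' @param stage1 numeric vector of exactly 20 local reference values.
#' @param interval numeric `c(lower, upper)`; use `-Inf`/`Inf` for one-tailed
#'   intervals.
#' @param stage2 optional second sample of exactly 20 values (required when
#'   stage 1 leaves the decision open).
#' @return An object of class `verification_report`: `stage1_outside`,
#'   `stage2_outside` (NA if unused), `decision` (one of `"accept"`,
#'   `"accept_after_stage2"`, `"review_protocols"`, `"stage2_required"`).
#' @examples
#' verify_reference_interval(rnorm(20), c(-1.96, 1.96))
#' @export
verify_reference_interval <- function(stage1, interval, stage2 = NULL) {
  if (length(stage1) != 20)
    refuse(sprintf("stage 1 requires exactly 20 local values (got %d)",
                   length(stage1)))
  if (length(interval) != 2 || interval[1] > interval[2])
    data_error("interval must be c(lower, upper)")
  outside <- function(v) sum(v < interval[1] | v > interval[2])
  n1 <- outside(stage1)
  n2 <- NA_integer_
  if (n1 <= 2) decision <- "accept"
  else if (n1 >= 5) decision <- "review_protocols"
  else if (is.null(stage2)) decision <- "stage2_required"
  else {
    if (length(stage2) != 20)
      refuse(sprintf("stage 2 requires exactly 20 local values (got %d)",
                     length(stage2)))
    n2 <- outside(stage2)
    decision <- if (n2 <= 2) "accept_after_stage2" else "review_protocols"
  }
  structure(list(stage1_outside = n1, stage2_outside = n2,
                 interval = interval, decision = decision),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("Verification: %d of 20 outside at stage 1", x$stage1_outside))
  if (!is.na(x$stage2_outside))
    cat(sprintf("; %d of 20 at stage 2", x$stage2_outside))
  cat("\n  decision:", x$decision, "\n")
  invisible(x)
}

# Siegel-Tukey dispersion ranks: alternate extremes inward so that larger
# spread collects smaller ranks
siegel_tukey_ranks <- function(n) {
  r <- integer(n)
  lo <- 1L; hi <- n; rk <- 1L
  r[lo] <- rk; lo <- lo + 1L; rk <- rk + 1L   # rank 1 to the minimum
  take_high <- TRUE
  while (lo <= hi) {
    if (take_high) {
      r[hi] <- rk; rk <- rk + 1L; hi <- hi - 1L
      if (lo <= hi) { r[hi] <- rk; rk <- rk + 1L; hi <- hi - 1L }
    } else {
      r[lo] <- rk; rk <- rk + 1L; lo <- lo + 1L
      if (lo <= hi) { r[lo] <- rk; rk <- rk + 1L; lo <- lo + 1L }
    }
    take_high <- !take_high
  }
  r
}

# Siegel-Tukey test for a dispersion difference (equal medians assumed);
# Wilcoxon rank-sum applied to the alternating-extreme ranks
siegel_tukey_test <- function(x, y) {
  v <- c(x, y)
  g <- rep(c("x", "y"), c(length(x), length(y)))
  if (anyDuplicated(v))
    warning("heavy ties: Siegel-Tukey ranks depend on tie order")
  o <- order(v)
  st <- siegel_tukey_ranks(length(v))
  rk <- numeric(length(v))
  rk[o] <- st
  stats::wilcox.test(rk[g == "x"], rk[g == "y"], exact = FALSE)
}

#' Compare a local reference dataset with the full primary dataset
#'
#' When the full primary reference dataset is available, two-sample tests are
#' more sensitive and specific than the 20-subject count rule: Mann-Whitney U
#' detects location shifts, Siegel-Tukey detects dispersion differences
#' (assuming comparable medians), and Kolmogorov-Smirnov detects any shape
#' difference.
#'
#' @param local,primary numeric vectors, each n >= 20.
#' @param test one of `"mann_whitney"`, `"kolmogorov_smirnov"`,
#'   `"siegel_tukey"`, or `"all"`.
#' @param alpha significance level used in the interpretation text.
#' @return List of class `dataset_comparison` with per-test `p_value`,
#'   `statistic` and an `interpretation` string.
#' @export
verify_full_dataset <- function(local, primary,
                                test = c("all", "mann_whitney",
                                         "kolmogorov_smirnov",
                                         "siegel_tukey"),
                                alpha = 0.05) {
  test <- match.arg(test)
  local <- as.numeric(local); primary <- as.numeric(primary)
  if (length(local) < 20 || length(primary) < 20)
    refuse("full-dataset comparison needs n >= 20 in both datasets")
  wanted <- if (test == "all")
    c("mann_whitney", "siegel_tukey", "kolmogorov_smirnov") else test
  out <- list()
  for (t in wanted) {
    h <- switch(t,
      mann_whitney = stats::wilcox.test(local, primary, exact = FALSE),
      kolmogorov_smirnov = suppressWarnings(stats::ks.test(local, primary)),
      siegel_tukey = siegel_tukey_test(local, primary))
    aspect <- switch(t, mann_whitney = "location",
                     siegel_tukey = "dispersion",
                     kolmogorov_smirnov = "distribution shape")
    out[[t]] <- list(
      p_value = h$p.value, statistic = unname(h$statistic),
      interpretation = sprintf(
        "%s: %s difference %s (p = %.3g)", t, aspect,
        if (h$p.value < alpha) "detected" else "not detected", h$p.value))
  }
  structure(out, class = "dataset_comparison")
}

#' @export
print.dataset_comparison <- function(x, ...) {
  cat("Local vs primary reference dataset comparison\n")
  for (t in names(x)) cat(" ", x[[t]]$interpretation, "\n")
  invisible(x)
}
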