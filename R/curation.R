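# outlier handling, robust estimation, age compensation, partitioning

new_outlier_report <- function(values, flags, method, constants,
                               warnings = character()) {
  structure(list(values = values, flags = flags, method = method,
                 constants = constants,
                 n = length(values),
                 n_flagged = sum(flags != "kept"),
                 warnings = warnings),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report (%s): %d of %d values flagged\n",
              x$method, x$n_flagged, x$n))
  print(table(x$flags))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tukey's fences outlier detection
#'
#' Nonparametric outlier flagging by distance from the quartiles: values
#' beyond Q1 - k IQR or Q3 + k IQR are flagged, with the inner fence at
#' k = 1.5 and the far fence at k = 3.  The default removal policy removes
#' only far-fence violators, reflecting the emphasis on retaining data: the
#' far fence rejects about two values per million from a Gaussian
#' distribution, but far more (order two per thousand) from skewed
#' distributions such as a gamma.  Quartiles use the same rank convention as
#' [quantile_nonparametric()].
#'
#' @param values numeric vector (n >= 4).
#' @param inner,far fence multipliers of the IQR (defaults 1.5 and 3).
#' @return An `outlier_report` with per-value flags `kept`,
#'   `outside_inner_fence` or `outside_far_fence`; under the default policy
#'   only `outside_far_fence` values are removed by [remove_outliers()].
#' @examples
#' tukey_fences(c(rnorm(50), 25))
#' @export
tukey_fences <- function(values, inner = 1.5, far = 3.0) {
  values <- as.numeric(values)
  if (length(values) < 4) refuse("Tukey fences need n >= 4")
  q <- quantile_nonparametric(values, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  warnings <- character()
  if (iqr == 0)
    warnings <- "IQR is zero; no fences can be drawn, no values flagged"
  flags <- rep("kept", length(values))
  if (iqr > 0) {
    flags[values < q[1] - inner * iqr | values > q[2] + inner * iqr] <-
      "outside_inner_fence"
    flags[values < q[1] - far * iqr | values > q[2] + far * iqr] <-
      "outside_far_fence"
  }
  new_outlier_report(values, flags, "tukey",
                     c(inner = inner, far = far, q1 = unname(q[1]),
                       q3 = unname(q[2]), iqr = unname(iqr)),
                     warnings)
}

#' Gaussian far-fence exceedance rate in closed form
#'
#' Probability that a standard Gaussian value falls beyond either far fence
#' Q3 + k IQR / Q1 - k IQR, using the population quartiles.  At k = 3 this is
#' about 2.3 per million ("two values per million").
#'
#' @param k fence multiplier (default 3, the far fence).
#' @return Two-sided exceedance probability.
#' @export
gaussian_fence_rate <- function(k = 3) {
  q3 <- stats::qnorm(0.75)
  iqr <- 2 * q3
  2 * stats::pnorm(-(q3 + k * iqr))
}

#' Grubbs' test for outliers
#'
#' Iterative single-outlier Grubbs test on approximately Gaussian data: the
#' most extreme value is tested against the critical value derived from the
#' t distribution and, if significant, flagged and removed from the working
#' set; the test repeats until no further value is significant.  Flags only;
#' removal is a separate explicit step.
#'
#' @param values numeric vector (n >= 7 recommended; refuses below 3).
#' @param alpha significance level (default 0.05).
#' @param max_outliers cap on iterations.
#' @return An `outlier_report` (flag `outside_far_fence` reused for
#'   significant values so that the removal policy is shared).
#' @export
grubbs_test <- function(values, alpha = 0.05, max_outliers = Inf) {
  values <- as.numeric(values)
  n0 <- length(values)
  if (n0 < 3) refuse("Grubbs' test needs n >= 3")
  warnings <- character()
  nt <- normality_test(values)
  if (isFALSE(nt$pass))
    warnings <- sprintf(
      "normality assumption questionable (Anderson-Darling p = %.3g)",
      nt$p_value)
  flags <- rep("kept", n0)
  active <- seq_len(n0)
  while (length(active) >= 3 && sum(flags != "kept") < max_outliers) {
    x <- values[active]
    n <- length(x)
    g <- abs(x - mean(x)) / stats::sd(x)
    i <- which.max(g)
    tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g[i] > gcrit) {
      flags[active[i]] <- "outside_far_fence"
      active <- active[-i]
    } else break
  }
  new_outlier_report(values, flags, "grubbs", c(alpha = alpha), warnings)
}

# Dixon's Q critical values, alpha = 0.05 two-sided (Rorabacher 1991), n 3-30
.dixon_q05 <- c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
                0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
                0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
                0.308, 0.305, 0.301, 0.290)

#' Dixon's Q test for a single outlier at either extreme
#'
#' Q = gap/range for the smallest and largest value, compared with the
#' alpha = 0.05 critical value; assumes approximate normality (the caller's
#' responsibility) and flags at most one value per extreme.
#'
#' @param values numeric vector, 3 <= n <= 30.
#' @param alpha only 0.05 is tabulated.
#' @return An `outlier_report`.
#' @export
dixon_q <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 30)
    refuse("Dixon's Q test is tabulated for 3 <= n <= 30")
  if (!isTRUE(all.equal(alpha, 0.05)))
    refuse("Dixon's Q critical values are tabulated for alpha = 0.05 only")
  warnings <- character()
  nt <- normality_test(values)
  if (isFALSE(nt$pass))
    warnings <- sprintf(
      "normality assumption questionable (Anderson-Darling p = %.3g)",
      nt$p_value)
  qcrit <- .dixon_q05[n - 2]
  o <- order(values)
  x <- values[o]
  rng <- x[n] - x[1]
  flags <- rep("kept", n)
  if (rng > 0) {
    if ((x[2] - x[1]) / rng > qcrit) flags[o[1]] <- "outside_far_fence"
    if ((x[n] - x[n - 1]) / rng > qcrit) flags[o[n]] <- "outside_far_fence"
  }
  new_outlier_report(values, flags, "dixon_q", c(alpha = alpha, q_crit = qcrit),
                     warnings)
}

#' Remove flagged outliers from a reference sample
#'
#' Applies an outlier report to a sample, removing (by default) only values
#' flagged beyond the far fence, and appends the action to the sample's
#' curation log.
#'
#' @param sample a [reference_sample] whose values produced `report` (same
#'   order).
#' @param report an `outlier_report`.
#' @param remove which flags to remove (default far fence only).
#' @return The curated `reference_sample`.
#' @export
remove_outliers <- function(sample, report,
                            remove = "outside_far_fence") {
  stopifnot(inherits(sample, "reference_sample"),
            inherits(report, "outlier_report"),
            nrow(sample$data) == report$n)
  drop <- report$flags %in% remove
  sample$data <- sample$data[!drop, , drop = FALSE]
  sample$curation_log <- c(sample$curation_log, list(list(
    step = "remove_outliers", method = report$method,
    constants = report$constants, removed = sum(drop),
    flags = table(report$flags))))
  sample
}

#' Tukey biweight location and IQR-based scale
#'
#' Robust location by the iterative one-sample Tukey biweight (errors beyond
#' `c_tune` MADs are given zero weight; weights (1 - u^2)^2 inside) and
#' robust scale as IQR/1.349, which matches the standard deviation for
#' Gaussian data.  Used by the small-sample reporting tier and by robust
#' fitting.
#'
#' @param values numeric vector (n >= 5).
#' @param c_tune biweight tuning constant in MAD units (default 6).
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return List with `location`, `scale`, `iterations`, `converged`.
#' @export
robust_location_scale <- function(values, c_tune = 6, max_iter = 50L,
                                  tol = 1e-8) {
  values <- as.numeric(values)
  if (length(values) < 5) refuse("robust location/scale needs n >= 5")
  q <- quantile_nonparametric(values, c(0.25, 0.75))
  scale <- (q[2] - q[1]) / (2 * stats::qnorm(0.75))
  loc <- stats::median(values)
  s0 <- stats::mad(values)
  converged <- FALSE
  it <- 0L
  if (s0 > 0) {
    for (it in seq_len(max_iter)) {
      u <- (values - loc) / (c_tune * s0)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (sum(w) == 0) break
      new <- sum(w * values) / sum(w)
      if (abs(new - loc) <= tol * max(1, abs(loc))) {
        loc <- new; converged <- TRUE; break
      }
      loc <- new
    }
    if (!converged) {
      loc <- stats::median(values)
    }
  } else converged <- TRUE
  if (!converged)
    warning("biweight iteration did not converge; falling back to median")
  list(location = unname(loc), scale = unname(scale),
       iterations = it, converged = converged)
}

#' Fit a continuous age-compensation model
#'
#' Compensating for age with a continuous function (linear in age, or linear
#' in log age for early-life maturation) keeps all subjects in one partition
#' and avoids boundary artefacts of age-group partitions.  Fitting is robust
#' (Tukey bisquare M-estimation via `MASS::rlm`) by default so that age
#' compensation can precede outlier removal — otherwise a true age trend
#' makes the oldest and youngest subjects look like outliers.  Optionally the
#' residual spread above and below the trend is fitted separately against
#' age, so upper and lower limits can diverge with age.
#'
#' @param sample a [reference_sample] with ages, or a data.frame with `age`
#'   and `value`.
#' @param form `"linear"` or `"log_age"`.
#' @param method `"tukey_biweight"` or `"least_squares"`.
#' @param min_age_range refuse age modelling when the observed age span is
#'   smaller than this (years).
#' @param fit_spread also fit |residual| vs age separately for points above
#'   and below the trend.
#' @return An object of class `age_model`: `form`, `coefficients`, `method`,
#'   `age_range`, optional `spread_fits`; or form `"none"` when refused.
#' @export
fit_age_model <- function(sample, form = c("linear", "log_age"),
                          method = c("tukey_biweight", "least_squares"),
                          min_age_range = 5, fit_spread = FALSE) {
  form <- match.arg(form)
  method <- match.arg(method)
  d <- if (inherits(sample, "reference_sample")) sample$data else sample
  ok <- is.finite(d$age)
  if (mean(ok) < 0.9)
    refuse(sprintf("ages present for only %.0f%% of measurements (need >= 90%%)",
                   100 * mean(ok)))
  if (any(!ok))
    warning(sprintf("%d measurement(s) without age excluded from the fit",
                    sum(!ok)))
  d <- d[ok, , drop = FALSE]
  if (form == "log_age" && any(d$age <= 0))
    data_error("log_age form needs ages > 0")
  x <- if (form == "log_age") log(d$age) else d$age
  if (diff(range(d$age)) < min_age_range) {
    warning(sprintf("age range %.1f y below minimum %.1f y; no age model fitted",
                    diff(range(d$age)), min_age_range))
    return(structure(list(form = "none", coefficients = c(0, 0),
                          method = method), class = "age_model"))
  }
  df <- data.frame(x = x, value = d$value)
  fit <- if (method == "tukey_biweight")
    MASS::rlm(value ~ x, data = df, psi = MASS::psi.bisquare, maxit = 50)
  else stats::lm(value ~ x, data = df)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  spread <- NULL
  if (fit_spread) {
    res <- stats::residuals(fit)
    spread <- lapply(list(upper = res >= 0, lower = res < 0), function(idx) {
      if (sum(idx) < 5) return(NULL)
      stats::coef(stats::lm(abs(res[idx]) ~ x[idx]))
    })
  }
  structure(list(form = form, coefficients = co, se = se, method = method,
                 age_range = range(d$age), spread_fits = spread),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  if (x$form == "none") {
    cat("Age model: none\n"); return(invisible(x))
  }
  cat(sprintf("Age model (%s, %s): value = %.4g %+.4g * %s\n",
              x$form, x$method, x$coefficients[1], x$coefficients[2],
              if (x$form == "log_age") "log(age)" else "age"))
  invisible(x)
}

#' Age-adjust a reference sample
#'
#' Removes the fitted age trend, re-centering every value at a reference age
#' so adjusted values remain on the measurement scale.  Appends to the
#' curation log.
#'
#' @param sample a [reference_sample] with ages.
#' @param model an `age_model` from [fit_age_model()].
#' @param reference_age age (years) at which values are expressed; default
#'   the midpoint of the fitted range.
#' @return The adjusted `reference_sample`.
#' @export
age_adjust <- function(sample, model, reference_age = NULL) {
  stopifnot(inherits(sample, "reference_sample"),
            inherits(model, "age_model"))
  if (model$form == "none") return(sample)
  if (any(vapply(sample$curation_log, function(e)
        identical(e$step, "remove_outliers"), TRUE)))
    warning("outliers were removed before age adjustment; adjustment should come first")
  reference_age <- reference_age %||% mean(model$age_range)
  xf <- if (model$form == "log_age") log else identity
  pred <- function(age) model$coefficients[1] + model$coefficients[2] * xf(age)
  ok <- is.finite(sample$data$age)
  if (any(!ok)) {
    warning(sprintf("%d measurement(s) without age dropped in age adjustment",
                    sum(!ok)))
    sample$data <- sample$data[ok, , drop = FALSE]
  }
  sample$data$value <- sample$data$value - pred(sample$data$age) +
    pred(reference_age)
  sample$curation_log <- c(sample$curation_log, list(list(
    step = "age_adjust", form = model$form,
    coefficients = unname(model$coefficients),
    reference_age = reference_age)))
  sample
}

#' Partitioning decision between two demographic subgroups
#'
#' Decides whether two subgroups (e.g. the sexes) need separate reference
#' intervals.  Rules evaluated: (i) subgroup means differ by more than 25% of
#' the combined group's 95% reference-interval width (a stricter 15% variant
#' is reported but not decisive); (ii) more than 4% of either subgroup's
#' points fall beyond one of the combined nonparametric limits — the tails
#' are judged separately against the 2.5% each should hold, since by
#' construction about 5% of every subgroup lies outside the combined limits
#' in total even when the groups are identical; (iii) the ratio of subgroup
#' standard deviations is 1.5 or greater, regardless of the means.  The
#' recommendation is to partition if any decisive rule fires.
#'
#' @param group_a,group_b numeric vectors, each n >= 20.
#' @param coverage combined reference-interval coverage (default 0.95).
#' @return An object of class `partition_decision` with each rule's outcome
#'   and the overall `recommendation` ("combine" or "partition").
#' @export
partition_check <- function(group_a, group_b, coverage = 0.95) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 20 || length(group_b) < 20)
    refuse("partition check needs n >= 20 per subgroup")
  combined <- c(group_a, group_b)
  a <- (1 - coverage) / 2
  lims <- quantile_nonparametric(combined, c(a, 1 - a))
  ri <- diff(lims)
  if (ri <= 0) refuse("combined reference interval is degenerate")
  gap <- abs(mean(group_a) - mean(group_b))
  frac_out <- function(g) max(mean(g < lims[1]), mean(g > lims[2]))
  sa <- stats::sd(group_a); sb <- stats::sd(group_b)
  sd_ratio <- max(sa, sb) / min(sa, sb)
  rules <- list(mean_rule_25pct = gap > 0.25 * ri,
                mean_rule_15pct = gap > 0.15 * ri,
                outside_4pct_rule = max(frac_out(group_a),
                                        frac_out(group_b)) > 0.04,
                sd_ratio_rule = sd_ratio >= 1.5)
  decisive <- c("mean_rule_25pct", "outside_4pct_rule", "sd_ratio_rule")
  structure(list(rules = rules,
                 decisive = decisive,
                 mean_gap = gap, ri_width = ri, sd_ratio = sd_ratio,
                 fraction_outside = c(a = frac_out(group_a),
                                      b = frac_out(group_b)),
                 recommendation = if (any(unlist(rules[decisive])))
                   "partition" else "combine"),
            class = "partition_decision")
}

#' @export
print.partition_decision <- function(x, ...) {
  cat("Partitioning decision:", x$recommendation, "\n")
  for (r in names(x$rules))
    cat(sprintf("  %-18s %s%s\n", r, if (x$rules[[r]]) "fires" else "quiet",
                if (r %in% x$decisive) "" else " (reported only)"))
  invisible(x)
}
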