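# container for an estimated reference limit pair and its uncertainty

new_limit_estimate <- function(lower, upper, method, transform, tails,
                               coverage, confidence, n_subjects, n_values,
                               ri_width, seed = NULL, extras = list(),
                               warnings = character()) {
  est <- structure(list(
    lower_limit = lower$limit %||% NA_real_,
    upper_limit = upper$limit %||% NA_real_,
    ci_lower_limit = lower$ci %||% c(NA_real_, NA_real_),
    ci_upper_limit = upper$ci %||% c(NA_real_, NA_real_),
    method = method, transform = transform, tails = tails,
    coverage = coverage, confidence = confidence,
    n_subjects = n_subjects, n_values = n_values,
    ri_width = as.numeric(ri_width),
    seed = seed, extras = c(extras,
      list(ci_lower_attainable = lower$ci_attainable %||% NA,
           ci_upper_attainable = upper$ci_attainable %||% NA)),
    warnings = warnings), class = "reference_limit_estimate")
  if (!is.na(est$lower_limit) && !is.na(est$upper_limit) &&
      est$lower_limit > est$upper_limit)
    data_error("lower limit exceeds upper limit")
  r <- ci_ri_ratio(est)
  est$ci_ri_ratio <- r
  est$quality_flag <- length(r) > 0L && all(is.finite(r)) && all(r < 0.2)
  est
}

#' CI/RI uncertainty ratio of a reference limit estimate
#'
#' The quality metric for a reference limit: the width of its 90% confidence
#' interval divided by the width of the whole two-tailed 95% reference
#' interval.  The two-tailed 2.5th-97.5th width is used as the denominator
#' even for one-tailed limits, because one-tailed interval widths depend on
#' the most extreme value observed and do not converge with n.  Each ratio
#' should be below 0.2 for a limit to be considered adequately reliable.
#'
#' @param estimate a [reference_limit_estimate].
#' @return Named numeric vector with one ratio per estimated limit (`lower`,
#'   `upper`).  Degenerate reference intervals (width 0) give ratio 0 when
#'   the CI width is also 0 and `NaN` otherwise.
#' @export
ci_ri_ratio <- function(estimate) {
  stopifnot(inherits(estimate, "reference_limit_estimate"))
  ri <- estimate$ri_width
  out <- c()
  for (side in c("lower", "upper")) {
    ci <- estimate[[paste0("ci_", side, "_limit")]]
    if (all(is.na(ci))) next
    w <- diff(ci)
    out[side] <- if (!is.finite(ri)) NA_real_
                 else if (ri > 0) w / ri else if (w == 0) 0 else NaN
  }
  out
}

#' @export
print.reference_limit_estimate <- function(x, ...) {
  cat(sprintf("Reference limits (%s%s, %s, %g%% interval)\n",
              x$method,
              if (x$transform != "none") paste0(", ", x$transform) else "",
              x$tails, 100 * x$coverage))
  fmt <- function(lim, ci, ratio) {
    sprintf("%.6g  [%g%% CI %.6g, %.6g]  CI/RI = %s", lim,
            100 * x$confidence, ci[1], ci[2],
            if (is.null(ratio) || is.na(ratio)) "-" else sprintf("%.3f", ratio))
  }
  if (!is.na(x$lower_limit))
    cat("  lower:", fmt(x$lower_limit, x$ci_lower_limit,
                        x$ci_ri_ratio["lower"]), "\n")
  if (!is.na(x$upper_limit))
    cat("  upper:", fmt(x$upper_limit, x$ci_upper_limit,
                        x$ci_ri_ratio["upper"]), "\n")
  cat(sprintf("  n = %d values from %d subjects; quality (all CI/RI < 0.2): %s\n",
              x$n_values, x$n_subjects,
              if (isTRUE(x$quality_flag)) "pass" else "fail"))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialise a reference limit estimate to JSON
#'
#' @param estimate a [reference_limit_estimate].
#' @param file optional path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
limit_estimate_json <- function(estimate, file = NULL) {
  stopifnot(inherits(estimate, "reference_limit_estimate"))
  x <- unclass(estimate)
  x$extras <- x$extras[vapply(x$extras, function(e)
    is.atomic(e) && length(e) > 0, TRUE)]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
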