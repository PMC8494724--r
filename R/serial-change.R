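# subject-based reference values: repeatability coefficient and delta checks

#' Build replicate sets from long-format measurements
#'
#' Groups replicate measurements into subject-eye units for repeatability
#' estimation.  Each eye is treated as a separate unit, never averaged or
#' pooled with the fellow eye: combining both eyes into one standard
#' deviation artificially inflates it whenever the two eyes' expected values
#' differ (e.g. unilateral disease).
#'
#' @param data data.frame with `subject_id`, `value` and optionally `side`
#'   and `session_id`/`replicate_index`, or a [reference_sample].
#' @param min_k units with fewer replicates than this are dropped with a
#'   note (default 2; a dispersion needs at least two replicates).
#' @return An object of class `replicate_sets`: data.frame with one row per
#'   unit (`unit_id`, `subject_id`, `k`, `mean`, `sd`, `cv` in percent).
#' @export
replicate_sets <- function(data, min_k = 2L) {
  d <- if (inherits(data, "reference_sample")) data$data else data
  stopifnot(all(c("subject_id", "value") %in% names(d)))
  if (is.null(d$side)) d$side <- NA_character_
  unit <- paste(d$subject_id, ifelse(is.na(d$side), "U", d$side), sep = ":")
  agg <- lapply(split(d$value, unit), function(v)
    c(k = length(v), mean = mean(v), sd = stats::sd(v)))
  subj_of <- vapply(split(d$subject_id, unit), `[[`, "", 1L)
  df <- data.frame(unit_id = names(agg),
                   subject_id = unname(subj_of[names(agg)]),
                   k = vapply(agg, `[[`, 0, "k"),
                   mean = vapply(agg, `[[`, 0, "mean"),
                   sd = vapply(agg, `[[`, 0, "sd"),
                   row.names = NULL)
  df$cv <- 100 * df$sd / df$mean
  dropped <- df$k < min_k
  if (all(dropped)) refuse("no unit has two or more replicates")
  if (any(dropped))
    message(sprintf("%d unit(s) with fewer than %d replicates dropped",
                    sum(dropped), min_k))
  structure(df[!dropped, , drop = FALSE], class = c("replicate_sets",
                                                    "data.frame"))
}

#' Pooled within-unit dispersion
#'
#' Weighted average of per-unit replicate dispersions, weighting each unit by
#' its degrees of freedom so units with more replicates count for more:
#' sqrt( sum (k_i - 1) s_i^2 / sum (k_i - 1) ).  The CV basis pools the
#' per-unit coefficients of variation analogously.
#'
#' @param sets a `replicate_sets` object (or data.frame with columns `k` and
#'   `sd`/`cv`).
#' @param basis `"sd"` (absolute units; use for peak times) or `"cv"`
#'   (percent; use for amplitudes).
#' @return Pooled dispersion (same units as the basis).
#' @examples
#' s <- data.frame(k = c(3, 2), sd = c(2, 0), cv = c(10, 0))
#' pooled_dispersion(s, "sd")  # sqrt(8/3)
#' @export
pooled_dispersion <- function(sets, basis = c("sd", "cv")) {
  basis <- match.arg(basis)
  k <- sets$k
  if (!length(k) || all(k < 2)) refuse("every unit needs k >= 2 replicates")
  disp <- sets[[basis]]
  w <- k - 1
  sqrt(sum(w * disp^2) / sum(w))
}

#' Repeatability coefficient
#'
#' The critical difference for serial measurements: RC = z sqrt(2) x the
#' within-unit dispersion (SD in measurement units or CV in percent).  At
#' z = 1.96 this is RC = 2.77 x SD (or CV), giving a 5% false-positive rate
#' for declaring a change; larger z trades false positives for false
#' negatives.
#'
#' @param dispersion pooled within-unit SD or CV (>= 0).
#' @param z z-statistic (default 1.96).
#' @return RC in the units of `dispersion`.
#' @examples
#' repeatability_coefficient(10)  # 27.7 (percent, for CV = 10%)
#' @export
repeatability_coefficient <- function(dispersion, z = 1.96) {
  stopifnot(all(dispersion >= 0))
  z * sqrt(2) * dispersion
}

#' Repeatability estimate from replicate sets
#'
#' Pools the per-unit dispersions ([pooled_dispersion()]) and converts to a
#' repeatability coefficient, optionally with a bootstrap CI
#' ([rc_uncertainty()]).  The basis defaults from the parameter type:
#' SD for times, CV for amplitudes.
#'
#' @param sets a `replicate_sets` object.
#' @param basis `"sd"` or `"cv"`.
#' @param z z-statistic (default 1.96).
#' @param ci_B bootstrap resamples for the CI (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `repeatability_estimate`: `rc`, `basis`, `z`,
#'   `pooled_dispersion`, `n_units`, `ci90` (or NULL), `flags`.
#' @export
rc_estimate <- function(sets, basis = c("sd", "cv"), z = 1.96, ci_B = 0L,
                        seed = NULL) {
  basis <- match.arg(basis)
  disp <- pooled_dispersion(sets, basis)
  flags <- character()
  if (nrow(sets) < 8)
    flags <- sprintf("only %d units; the RC needs at least eight subjects",
                     nrow(sets))
  ci <- NULL
  if (ci_B > 0)
    ci <- rc_uncertainty(sets, basis, B = ci_B, seed = seed, z = z,
                         .warn_small = FALSE)$ci90
  structure(list(rc = repeatability_coefficient(disp, z), basis = basis,
                 z = z, pooled_dispersion = disp, n_units = nrow(sets),
                 ci90 = ci, flags = flags),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  unit <- if (x$basis == "cv") "%" else " (measurement units)"
  cat(sprintf("Repeatability coefficient: %.4g%s (z = %g, %s basis, %d units)\n",
              x$rc, unit, x$z, toupper(x$basis), x$n_units))
  if (!is.null(x$ci90))
    cat(sprintf("  90%% CI: %.4g to %.4g\n", x$ci90[1], x$ci90[2]))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Bootstrap uncertainty of the repeatability coefficient
#'
#' Percentile bootstrap CI of the RC.  Resampling is at the subject level,
#' carrying each subject's eye-units together, so the within-subject
#' correlation between fellow eyes is respected.
#'
#' @param sets a `replicate_sets` object.
#' @param basis `"sd"` or `"cv"`.
#' @param B resamples (default 1000).
#' @param seed RNG seed.
#' @param z z-statistic.
#' @param confidence CI level (default 0.90).
#' @param .warn_small internal; set FALSE to suppress the small-N warning.
#' @return List with `ci90` (CI of the RC), `rc`, `flagged_small`.
#' @export
rc_uncertainty <- function(sets, basis = c("sd", "cv"), B = 1000L,
                           seed = NULL, z = 1.96, confidence = 0.90,
                           .warn_small = TRUE) {
  basis <- match.arg(basis)
  subj <- split(seq_len(nrow(sets)), sets$subject_id)
  nsub <- length(subj)
  flagged <- nsub < 8
  if (flagged && .warn_small)
    warning(sprintf("only %d subjects; the RC needs at least eight", nsub))
  rc0 <- repeatability_coefficient(pooled_dispersion(sets, basis), z)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- unlist(subj[sample.int(nsub, nsub, replace = TRUE)],
                  use.names = FALSE)
    repeatability_coefficient(pooled_dispersion(sets[idx, , drop = FALSE],
                                                basis), z)
  }, 0))
  a <- (1 - confidence) / 2
  list(ci90 = unname(stats::quantile(reps, c(a, 1 - a), type = 5)),
       rc = rc0, flagged_small = flagged)
}

#' Delta check for a serial measurement
#'
#' Decides whether a parameter has changed by more than measurement noise
#' between two visits.  On the CV basis the percent change
#' 100 |current - previous| / previous is compared with the RC; on the SD
#' basis the absolute change is compared.  A change must strictly exceed the
#' RC to be declared; a change exactly equal to the RC is reported as no
#' change.
#'
#' @param previous,current the two serial values (same units).
#' @param rc a `repeatability_estimate` (or a number, interpreted with
#'   `basis`).
#' @param basis used only when `rc` is numeric.
#' @return Object of class `delta_verdict`: `verdict` ("no_change",
#'   "changed_up", "changed_down"), `change`, `rc`, `basis`.
#' @examples
#' rc <- structure(list(rc = 27.7, basis = "cv"),
#'                 class = "repeatability_estimate")
#' delta_check(100, 70, rc)$verdict  # "changed_down"
#' @export
delta_check <- function(previous, current, rc, basis = c("sd", "cv")) {
  if (inherits(rc, "repeatability_estimate")) {
    basis <- rc$basis
    rc_val <- rc$rc
  } else {
    basis <- match.arg(basis)
    rc_val <- as.numeric(rc)
  }
  stopifnot(is.finite(previous), is.finite(current), rc_val >= 0)
  if (basis == "cv") {
    if (previous <= 0)
      refuse("CV-basis delta check needs a positive previous value")
    change <- 100 * (current - previous) / previous
  } else {
    change <- current - previous
  }
  verdict <- if (abs(change) > rc_val) {
    if (change > 0) "changed_up" else "changed_down"
  } else "no_change"
  structure(list(verdict = verdict, change = change, rc = rc_val,
                 basis = basis, previous = previous, current = current),
            class = "delta_verdict")
}

#' @export
print.delta_verdict <- function(x, ...) {
  unit <- if (x$basis == "cv") "%" else ""
  cat(sprintf("Delta check: %.4g -> %.4g (change %.4g%s vs RC %.4g%s): %s\n",
              x$previous, x$current, x$change, unit, x$rc, unit, x$verdict))
  invisible(x)
}

#' Default repeatability basis for a parameter type
#'
#' Variability of peak times is expressed in absolute units (SD basis, ms);
#' variability of amplitudes in percent (CV basis).
#'
#' @param parameter_type "amplitude", "time" or "other".
#' @return "cv" for amplitudes, "sd" otherwise.
#' @export
default_rc_basis <- function(parameter_type) {
  if (identical(parameter_type, "amplitude")) "cv" else "sd"
}
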