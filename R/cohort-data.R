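#' Construct a reference sample
#'
#' A reference sample holds the curated measurements for one test parameter
#' (for example the dark-adapted ERG b-wave amplitude) within one partition of
#' the reference population (for example females aged 18-60).  Measurements are
#' stored long format, one row per measured value, so that bilateral (two-eye)
#' data, replicates and sessions all use the same schema.
#'
#' @param data data.frame with at least columns `subject_id` and `value`;
#'   optional columns `side` ("R", "L" or NA), `units`, `age`, `sex`,
#'   `session_id`, `replicate_index`.
#' @param parameter name of the measured parameter (single string).
#' @param partition named character vector of partition factor levels, e.g.
#'   `c(sex = "female")`.
#' @param units measurement units (e.g. "uV" for amplitudes, "ms" for peak
#'   times); taken from the data if present there.
#' @param parameter_type one of "amplitude", "time" or "other"; drives the
#'   positivity invariant and the default repeatability basis (CV for
#'   amplitudes, SD for times).
#' @return An object of class `reference_sample`.
#' @examples
#' d <- data.frame(subject_id = c("s1", "s1", "s2", "s2"),
#'                 side = c("R", "L", "R", "L"),
#'                 value = c(101, 98, 110, 113))
#' s <- reference_sample(d, parameter = "b_amp", units = "uV")
#' n_subjects(s)
#' @export
reference_sample <- function(data, parameter, partition = NULL, units = NULL,
                             parameter_type = c("other", "amplitude", "time")) {
  parameter_type <- match.arg(parameter_type)
  if (!is.data.frame(data)) data_error("`data` must be a data.frame")
  need <- c("subject_id", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    data_error(sprintf("missing mandatory column(s): %s",
                       paste(miss, collapse = ", ")))
  data$subject_id <- as.character(data$subject_id)
  data$value <- as.numeric(data$value)
  if (any(!is.finite(data$value)))
    data_error("all measurement values must be finite")
  if (parameter_type %in% c("amplitude", "time") && any(data$value <= 0))
    data_error(sprintf("%s values must be > 0", parameter_type))
  if (is.null(data$side)) data$side <- NA_character_
  data$side <- normalise_side(data$side)
  for (col in c("units", "sex", "session_id"))
    if (is.null(data[[col]])) data[[col]] <- NA_character_
  if (is.null(data$age)) data$age <- NA_real_
  if (is.null(data$replicate_index)) data$replicate_index <- NA_integer_
  if (is.null(units)) {
    u <- unique(stats::na.omit(data$units))
    units <- if (length(u) == 1L) u else NA_character_
  }
  key <- paste(data$subject_id, data$side, data$session_id,
               data$replicate_index, sep = "\r")
  if (anyDuplicated(key))
    data_error("(subject_id, side, session_id, replicate_index) must be unique")
  structure(list(parameter = as.character(parameter)[1L],
                 data = data,
                 partition = partition,
                 units = units,
                 parameter_type = parameter_type,
                 curation_log = list()),
            class = "reference_sample")
}

normalise_side <- function(side) {
  side <- toupper(trimws(as.character(side)))
  side[side %in% c("", "NA", "UNSPECIFIED")] <- NA_character_
  side[side %in% c("RIGHT", "OD")] <- "R"
  side[side %in% c("LEFT", "OS")] <- "L"
  bad <- !is.na(side) & !side %in% c("R", "L")
  if (any(bad))
    data_error(sprintf("unrecognised side label(s): %s",
                       paste(unique(side[bad]), collapse = ", ")))
  side
}

#' @rdname reference_sample
#' @param x,sample a `reference_sample`.
#' @export
n_subjects <- function(sample) length(unique(sample$data$subject_id))

#' @rdname reference_sample
#' @export
n_measurements <- function(sample) nrow(sample$data)

#' @rdname reference_sample
#' @export
measurement_values <- function(sample) sample$data$value

#' @rdname reference_sample
#' @param ... ignored.
#' @export
print.reference_sample <- function(x, ...) {
  cat(sprintf("Reference sample: %s%s\n", x$parameter,
              if (!is.na(x$units %||% NA)) sprintf(" [%s]", x$units) else ""))
  if (!is.null(x$partition))
    cat("  partition:", paste(names(x$partition), x$partition, sep = "=",
                              collapse = ", "), "\n")
  cat(sprintf("  %d measurements from %d subjects\n",
              n_measurements(x), n_subjects(x)))
  tier <- reporting_tier(n_subjects(x))
  cat(sprintf("  reporting tier: %s (n = %d)\n", tier$tier, tier$n))
  if (length(x$curation_log))
    cat(sprintf("  curation steps applied: %d\n", length(x$curation_log)))
  invisible(x)
}

#' Read a long-format reference data table
#'
#' Reads a UTF-8 CSV with a header row naming at least `subject_id`,
#' `parameter` and `value` columns (optional: `side`, `units`, `age`, `sex`,
#' `session_id`, `replicate_index`) and returns one [reference_sample] per
#' parameter and partition-factor combination.  Rows with non-numeric values
#' are collected as row errors rather than aborting the read, unless every
#' row fails.
#'
#' @param file path or connection to a CSV file.
#' @param partition_by character vector of column names (e.g. `"sex"`) used to
#'   split each parameter's rows into partitions; `NULL` for no partitioning.
#' @param parameter_types optional named character vector mapping parameter
#'   name to "amplitude"/"time"/"other".
#' @return Named list of `reference_sample` objects (names
#'   `parameter[.factor=level]`), with attribute `"row_errors"` holding a
#'   data.frame of rejected rows (line numbers refer to the file, header
#'   included).
#' @export
read_reference_table <- function(file, partition_by = NULL,
                                 parameter_types = NULL) {
  raw <- utils::read.csv(file, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "parameter", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    data_error(sprintf("missing mandatory column(s): %s",
                       paste(miss, collapse = ", ")))
  if (!is.null(partition_by)) {
    missp <- setdiff(partition_by, names(raw))
    if (length(missp))
      data_error(sprintf("partition column(s) not in file: %s",
                         paste(missp, collapse = ", ")))
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- !is.finite(val)
  row_errors <- data.frame(line = which(bad) + 1L,
                           value = raw$value[bad],
                           reason = rep("non-numeric value", sum(bad)))
  if (all(bad) && nrow(raw) > 0L)
    data_error("no row has a numeric value")
  keep <- raw[!bad, , drop = FALSE]
  keep$value <- val[!bad]
  if (!is.null(keep$age)) keep$age <- suppressWarnings(as.numeric(keep$age))
  if (!is.null(keep$replicate_index))
    keep$replicate_index <- suppressWarnings(as.integer(keep$replicate_index))
  split_key <- keep$parameter
  if (!is.null(partition_by))
    for (f in partition_by)
      split_key <- paste(split_key, paste0(f, "=", keep[[f]]), sep = ".")
  out <- lapply(split(keep, split_key), function(d) {
    par <- d$parameter[1L]
    part <- NULL
    if (!is.null(partition_by)) {
      part <- vapply(partition_by, function(f) d[[f]][1L], "")
      names(part) <- partition_by
    }
    ptype <- "other"
    if (!is.null(parameter_types) && par %in% names(parameter_types))
      ptype <- parameter_types[[par]]
    reference_sample(d[setdiff(names(d), "parameter")], parameter = par,
                     partition = part, parameter_type = ptype)
  })
  attr(out, "row_errors") <- row_errors
  out
}

#' Write reference samples back to a long-format CSV
#'
#' Inverse of [read_reference_table()]; the read-write-read round trip is
#' exact for finite decimal values.
#'
#' @param samples a `reference_sample` or list of them.
#' @param file output path.
#' @export
write_reference_table <- function(samples, file) {
  if (inherits(samples, "reference_sample")) samples <- list(samples)
  rows <- do.call(rbind, lapply(samples, function(s) {
    d <- s$data
    d$parameter <- s$parameter
    if (!is.null(s$partition))
      for (f in names(s$partition)) if (is.null(d[[f]])) d[[f]] <- s$partition[[f]]
    d
  }))
  first <- c("subject_id", "side", "parameter", "value")
  rows <- rows[c(first, setdiff(names(rows), first))]
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Reporting tier for a given number of reference subjects
#'
#' Sample-size policy for how reference data may be reported: fewer than 10
#' subjects should not be reported at all; 10-19 support only a ranked table
#' with a median; 20-39 support robust or parametric limits with confidence
#' intervals that are illustrative only; 40-119 additionally permit bootstrap
#' limit estimation; 120 or more support the gold-standard nonparametric
#' limits with exact order-statistic confidence intervals.
#'
#' @param n number of reference subjects (after outlier removal).
#' @return list of class `reporting_tier` with elements `tier` (one of
#'   "refuse", "ranked_table", "robust_small", "transfer_scale", "full") and
#'   `n`.
#' @examples
#' reporting_tier(25)$tier   # "robust_small"
#' reporting_tier(120)$tier  # "full"
#' @export
reporting_tier <- function(n) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 0, n == round(n))
  tier <- if (n < 10) "refuse"
          else if (n < 20) "ranked_table"
          else if (n < 40) "robust_small"
          else if (n < 120) "transfer_scale"
          else "full"
  structure(list(tier = tier, n = as.integer(n)), class = "reporting_tier")
}

#' @export
print.reporting_tier <- function(x, ...) {
  cat(sprintf("Reporting tier for n = %d subjects: %s\n", x$n, x$tier))
  invisible(x)
}
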