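# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

# a small bilateral cohort data.frame: n subjects, both eyes, values around
# 100 with a fixed per-subject offset so eyes correlate
bilateral_df <- function(n = 10, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    subj <- rep(sprintf("s%02d", seq_len(n)), each = 2)
    base <- rep(rnorm(n, 100, 10), each = 2)
    data.frame(subject_id = subj, side = rep(c("R", "L"), n),
               value = base + rnorm(2 * n, 0, 2))
  })
}

write_ref_csv <- function(df, path = tempfile(fileext = ".csv"),
                          parameter = "b_amp") {
  df$parameter <- parameter
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# brute-force order-statistic CI: exhaustive search over every rank pair
oracle_os_ci <- function(n, p, confidence = 0.90) {
  best <- NULL
  for (u in 2:n) for (l in 1:(u - 1)) {
    cov <- sum(stats::dbinom(l:(u - 1), n, p))
    if (cov >= confidence) {
      width <- u - l
      sym <- abs((l + u) / 2 - (0.5 + p * n))
      if (is.null(best) || width < best$width ||
          (width == best$width && sym < best$sym))
        best <- list(lower = l, upper = u, width = width, sym = sym,
                     coverage = cov)
    }
  }
  best
}

# a limit estimate with prescribed limits and CI bands, for classification
new_limit_estimate_for_test <- function(lower, upper, ci_lower, ci_upper,
                                        tails = "two_tailed") {
  visref:::new_limit_estimate(
    lower = if (!is.na(lower)) list(limit = lower, ci = ci_lower),
    upper = if (!is.na(upper)) list(limit = upper, ci = ci_upper),
    method = "nonparametric", transform = "none", tails = tails,
    coverage = 0.95, confidence = 0.90, n_subjects = 120, n_values = 120,
    ri_width = if (!is.na(lower) && !is.na(upper)) upper - lower else 40)
}

# a bare repeatability estimate for delta-check tests
rc_from <- function(rc, basis)
  structure(list(rc = rc, basis = basis, z = 1.96),
            class = "repeatability_estimate")

# values with an exact number of points outside a given interval
values_with_outside <- function(k, interval = c(-1, 1), n = 20) {
  stopifnot(k <= n)
  c(rep(interval[2] + 1, k), rep(mean(interval), n - k))
}
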