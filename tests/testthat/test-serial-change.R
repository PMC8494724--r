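test_that("pooled dispersion is the df-weighted RMS of per-unit dispersions", {
  # worked arithmetic: k = (3, 2), s = (2, 0) -> sqrt(8/3)
  s <- data.frame(k = c(3, 2), sd = c(2, 0), cv = c(10, 0),
                  subject_id = c("a", "b"))
  expect_equal(pooled_dispersion(s, "sd"), sqrt(8 / 3))
  # all sets equal s: pooled equals s
  s2 <- data.frame(k = c(2, 3, 5), sd = 1.7, cv = 8, subject_id = c("a", "b", "c"))
  expect_equal(pooled_dispersion(s2, "sd"), 1.7)
  expect_equal(pooled_dispersion(s2, "cv"), 8)
  # equal k reduces to the unweighted RMS
  s3 <- data.frame(k = 3, sd = c(1, 2, 3), cv = c(5, 10, 15),
                   subject_id = c("a", "b", "c"))
  expect_equal(pooled_dispersion(s3, "sd"), sqrt(mean(c(1, 4, 9))))
  expect_error(pooled_dispersion(data.frame(k = 1, sd = 1, cv = 1), "sd"),
               class = "visref_refusal")
})

test_that("the repeatability coefficient is z sqrt(2) dispersion", {
  expect_equal(round(repeatability_coefficient(1), 2), 2.77)
  expect_equal(repeatability_coefficient(10), 27.7, tolerance = 0.01)
  expect_equal(repeatability_coefficient(0), 0)
  expect_equal(repeatability_coefficient(3, z = 2 * 1.96),
               2 * repeatability_coefficient(3))
  # round trip: RC / (1.96 sqrt 2) recovers the dispersion
  expect_equal(repeatability_coefficient(4.2) / (1.96 * sqrt(2)), 4.2)
})

test_that("eyes are pooled as separate units, never combined across eyes", {
  # unilateral effect: one eye of each subject shifted; per-eye replicate SDs
  # are unaffected, but pooling both eyes of a subject into one set inflates
  # the dispersion
  set.seed(61)
  n <- 30
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- rnorm(1, 100, 5)
    shift <- 20                       # unilateral disease in the left eye
    data.frame(subject_id = sprintf("s%02d", i),
               side = rep(c("R", "L"), each = 3),
               value = c(base + rnorm(3, 0, 2), base + shift + rnorm(3, 0, 2)))
  }))
  per_eye <- replicate_sets(rows)
  expect_equal(nrow(per_eye), 2 * n)
  sd_per_eye <- pooled_dispersion(per_eye, "sd")
  rows_combined <- rows
  rows_combined$side <- NA            # erases eye identity: 6 reps per subject
  sd_combined <- pooled_dispersion(replicate_sets(rows_combined), "sd")
  expect_lt(sd_per_eye, sd_combined)
  expect_equal(sd_per_eye, 2, tolerance = 0.3)  # the true replicate noise
})

test_that("delta checks require strict exceedance of the RC", {
  rc_cv <- rc_from(27.7, "cv")
  expect_identical(delta_check(100, 70, rc_cv)$verdict, "changed_down")
  expect_identical(delta_check(100, 72.4, rc_cv)$verdict, "no_change")
  expect_identical(delta_check(100, 130, rc_cv)$verdict, "changed_up")
  # boundary: a change exactly equal to the RC is not a change
  expect_identical(delta_check(50, 52, rc_from(2, "sd"))$verdict, "no_change")
  rc_sd <- rc_from(2.77, "sd")
  expect_identical(delta_check(50, 51, rc_sd)$verdict, "no_change")
  expect_identical(delta_check(50, 53, rc_sd)$verdict, "changed_up")
  expect_error(delta_check(0, 10, rc_cv), class = "visref_refusal")
  # basis defaults: CV for amplitudes, SD otherwise
  expect_identical(default_rc_basis("amplitude"), "cv")
  expect_identical(default_rc_basis("time"), "sd")
})

test_that("bootstrap RC uncertainty covers the true value and flags tiny cohorts", {
  # identical sets: zero-width CI
  s <- data.frame(k = 3, sd = 1.5, cv = 10,
                  subject_id = sprintf("s%02d", 1:12))
  u <- rc_uncertainty(s, "sd", B = 200, seed = 62)
  expect_equal(diff(u$ci90), 0)
  expect_false(u$flagged_small)
  # nested simulation: CI contains the true RC = 2.77 sigma most of the time
  set.seed(63)
  sigma <- 2
  hits <- 0L
  runs <- 40L
  for (i in seq_len(runs)) {
    reps <- do.call(rbind, lapply(1:20, function(j)
      data.frame(subject_id = sprintf("u%02d", j), side = "R",
                 value = rnorm(4, 100, sigma))))
    sets <- replicate_sets(reps)
    ci <- rc_uncertainty(sets, "sd", B = 300, seed = i)$ci90
    true_rc <- repeatability_coefficient(sigma)
    hits <- hits + (ci[1] <= true_rc && true_rc <= ci[2])
  }
  expect_gte(hits / runs, 0.75)      # near-nominal 90% with MC slack
  # minimal eight-unit cohorts run, smaller ones are flagged
  s8 <- data.frame(k = 2, sd = rnorm(8, 2, 0.1), cv = 10,
                   subject_id = sprintf("m%d", 1:8))
  expect_false(rc_uncertainty(s8, "sd", B = 100, seed = 1)$flagged_small)
  s5 <- s8[1:5, ]
  expect_warning(u5 <- rc_uncertainty(s5, "sd", B = 100, seed = 1),
                 "eight")
  expect_true(u5$flagged_small)
})
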