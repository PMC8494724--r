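test_that("eye strategies resolve bilateral data as specified", {
  d <- bilateral_df(8)
  s <- reference_sample(d, "b_amp")

  all_eyes <- apply_eye_strategy(s, "all_eyes_independent")
  expect_length(all_eyes$values, 16)

  one <- apply_eye_strategy(s, "one_eye")
  expect_length(one$values, 8)
  # right-eye preference by default
  expect_equal(sort(one$values), sort(d$value[d$side == "R"]))
  left <- apply_eye_strategy(s, "one_eye", prefer = "left")
  expect_equal(sort(left$values), sort(d$value[d$side == "L"]))

  # all bilateral: duplication is identical to using all eyes
  dup <- apply_eye_strategy(s, "duplicate_singletons")
  expect_equal(sort(dup$values), sort(all_eyes$values))

  # all single-eye: every value appears twice and (at n where the rank
  # arithmetic aligns) nonparametric limits equal the one-eye limits
  d1 <- d[d$side == "R", ]
  d1 <- d1[rep(1:8, 5), ]          # 40 single-eye subjects
  d1$subject_id <- sprintf("t%02d", 1:40)
  s1 <- reference_sample(d1, "b_amp")
  dup1 <- apply_eye_strategy(s1, "duplicate_singletons")
  expect_length(dup1$values, 80)
  expect_equal(sort(dup1$values), sort(rep(d1$value, 2)))
  e_dup <- nonparametric_limits(dup1$values, n_subjects = 40)
  e_one <- nonparametric_limits(d1$value)
  expect_equal(e_dup$lower_limit, e_one$lower_limit)
  expect_equal(e_dup$upper_limit, e_one$upper_limit)

  # mixed 75% bilateral: duplication gives exactly two values per subject
  spec <- bilateral_cohort_spec(40, r = 0.6, fraction_bilateral = 0.75,
                                seed = 2)
  sm <- generate_bilateral_cohort(spec)
  dupm <- apply_eye_strategy(sm, "duplicate_singletons")
  expect_equal(as.integer(table(dupm$subject)), rep(2L, 40))

  # more than two values per subject is a data error
  d_bad <- rbind(d, data.frame(subject_id = "s01", side = NA,
                               value = 100))
  expect_error(apply_eye_strategy(reference_sample(d_bad, "x")),
               class = "visref_data_error")
})

test_that("subject bootstrap limits behave at the degenerate and skewed ends", {
  # identical values: limits equal that value, CI width zero
  d <- data.frame(subject_id = sprintf("s%02d", rep(1:45, each = 2)),
                  side = rep(c("R", "L"), 45), value = 7)
  s <- reference_sample(d, "flat")
  est <- bootstrap_limits(s, B = 200, seed = 3)
  expect_equal(est$lower_limit, 7)
  expect_equal(est$upper_limit, 7)
  expect_equal(diff(est$ci_lower_limit), 0)
  expect_equal(diff(est$ci_upper_limit), 0)

  # reproducibility from the seed
  e1 <- bootstrap_limits(generate_bilateral_cohort(
    bilateral_cohort_spec(60, r = 0.5, seed = 4)), B = 150, seed = 9)
  e2 <- bootstrap_limits(generate_bilateral_cohort(
    bilateral_cohort_spec(60, r = 0.5, seed = 4)), B = 150, seed = 9)
  expect_identical(e1$ci_lower_limit, e2$ci_lower_limit)

  # small B warns; refusal below the reporting floor
  expect_warning(bootstrap_limits(s, B = 50, seed = 1), "B < 100")
  tiny <- reference_sample(d[1:10, ], "flat")
  expect_error(bootstrap_limits(tiny, B = 100, seed = 1),
               class = "visref_refusal")
})

test_that("bootstrapping narrows the CI of a skewed sample's long-tail limit", {
  x <- generate_skewed_reference(120, seed = 21)
  d <- data.frame(subject_id = sprintf("s%03d", 1:120), side = "R",
                  value = as.numeric(x))
  s <- reference_sample(d, "amp")
  npe <- nonparametric_limits(as.numeric(x))
  bte <- bootstrap_limits(s, strategy = "one_eye", B = 1000, seed = 22)
  expect_lt(ci_ri_ratio(bte)["upper"], ci_ri_ratio(npe)["upper"])
})

test_that("at perfect inter-eye correlation one-eye and all-eyes bootstrap CIs agree", {
  spec <- bilateral_cohort_spec(80, r = 1, seed = 5)
  sm <- generate_bilateral_cohort(spec)
  # each subject's two values are identical at r = 1
  expect_true(all(tapply(sm$data$value, sm$data$subject_id,
                         function(v) diff(range(v)) == 0)))
  e_all <- bootstrap_limits(sm, strategy = "all_eyes_independent",
                            B = 800, seed = 6)
  e_one <- bootstrap_limits(sm, strategy = "one_eye", B = 800, seed = 6)
  w_all <- diff(e_all$ci_lower_limit)
  w_one <- diff(e_one$ci_lower_limit)
  # identical information: widths agree within Monte-Carlo error
  expect_equal(w_all, w_one, tolerance = 0.25)
})
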