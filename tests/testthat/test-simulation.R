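test_that("bilateral cohort generation honours correlation and design fractions", {
  # r = 1: both eyes identical per subject
  s1 <- generate_bilateral_cohort(bilateral_cohort_spec(50, r = 1, seed = 71))
  expect_true(all(tapply(s1$data$value, s1$data$subject_id,
                         function(v) diff(range(v)) == 0)))
  # r = 0 at n = 10 000: sample inter-eye correlation near zero
  s0 <- generate_bilateral_cohort(bilateral_cohort_spec(10000, r = 0,
                                                        seed = 72))
  w <- reshape(s0$data[c("subject_id", "side", "value")],
               idvar = "subject_id", timevar = "side", direction = "wide")
  expect_lt(abs(cor(w$value.R, w$value.L)), 0.03)
  # 75% bilateral: 75% of subjects contribute two rows
  sf <- generate_bilateral_cohort(bilateral_cohort_spec(200, r = 0.5,
                                                        fraction_bilateral = 0.75,
                                                        seed = 73))
  rows_per <- table(sf$data$subject_id)
  expect_equal(sum(rows_per == 2), 150)
  expect_equal(sum(rows_per == 1), 50)
  # pure function of the spec: same seed, same bytes
  sa <- generate_bilateral_cohort(bilateral_cohort_spec(30, r = 0.4, seed = 74))
  sb <- generate_bilateral_cohort(bilateral_cohort_spec(30, r = 0.4, seed = 74))
  expect_identical(sa$data, sb$data)
  expect_error(bilateral_cohort_spec(10, r = 1.2), class = "visref_data_error")
})

test_that("skewed generators expose analytic quantiles and reproduce exactly", {
  v <- generate_skewed_reference(120, seed = 75)
  expect_length(v, 120)
  q <- attr(v, "qfun")(c(0.025, 0.975))
  expect_lt(q[1], q[2])
  v2 <- generate_skewed_reference(120, seed = 75)
  expect_identical(as.numeric(v), as.numeric(v2))
  # log of a log-normal sample passes normality in nearly all seeded runs
  pass <- vapply(1:20, function(s) {
    x <- generate_skewed_reference(1000, distribution_spec("lognormal"),
                                   seed = s)
    nortest::ad.test(log(as.numeric(x)))$p.value >= 0.05
  }, TRUE)
  expect_gte(mean(pass), 0.9)
})

test_that("copula-correlated gamma pairs keep the marginal distribution", {
  spec <- bilateral_cohort_spec(5000, r = 0.8,
                                distribution = distribution_spec("gamma"),
                                seed = 76)
  s <- generate_bilateral_cohort(spec)
  v <- s$data$value
  # marginal matches the analytic gamma quantiles
  expect_equal(quantile_nonparametric(v, 0.5),
               qgamma(0.5, 12, scale = 25), tolerance = 0.02)
  # strong positive dependence survives the transform
  w <- reshape(s$data[c("subject_id", "side", "value")],
               idvar = "subject_id", timevar = "side", direction = "wide")
  expect_gt(cor(w$value.R, w$value.L, method = "spearman"), 0.7)
})

test_that("the approximation-error curve is monotone with 1/n scaling", {
  e <- eq2_error_curve(c(20, 40, 80, 160, 320))
  for (ep in unique(e$endpoint)) {
    err <- e$rel_error[e$endpoint == ep]
    expect_true(all(diff(err) < 0), info = ep)
    slope <- coef(lm(log(err) ~ log(c(20, 40, 80, 160, 320))))[2]
    expect_gt(slope, -1.15)
    expect_lt(slope, -0.85)
  }
})

test_that("strategy experiment cells carry Monte-Carlo errors and obey r = 1 logic", {
  g <- strategy_ci_experiment(r_grid = c(0, 1), n_grid = 60, reps = 1500,
                              seed = 77)
  expect_true(all(g$ci_ri_pct > 0))
  expect_true(all(is.finite(g$mc_se_pct)))
  # at r = 1 all strategies coincide exactly (identical estimator)
  at1 <- g[g$r == 1, ]
  expect_lt(diff(range(at1$ci_ri_pct)), 1e-10)
  # at r = 0 using all eyes beats one eye
  at0 <- g[g$r == 0, ]
  expect_lt(at0$ci_ri_pct[at0$strategy == "all_eyes_independent"],
            at0$ci_ri_pct[at0$strategy == "one_eye"])
})
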