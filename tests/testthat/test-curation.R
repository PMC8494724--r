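test_that("Tukey fences flag by quartile distance and retain by default", {
  set.seed(31)
  x <- c(rnorm(60), 30)             # one gross point
  rep_ <- tukey_fences(x)
  expect_identical(rep_$flags[61], "outside_far_fence")
  expect_equal(sum(rep_$flags == "outside_far_fence"), 1)
  # all equal: zero outliers, warning about zero IQR
  flat <- tukey_fences(rep(5, 10))
  expect_true(all(flat$flags == "kept"))
  expect_match(flat$warnings, "IQR")
  # flags invariant under monotone affine transforms
  y <- 3 * x - 100
  expect_identical(tukey_fences(y)$flags, rep_$flags)
  yn <- -2 * x + 5                  # order-reversing affine map
  expect_identical(tukey_fences(yn)$flags, rep_$flags)
  expect_error(tukey_fences(1:3), class = "visref_refusal")
})

test_that("closed-form Gaussian far-fence rate is ~2 per million; gamma far higher", {
  expect_equal(round(1e6 * gaussian_fence_rate()), 2)
  expect_lt(gaussian_fence_rate(), 1e-5)  # conservative retention on Gaussians
  # Monte-Carlo oracle for a skewed gamma: exceedance around per-mille scale
  set.seed(32)
  g <- rgamma(1e6, shape = 2, scale = 1)
  q <- quantile_nonparametric(g, c(0.25, 0.75))
  iqr <- diff(q)
  mc_rate <- mean(g > q[2] + 3 * iqr | g < q[1] - 3 * iqr)
  rep_ <- tukey_fences(g)
  pkg_rate <- mean(rep_$flags == "outside_far_fence")
  expect_equal(pkg_rate, mc_rate, tolerance = 1e-6)
  expect_gt(mc_rate, 1e-4)          # orders of magnitude above the Gaussian
})

test_that("Grubbs and Dixon flag injected gross errors but not clean samples", {
  set.seed(33)
  x <- rnorm(50)
  xi <- c(x, 10)                     # 10 sigma injection
  g <- grubbs_test(xi)
  expect_identical(g$flags[51], "outside_far_fence")
  expect_true(all(g$flags[1:50] == "kept"))
  # symmetric three-point sample: nothing to flag
  expect_true(all(grubbs_test(c(1, 2, 3))$flags == "kept"))
  # gamma data surface the normality caveat
  set.seed(34)
  expect_match(grubbs_test(rgamma(100, 2))$warnings, "normality")
  d <- dixon_q(c(1.1, 1.2, 1.15, 1.18, 4.0))
  expect_identical(d$flags[5], "outside_far_fence")
  expect_error(dixon_q(rnorm(40)), class = "visref_refusal")
})

test_that("removing zero outliers leaves limit estimates bit-identical", {
  set.seed(35)
  d <- data.frame(subject_id = sprintf("s%03d", 1:150), side = "R",
                  value = rnorm(150, 100, 10))
  s <- reference_sample(d, "amp")
  rep_ <- tukey_fences(s$data$value)
  s2 <- remove_outliers(s, rep_)
  if (sum(rep_$flags == "outside_far_fence") == 0)
    expect_identical(nonparametric_limits(s2)[1:4],
                     nonparametric_limits(s)[1:4])
  expect_length(s2$curation_log, 1)
})

test_that("robust biweight location and IQR scale resist contamination", {
  set.seed(36)
  x <- rnorm(10000, 50, 4)
  rs <- robust_location_scale(x)
  expect_equal(rs$location, 50, tolerance = 3 * 4 / sqrt(10000) / 50)
  expect_equal(rs$scale, 4, tolerance = 0.05)
  # 10% gross contamination at +100 sigma barely moves the location
  xc <- c(rnorm(9000, 50, 4), rep(50 + 400, 1000))
  rc <- robust_location_scale(xc)
  expect_lt(abs(rc$location - 50), 0.1 * 4)
  # two symmetric points: midpoint
  expect_equal(robust_location_scale(c(2, 2, 4, 4, 3))$location, 3,
               tolerance = 1e-6)
  expect_error(robust_location_scale(1:4), class = "visref_refusal")
})

test_that("age models recover a linear trend and refuse flat designs", {
  set.seed(37)
  n <- 200
  age <- runif(n, 20, 80)
  d <- data.frame(subject_id = sprintf("s%03d", 1:n), side = "R",
                  value = 100 - 0.2 * age + rnorm(n, 0, 3), age = age)
  s <- reference_sample(d, "amp")
  m <- fit_age_model(s, form = "linear")
  expect_equal(unname(m$coefficients[2]), -0.2,
               tolerance = 3 * m$se[2] / 0.2)
  # age-independent data: slope CI contains zero
  d0 <- d; d0$value <- rnorm(n, 100, 3)
  m0 <- fit_age_model(reference_sample(d0, "amp"), form = "linear")
  expect_lt(abs(m0$coefficients[2]), 2 * m0$se[2])
  # insufficient age spread refuses modelling
  dn <- d; dn$age <- runif(n, 40, 42)
  expect_warning(mn <- fit_age_model(reference_sample(dn, "amp")),
                 "age range")
  expect_identical(mn$form, "none")
})

test_that("age adjustment precedes outlier detection to protect the elderly", {
  set.seed(38)
  n <- 300
  age <- c(runif(n - 30, 20, 60), runif(30, 75, 90))  # an elderly tail
  d <- data.frame(subject_id = sprintf("s%03d", 1:n), side = "R",
                  value = 120 - 0.8 * age + rnorm(n, 0, 2), age = age)
  s <- reference_sample(d, "peak_time")
  before <- tukey_fences(s$data$value)
  m <- fit_age_model(s, form = "linear")
  s_adj <- age_adjust(s, m)
  after <- tukey_fences(s_adj$data$value)
  elderly <- which(age > 75)
  flagged_before <- sum(before$flags[elderly] != "kept")
  flagged_after <- sum(after$flags[elderly] != "kept")
  expect_gt(flagged_before, flagged_after)  # the direction of the hazard
  expect_length(s_adj$curation_log, 1)
})

test_that("partitioning rules fire on mean gaps and SD ratios", {
  set.seed(39)
  a <- rnorm(200, 100, 10)
  # identical groups: combine
  expect_identical(partition_check(a, a)$recommendation, "combine")
  # a 16-unit mean gap is ~30% of the combined RI width: the 25% rule fires
  b <- a + 16
  dec <- partition_check(a, b)
  expect_true(dec$rules$mean_rule_25pct)
  expect_identical(dec$recommendation, "partition")
  # equal means, SD ratio 1.6: rule (iii) alone partitions
  set.seed(40)
  c1 <- rnorm(500, 100, 10)
  c2 <- 100 + (rnorm(500, 100, 16) - 100)
  dec2 <- partition_check(c1, c2)
  expect_true(dec2$rules$sd_ratio_rule)
  expect_identical(dec2$recommendation, "partition")
  expect_error(partition_check(rnorm(10), rnorm(30)),
               class = "visref_refusal")
})
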