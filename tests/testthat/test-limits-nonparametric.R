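test_that("rank index follows 0.5 + p n", {
  expect_equal(rank_index(0.025, 100), 3)
  expect_equal(rank_index(0.5, 1), 1)
  expect_equal(rank_index(0.975, 100), 98)
  expect_error(rank_index(1.2, 10), class = "visref_data_error")
  expect_error(rank_index(0, 10), class = "visref_data_error")
})

test_that("nonparametric quantiles match the type-5 oracle and handle edges", {
  # the interpolating convention is exactly stats::quantile type = 5
  set.seed(42)
  for (n in c(5, 39, 40, 100, 257)) {
    x <- rnorm(n)
    p <- runif(8, 0.01, 0.99)
    expect_equal(quantile_nonparametric(x, p),
                 unname(stats::quantile(x, p, type = 5)),
                 tolerance = 1e-12)
  }
  # worked example: rank 3 of 1..100 at the 2.5th percentile
  expect_equal(quantile_nonparametric(1:100, 0.025), 3)
  # odd n median is the middle order statistic
  expect_equal(quantile_nonparametric(c(9, 1, 5), 0.5), 5)
  # clamping at extreme ranks
  expect_equal(quantile_nonparametric(1:10, 0.011), 1)
  expect_error(quantile_nonparametric(numeric(0), 0.5),
               class = "visref_data_error")
})

test_that("rounded-rank convention keeps the 10th percentile of repeated digit sets at 1", {
  for (k in c(1, 2, 5, 10))
    expect_equal(quantile_nonparametric(rep(0:9, k), 0.10, "round"), 1)
})

test_that("minimum n to separate adjacent percentiles follows 100/P - 1", {
  expect_equal(min_n_for_separation(2.5), 39)
  expect_equal(min_n_for_separation(100), 0)
  expect_equal(min_n_for_separation(5), 19)
  expect_error(min_n_for_separation(0), class = "visref_data_error")
})

test_that("order-statistic CI matches an exhaustive brute-force search", {
  for (case in list(c(120, 0.025), c(120, 0.975), c(100, 0.05),
                    c(60, 0.5), c(200, 0.025))) {
    n <- case[1]; p <- case[2]
    got <- order_statistic_ci(n, p)
    oracle <- oracle_os_ci(n, p)
    expect_true(got$attainable, info = sprintf("n=%d p=%g", n, p))
    expect_equal(c(got$lower, got$upper), c(oracle$lower, oracle$upper),
                 info = sprintf("n=%d p=%g", n, p))
    expect_equal(got$coverage, oracle$coverage, tolerance = 1e-12)
  }
  # at the bare-minimum 39 points no interior pair reaches 90%: the extreme
  # values are the only available bracket
  res <- order_statistic_ci(39, 0.025)
  expect_false(res$attainable)
  expect_equal(c(res$lower, res$upper), c(1, 39))
  # zero required confidence is always attainable next to the median
  res0 <- order_statistic_ci(11, 0.5, confidence = 0)
  expect_true(res0$attainable)
  expect_equal(res0$upper - res0$lower, 1)
})

test_that("smallest n for an exact equal-tailed CI of the 2.5th percentile is 119", {
  # brute force on the defining condition: the minimum must lie below the
  # percentile with >= 95% probability, i.e. 0.975^n <= 0.05
  brute <- which(0.975^(2:400) <= 0.05 & 0.025^(2:400) <= 0.05)[1] + 1
  expect_equal(min_n_exact_ci(0.025, 0.90), brute)
  expect_equal(brute, 119)  # the conventional recommendation rounds to 120
  # pure-coverage attainability starts earlier
  expect_lt(min_n_exact_ci(0.025, 0.90, convention = "coverage"), 119)
})

test_that("nonparametric limit estimates equal a sort-and-index oracle", {
  set.seed(7)
  x <- rgamma(200, shape = 5, scale = 20)
  est <- nonparametric_limits(x)
  xs <- sort(x)
  # oracle: explicit rank arithmetic
  r_lo <- 0.5 + 0.025 * 200   # 5.5
  r_hi <- 0.5 + 0.975 * 200   # 195.5
  expect_equal(est$lower_limit, mean(xs[5:6]))
  expect_equal(est$upper_limit, mean(xs[195:196]))
  # each limit lies inside its own CI; limits ordered
  expect_lte(est$ci_lower_limit[1], est$lower_limit)
  expect_gte(est$ci_lower_limit[2], est$lower_limit)
  expect_lte(est$lower_limit, est$upper_limit)
})

test_that("one-tailed modes use the 5th/95th percentile but a two-tailed RI denominator", {
  set.seed(8)
  x <- rnorm(500)
  lo <- nonparametric_limits(x, tails = "lower_only")
  expect_true(is.na(lo$upper_limit))
  expect_equal(lo$lower_limit, quantile_nonparametric(x, 0.05))
  two <- nonparametric_limits(x)
  expect_equal(lo$ri_width, two$ri_width)  # same 2.5-97.5 denominator
  up <- nonparametric_limits(x, tails = "upper_only")
  expect_equal(up$upper_limit, quantile_nonparametric(x, 0.95))
})

test_that("CI/RI ratio boundary behaviour and skew asymmetry", {
  set.seed(9)
  # degenerate CI width 0 gives ratio 0 and a pass
  est <- nonparametric_limits(rnorm(200))
  est$ci_lower_limit <- rep(est$lower_limit, 2)
  est$ci_upper_limit <- rep(est$upper_limit, 2)
  r <- ci_ri_ratio(est)
  expect_equal(unname(r), c(0, 0))
  # CI as wide as the RI fails
  est$ci_upper_limit <- est$lower_limit + c(0, est$ri_width)
  expect_equal(unname(ci_ri_ratio(est)["upper"]), 1)
  # skewed data: wider CI at the long (right) tail
  x <- rgamma(150, shape = 4, scale = 25)
  sk <- nonparametric_limits(x)
  rr <- ci_ri_ratio(sk)
  expect_gt(rr["upper"], rr["lower"])
})
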