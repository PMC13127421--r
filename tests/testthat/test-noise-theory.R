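test_that("large-regime SNR is sqrt(np) and matches the Binomial law", {
  expect_equal(snr_large(risk_params(30000, 1 / 30000)), 1)
  expect_equal(snr_large(risk_params(120000, 1 / 30000)), 2)
  # Monte-Carlo: mean/sd of Binomial draws at np = 1/3
  draws <- simulate_counts(risk_params(10000, 1 / 30000), "binomial",
                           n_draws = 2e5, seed = 11)
  expect_equal(mean(draws) / sd(draws),
               snr_large(risk_params(10000, 1 / 30000)),
               tolerance = 0.02)
})

test_that("expected absolute deviation matches the folded-normal form", {
  # np = pi/2 collapses to 1
  expect_equal(expected_abs_deviation(risk_params(10000, pi / 2 / 10000)), 1)
  # frozen Monte-Carlo value for Normal(2, 2): 1.1284 (= sqrt(4/pi))
  expect_equal(expected_abs_deviation(risk_params(20000, 1e-4)), 1.1284,
               tolerance = 1e-4)
  mc <- mean(abs(rnorm(4e5, 2, sqrt(2)) - 2))
  expect_equal(expected_abs_deviation(risk_params(20000, 1e-4)), mc,
               tolerance = 0.01)
})

test_that("large-regime expected SMAPE follows sqrt(2/(pi np))", {
  # np = 2/pi collapses to 1
  expect_equal(expected_smape_large(risk_params(10000, 2 / pi / 10000)), 1)
  expect_equal(expected_smape_large(risk_params(10000, 1e-4)),
               sqrt(2 / pi), tolerance = 1e-12)
  expect_lt(expected_smape_large(risk_params(10000000, 0.1)), 0.002)
  # monotone decreasing in np
  vals <- sapply(c(1, 2, 5, 20, 100), function(np)
    expected_smape_large(risk_params(100000, np / 100000)))
  expect_true(all(diff(vals) < 0))
})

test_that("Monte-Carlo SMAPE of calibrated Binomial counts approaches the closed form", {
  # module-level oracle at np = 25: agreement within 3% relative
  pr <- risk_params(1000000, 25 / 1000000)
  y <- simulate_counts(pr, "binomial", n_draws = 1e5, seed = 7)
  emp <- mean(smape_point(y, rep(25, length(y))))
  expect_equal(emp, expected_smape_large(pr), tolerance = 0.03)
})

test_that("small-regime SNR uses the Bernoulli variance approximation", {
  expect_equal(snr_small(risk_params(5000, 1e-4)), 0.5 / sqrt(0.25))
  expect_equal(snr_small(risk_params(100, 1e-4)),
               0.01 / sqrt(0.01 * 0.99))
  expect_lt(snr_small(risk_params(1, 1e-8)), 1e-3)
  expect_error(snr_small(risk_params(100000, 1e-4)),
               class = "odcast_domain_error")
})

test_that("small-regime expected SMAPE equals the two-outcome Bernoulli enumeration", {
  # independent oracle: enumerate y in {0, 1} with calibrated y_hat = np
  enumerate <- function(np) {
    np * (2 * abs(1 - np) / (1 + np)) + (1 - np) * (2 * np / np)
  }
  for (np in c(0.01, 0.1, 0.5)) {
    pr <- risk_params(10000, np / 10000)
    expect_equal(expected_smape_small(pr), enumerate(np),
                 tolerance = 1e-14)
  }
  expect_equal(expected_smape_small(risk_params(10000, 0.5 / 10000)),
               4 / 3)
  expect_equal(expected_smape_small(risk_params(10000, 0.1 / 10000)),
               1.963636, tolerance = 1e-6)
  # np -> 0 limit is the maximal SMAPE of 2
  expect_equal(expected_smape_small(risk_params(1, 1e-9)), 2,
               tolerance = 1e-6)
})

test_that("pointwise SMAPE is symmetric, bounded, and handles the 0/0 case", {
  expect_equal(smape_point(4, 4), 0)
  expect_equal(smape_point(1, 0), 2)
  expect_equal(smape_point(3, 1), 1)
  expect_equal(smape_point(0, 0), 0)
  expect_error(smape_point(-1, 2), class = "odcast_domain_error")
  set.seed(42)
  y <- rpois(200, 3)
  yh <- runif(200, 0, 10)
  s <- smape_point(y, yh)
  expect_true(all(s >= 0 & s <= 2))
  expect_equal(s, smape_point(yh, y))
})

test_that("relative deviation reproduces the worked small-community examples", {
  expect_equal(relative_deviation(1, 4), 0.25)
  expect_equal(relative_deviation(1, 10000), 1e-4)
  expect_equal(relative_deviation(0, 4), 0)
  expect_error(relative_deviation(1, 0), class = "odcast_domain_error")
})

test_that("minimal population solves ceil(snr^2 / p) with tight boundaries", {
  expect_identical(minimal_population((4 / 10000) / 12), 30000L)
  expect_identical(minimal_population(0.5), 2L)
  expect_identical(minimal_population((4 / 10000) / 12, snr_target = 2),
                   120000L)
  # boundary property: threshold is the smallest integer meeting the target
  set.seed(9)
  for (p in runif(20, 1e-6, 0.5)) {
    m <- minimal_population(p)
    expect_gte(m * p, 1)
    if (m > 1) expect_lt((m - 1) * p, 1)
  }
})

test_that("count simulation is reproducible and respects each law", {
  pr <- risk_params(1000000, 1e-6)
  a <- simulate_counts(pr, "binomial", 1000, seed = 5)
  b <- simulate_counts(pr, "binomial", 1000, seed = 5)
  expect_identical(a, b)
  y <- simulate_counts(pr, "binomial", 1e5, seed = 6)
  se <- sqrt(1 / 1e5)   # Poisson-scale standard error of the mean at np=1
  expect_lt(abs(mean(y) - 1), 3 * se)
  bern <- simulate_counts(risk_params(100, 1e-3), "bernoulli_approx",
                          5000, seed = 2)
  expect_true(all(bern %in% c(0, 1)))
  norm <- simulate_counts(pr, "normal_approx", 5000, seed = 3)
  expect_true(all(norm >= 0))
  expect_error(simulate_counts(pr, "weibull", 10),
               class = "odcast_usage_error")
})

test_that("the theory report tabulates monotone SNR with reciprocal NSR", {
  grid <- c(12, 3899, 9802, 30000, 71189)
  tab <- theory_report(1 / 30000, grid)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$snr) > 0))
  expect_equal(tab$snr[tab$n == 30000], 1)
  expect_equal(tab$nsr, 1 / tab$snr)
  expect_equal(tab$regime,
               c(rep("small_bernoulli", 3), rep("large_normal", 2)))
  expect_error(theory_report(1 / 30000, numeric(0)),
               class = "odcast_domain_error")
})

test_that("invalid risk parameters fail with named bounds", {
  expect_error(risk_params(0, 0.1), class = "odcast_domain_error")
  expect_error(risk_params(100, 0), class = "odcast_domain_error")
  expect_error(risk_params(100, 1), class = "odcast_domain_error")
  expect_error(snr_large(list(n = 10, p = 0.1)),
               class = "odcast_domain_error")
})
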