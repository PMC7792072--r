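test_that("required events reproduce the classical design values", {
  # 379.3 unrounded under Schoenfeld at hr 0.75, alpha 0.05, power 0.80
  expect_equal(required_events(0.75, 0.05, 0.80, ceiling = FALSE),
               379.35, tolerance = 1e-4)
  expect_equal(required_events(0.75, 0.05, 0.80), 380L)
  # the exact median ratio 4.5/6.5 reproduces the stage-2 target of 232
  expect_equal(required_events(4.5 / 6.5, 0.05, 0.80, ceiling = FALSE),
               232.18, tolerance = 1e-4)
  # at the rounded 0.69 both documented variants stay within 2% of 232
  expect_lt(abs(required_events(0.69, 0.05, 0.80) - 232) / 232, 0.02)
  expect_lt(abs(required_events(0.69, 0.05, 0.80, method = "freedman") - 232) / 232,
            0.02)
})

test_that("required events error on null or invalid effects and accept inflation", {
  expect_error(required_events(1), "superiority")
  expect_error(required_events(1.2), "superiority")
  expect_error(required_events(-0.5), "positive")
  expect_error(required_events(1 - 1e-9), "cap")
  infl <- attr(obf_boundaries(c(0.5, 1)), "inflation_factor")
  expect_equal(required_events(0.75, gsd_inflation = infl),
               ceiling(379.3517 * infl))
})

test_that("freedman needs at least as many events as schoenfeld for hr < 1", {
  for (hr in seq(0.5, 0.9, by = 0.05)) {
    expect_gte(required_events(hr, method = "freedman", ceiling = FALSE),
               required_events(hr, method = "schoenfeld", ceiling = FALSE))
  }
})

test_that("event probability matches closed form, limits and Monte Carlo", {
  expect_equal(event_probability(4.5, 4, 4), 0.5968, tolerance = 1e-3)
  # long-median limit: almost no events
  expect_lt(event_probability(1e6, 4, 4), 1e-5)
  # instant-accrual limit: everyone followed exactly F years
  expect_equal(event_probability(3, 1e-9, 4), 1 - 2^(-4 / 3), tolerance = 1e-6)
  # Monte-Carlo oracle: exponential event times, uniform entry over accrual
  set.seed(2718)
  m <- 2e5
  entry <- runif(m, 0, 4)
  evt <- rexp(m, rate = log(2) / 4.5)
  p_mc <- mean(entry + evt <= 8)
  se <- sqrt(p_mc * (1 - p_mc) / m)
  expect_lt(abs(event_probability(4.5, 4, 4) - p_mc), 3 * se)
})

test_that("participants required reproduce the staged-design totals within 5%", {
  # original two-arm design: 379 events, medians 4.5 vs 6, 4y + 4y, 5% dropout
  r1 <- required_n(379, event_probability(4.5, 4, 4), event_probability(6, 4, 4),
                   dropout_prob = 0.05)
  expect_equal(r1$required_n_total, 732L)
  expect_lt(abs(r1$required_n_total - 754) / 754, 0.05)
  expect_equal(r1$dropout_inflation, 1 / 0.95)
  # amended comparison: 232 events, medians 4.5 vs 6.5, 2.5y + 3.5y
  r2 <- required_n(232, event_probability(4.5, 2.5, 3.5),
                   event_probability(6.5, 2.5, 3.5), dropout_prob = 0.05)
  expect_lt(abs(r2$required_n_per_arm - 274) / 274, 0.05)
  # degenerate: no dropout, certain events -> n equals the event target
  r3 <- required_n(100, 1, 1, dropout_prob = 0)
  expect_equal(r3$required_n_total, 100L)
  expect_error(required_n(100, 0, 0.5), "positive")
})

test_that("binary power reproduces the 90% design statements", {
  p1 <- binary_power(260, 0.10, 0.20)
  p2 <- binary_power(260, 0.20, 0.325)
  expect_gt(p1$power, 0.885); expect_lt(p1$power, 0.905)
  expect_gt(p2$power, 0.885); expect_lt(p2$power, 0.905)
})

test_that("binary power: null case sits at the significance level and is flagged", {
  pn <- binary_power(200, 0.3, 0.3)
  expect_true(pn$null_case)
  expect_equal(pn$power, 0.05, tolerance = 0.005)
  ps <- binary_power(200, 0.3, 0.3, test = "exact_sim", reps = 2e4, seed = 9)
  expect_lt(abs(ps$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2e4) + 0.005)
})

test_that("analytic binary power agrees with binomial simulation", {
  for (case in list(c(260, 0.10, 0.20), c(120, 0.25, 0.45), c(80, 0.5, 0.7))) {
    pa <- binary_power(case[1], case[2], case[3])
    ps <- binary_power(case[1], case[2], case[3], test = "exact_sim",
                       reps = 2e4, seed = 101)
    expect_lt(abs(pa$power - ps$power), 3 * ps$mc_se + 0.01)
  }
})

test_that("power is monotone in sample size and effect size", {
  ns <- c(50, 100, 200, 400)
  pw <- vapply(ns, function(n) binary_power(n, 0.1, 0.2)$power, numeric(1))
  expect_true(all(diff(pw) > 0))
  p1s <- c(0.15, 0.2, 0.25, 0.3)
  pw2 <- vapply(p1s, function(p) binary_power(200, 0.1, p)$power, numeric(1))
  expect_true(all(diff(pw2) > 0))
})
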