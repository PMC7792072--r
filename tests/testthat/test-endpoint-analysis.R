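make_surv <- function(n, hr = 1, censor = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- rexp(n, rate = log(2) / 4.5)
  t1 <- rexp(n, rate = log(2) / 4.5 * hr)
  tibble::tibble(
    treat = rep(c(0L, 1L), each = n),
    time = pmin(c(t0, t1), censor),
    event = c(t0, t1) <= censor)
}

test_that("log-rank on a hand-worked six-patient dataset", {
  # group A: events at 1, 3, censored 5; group B: events at 2, 4, 6.
  # O-E for A = 2 - (1/2 + 2/5 + 1/2 + 1/3 + 0) = 4/15,
  # V = 1/4 + 6/25 + 1/4 + 2/9, chi-square = (4/15)^2 / V = 0.0739.
  ds <- tibble::tibble(time = 1:6,
                       event = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                       treat = c(0, 1, 0, 1, 0, 1))
  lr <- logrank(ds)
  expect_equal(lr$chi_square, (4/15)^2 / (1/4 + 6/25 + 1/4 + 2/9),
               tolerance = 1e-12)
  expect_equal(lr$chi_square, 0.0739, tolerance = 1e-3)
})

test_that("log-rank is zero for arm-symmetric data and matches survdiff generally", {
  sym <- tibble::tibble(time = rep(c(1, 2, 3, 4), 2),
                        event = TRUE, treat = rep(0:1, each = 4))
  expect_equal(logrank(sym)$chi_square, 0, tolerance = 1e-12)
  for (s in 1:10) {
    ds <- make_surv(60, hr = 0.7, censor = 6, seed = 200 + s)
    ds$time <- round(ds$time, 1)  # induce ties
    lr <- logrank(ds)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ treat, data = ds)
    expect_equal(lr$chi_square, sd_$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank null calibration holds at the nominal level", {
  set.seed(303)
  rej <- replicate(3000, {
    ds <- make_surv(40, hr = 1, censor = 6)
    logrank(ds)$p_two_sided < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 3000) + 0.005)
})

test_that("log-rank input contracts", {
  ds <- make_surv(10, seed = 1)
  expect_error(logrank(ds[ds$treat == 1, ]), "2 groups")
  ds$event <- FALSE
  expect_error(logrank(ds), "at least one event")
})

test_that("the PH score test equals the log-rank chi-square", {
  ds <- make_surv(80, hr = 0.6, censor = 8, seed = 42)
  expect_equal(fit_ph(ds)$score_statistic, logrank(ds)$chi_square,
               tolerance = 1e-8)
})

test_that("the bespoke PH fitter matches coxph on random fixtures", {
  set.seed(909)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    ds <- make_surv(n, hr = runif(1, 0.4, 1.2), censor = runif(1, 3, 8))
    ds$age <- sample(c("young", "old"), 2 * n, replace = TRUE)
    ds$stage <- sample(1:2, 2 * n, replace = TRUE)
    if (i %% 2 == 0) ds$time <- round(ds$time, 1)  # exercise Breslow ties
    fit <- fit_ph(ds, covariates = c("age", "stage"))
    cf <- survival::coxph(
      survival::Surv(time, event) ~ treat + age + factor(stage),
      data = ds, ties = "breslow")
    expect_lt(max(abs(sort(fit$coefficients) - sort(coef(cf)))), 1e-4)
    expect_lt(max(abs(sort(fit$std_errors) - sort(sqrt(diag(vcov(cf)))))), 1e-4)
  }
})

test_that("PH fit recovers the generating log hazard ratio at large n", {
  ds <- make_surv(5000, hr = 0.75, censor = 10, seed = 77)
  fit <- fit_ph(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[1] - log(0.75)), 3 * fit$std_errors[1])
})

test_that("PH fit is invariant to affine rescaling of other covariates", {
  ds <- make_surv(150, hr = 0.7, censor = 6, seed = 11)
  ds$biomarker <- rnorm(300, 50, 10)
  f1 <- fit_ph(ds, covariates = "biomarker")
  ds$biomarker <- (ds$biomarker - 50) / 10
  f2 <- fit_ph(ds, covariates = "biomarker")
  expect_equal(unname(f1$coefficients["treat"]),
               unname(f2$coefficients["treat"]), tolerance = 1e-8)
})

test_that("PH fit flags degenerate inputs instead of returning silently", {
  ds <- make_surv(30, seed = 2)
  ds$event <- FALSE
  expect_error(fit_ph(ds), "at least one event")
  # monotone likelihood: all events on the control arm, none on treated
  sep <- tibble::tibble(treat = rep(0:1, each = 15),
                        time = c(rexp(15, 1), rep(10, 15)),
                        event = rep(c(TRUE, FALSE), each = 15))
  fit <- fit_ph(sep)
  expect_true(fit$diverged)
  expect_false(fit$converged)
})

test_that("logistic regression matches glm and the intercept+arm model matches the z-test", {
  set.seed(55)
  n <- 260
  ds <- tibble::tibble(treat = rep(0:1, each = n),
                       mrd_negative = c(rbinom(n, 1, 0.10), rbinom(n, 1, 0.20)) == 1,
                       sex = sample(c("f", "m"), 2 * n, replace = TRUE))
  lf <- fit_logistic(ds, covariates = "sex")
  gl <- glm(mrd_negative ~ treat + sex, family = binomial, data = ds)
  expect_lt(max(abs(lf$coefficients - coef(gl))), 1e-8)
  expect_lt(max(abs(lf$std_errors - sqrt(diag(vcov(gl))))), 1e-6)
  # intercept + arm only: the logistic score test IS the pooled-variance
  # two-proportion chi-square, and the Wald z tracks the unpooled z
  lf0 <- fit_logistic(ds)
  x0 <- sum(ds$mrd_negative[ds$treat == 0]); x1 <- sum(ds$mrd_negative[ds$treat == 1])
  tp_pooled <- two_prop_test(x0, n, x1, n, pooled = TRUE)
  expect_equal(lf0$score_statistic, tp_pooled$z^2, tolerance = 1e-6)
  tp <- two_prop_test(x0, n, x1, n, pooled = FALSE)
  z_wald <- unname(lf0$coefficients["treat"] / lf0$std_errors["treat"])
  expect_equal(z_wald, tp$z, tolerance = 0.05)
})

test_that("logistic separation is detected and flagged", {
  ds <- tibble::tibble(treat = rep(0:1, each = 20),
                       mrd_negative = rep(c(FALSE, TRUE), each = 20))
  lf <- fit_logistic(ds)
  expect_true(lf$separated)
  expect_false(lf$converged)
})

test_that("the two-proportion test behaves at its design points", {
  # 10% vs 20% with 260 per arm is significant at the 5% level
  tp <- two_prop_test(26, 260, 52, 260)
  expect_lt(tp$p_two_sided, 0.05)
  expect_gt(tp$z, 0)
  # equal counts give z = 0
  expect_equal(two_prop_test(30, 100, 30, 100)$z, 0)
  expect_error(two_prop_test(-1, 10, 0, 10))
})
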