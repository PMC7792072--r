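# Small designs built in code for the test suite.

# Minimal single-stage two-arm design: control median 4.5y, experimental 6y
# (hazard ratio 0.75), ~200 patients, interim at half the 80 planned events.
mini_design <- function(accrual_rate = 200, stop_n = 100, target_events = 80,
                        dropout = 0) {
  design_spec(
    arms = tibble::tibble(name = c("CTL", "EXP"),
                          role = c("control", "experimental"),
                          median_pfs = c(4.5, 6),
                          mrd_neg_prob = c(0.10, 0.20)),
    stages = tibble::tibble(index = 1L,
                            active_arms = list(c("CTL", "EXP")),
                            allocation = list(c(1L, 1L)),
                            entry_trigger = list(trigger("none"))),
    hypotheses = tibble::tibble(
      label = "EXP_vs_CTL", experimental_arm = "EXP", control_arm = "CTL",
      endpoint = "time_to_event", alpha_two_sided = 0.05, power = 0.8,
      target_hr = 0.75, control_median = 4.5, experimental_median = 6,
      p_control = NA_real_, p_experimental = NA_real_,
      accrual_years = 1, min_followup_years = 3, dropout_prob = dropout,
      interim_fractions = list(c(0.5, 1)),
      target_events = as.integer(target_events)),
    stratification = list(sex = c("f", "m"), site = c("s1", "s2", "s3")),
    accrual_rate = accrual_rate,
    minimisation_p = 0.8,
    stop_rule = trigger("arm_recruitment", arm = "CTL", n = stop_n)
  )
}

# Random valid spec for round-trip property tests.
random_design <- function() {
  n_arms <- sample(2:4, 1)
  arm_names <- paste0("A", seq_len(n_arms))
  roles <- c("control", sample(c("control", "experimental"), n_arms - 1,
                               replace = TRUE))
  arms <- tibble::tibble(
    name = arm_names, role = roles,
    median_pfs = round(runif(n_arms, 2, 8), 3),
    mrd_neg_prob = ifelse(runif(n_arms) < 0.5, NA_real_,
                          round(runif(n_arms, 0.05, 0.6), 3)))
  stages <- tibble::tibble(
    index = 1L, active_arms = list(arm_names),
    allocation = list(rep(1L, n_arms)),
    entry_trigger = list(trigger("none")))
  cm <- arms$median_pfs[1]
  em <- arms$median_pfs[2]
  if (em <= cm) { em <- cm * 1.5; arms$median_pfs[2] <- em }
  hyp <- tibble::tibble(
    label = "h1", experimental_arm = arm_names[2], control_arm = arm_names[1],
    endpoint = "time_to_event", alpha_two_sided = 0.05,
    power = sample(c(0.8, 0.9), 1), target_hr = cm / em,
    control_median = cm, experimental_median = em,
    p_control = NA_real_, p_experimental = NA_real_,
    accrual_years = round(runif(1, 1, 4), 2),
    min_followup_years = round(runif(1, 1, 4), 2),
    dropout_prob = round(runif(1, 0, 0.1), 3),
    interim_fractions = list(sort(c(runif(sample(0:2, 1), 0.2, 0.9), 1))),
    target_events = sample(c(NA_integer_, 100L), 1))
  design_spec(
    arms = arms, stages = stages, hypotheses = hyp,
    stratification = list(sex = c("f", "m"),
                          grp = paste0("g", seq_len(sample(2:5, 1)))),
    accrual_rate = sample(50:400, 1),
    minimisation_p = round(runif(1, 0.6, 1), 2),
    stop_rule = trigger("arm_recruitment", arm = arm_names[1],
                        n = sample(30:80, 1)))
}

expect_spec_equal <- function(a, b) {
  expect_equal(a$arms, b$arms)
  expect_equal(a$hypotheses, b$hypotheses)
  expect_equal(a$stratification, b$stratification)
  expect_equal(a$accrual_rate, b$accrual_rate)
  expect_equal(a$minimisation_p, b$minimisation_p)
  expect_equal(unclass(a$stop_rule), unclass(b$stop_rule))
  expect_equal(nrow(a$stages), nrow(b$stages))
  for (i in seq_len(nrow(a$stages))) {
    expect_equal(a$stages$active_arms[[i]], b$stages$active_arms[[i]])
    expect_equal(a$stages$allocation[[i]], b$stages$allocation[[i]])
    expect_equal(unclass(a$stages$entry_trigger[[i]]),
                 unclass(b$stages$entry_trigger[[i]]))
  }
}
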