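# Sample-size machinery for time-to-event and binary endpoints: required
# events under proportional hazards (Schoenfeld / Freedman), conversion of
# events to participants via the exponential-accrual event probability, and
# normal-approximation power for two-sample proportions.

#' Required number of events for a log-rank / proportional-hazards test
#'
#' Number of events needed to detect a superiority hazard ratio `hr` at a
#' two-sided level `alpha_two_sided` with the given power, under 1:1
#' allocation.  Two classical formulas are available: Schoenfeld,
#' \eqn{d = 4 (z_{1-\alpha/2} + z_{pow})^2 / (\log hr)^2}, and Freedman,
#' \eqn{d = ((1+hr)/(1-hr))^2 (z_{1-\alpha/2} + z_{pow})^2}.  The result is
#' multiplied by `gsd_inflation` (the information inflation of a
#' group-sequential plan, see [obf_boundaries()]) and rounded up.
#'
#' @param hr Hazard ratio under the alternative, in (0, 1).
#' @param alpha_two_sided Two-sided significance level.
#' @param power Target power.
#' @param method `"schoenfeld"` (default) or `"freedman"`.
#' @param gsd_inflation Multiplicative inflation factor (\eqn{\ge 1}) for a
#'   planned group-sequential analysis; 1 means a fixed design.
#' @param ceiling Round the (inflated) event count up to an integer; set to
#'   `FALSE` to obtain the unrounded value.
#' @return Required events (integer unless `ceiling = FALSE`).
#' @examples
#' required_events(0.75, 0.05, 0.80)                       # 380 (379.3 unrounded)
#' required_events(4.5 / 6.5, 0.05, 0.80)                  # 233
#' required_events(0.69, 0.05, 0.80, method = "freedman")  # 234
#' @export
required_events <- function(hr, alpha_two_sided = 0.05, power = 0.80,
                            method = c("schoenfeld", "freedman"),
                            gsd_inflation = 1, ceiling = TRUE) {
  method <- match.arg(method)
  if (!is.numeric(hr) || hr <= 0) abort("`hr` must be positive")
  if (hr >= 1) abort("no superiority effect: `hr` must be below 1")
  stopifnot(alpha_two_sided > 0, alpha_two_sided < 1, power > 0, power < 1,
            gsd_inflation >= 1)
  zz <- (qnorm(1 - alpha_two_sided / 2) + qnorm(power))^2
  d <- switch(method,
    schoenfeld = 4 * zz / log(hr)^2,
    freedman = ((1 + hr) / (1 - hr))^2 * zz
  )
  d <- d * gsd_inflation
  if (d > 1e7) abort("effect size too close to null: required events exceed cap")
  if (ceiling) as.integer(base::ceiling(d - 1e-9)) else d
}

#' Probability that an event is observed by the analysis time
#'
#' For exponential event times with the given median, uniform accrual over
#' `accrual_years` and analysis at `accrual_years + min_followup_years`, the
#' probability that a randomised patient's event occurs before the analysis:
#' \eqn{1 - \frac{1}{\lambda A}\left(e^{-\lambda F} - e^{-\lambda(F+A)}\right)}
#' with \eqn{\lambda = \log 2 / \mathrm{median}}, accrual \eqn{A} and minimum
#' follow-up \eqn{F}.
#'
#' @param median_years Median event time (years).
#' @param accrual_years Uniform accrual period (years).
#' @param min_followup_years Follow-up after accrual closes (years).
#' @return Event probability.
#' @examples
#' event_probability(4.5, 4, 4)  # 0.597
#' @export
event_probability <- function(median_years, accrual_years, min_followup_years) {
  stopifnot(median_years > 0, accrual_years > 0, min_followup_years > 0)
  lam <- log(2) / median_years
  a <- accrual_years
  f <- min_followup_years
  1 - (exp(-lam * f) - exp(-lam * (f + a))) / (lam * a)
}

#' Participants required to observe a target number of events
#'
#' Converts a required event count into a participant count: the total sample
#' size is the events divided by the allocation-weighted mean per-patient
#' event probability, inflated by \eqn{1/(1 - \mathrm{dropout})}, with
#' per-arm counts rounded up to whole patients in the allocation ratio.  All
#' inflation factors are itemised in the result.
#'
#' @param required_events Target number of events (see [required_events()]).
#' @param event_prob_control,event_prob_experimental Per-patient event
#'   probabilities by analysis time (see [event_probability()]).
#' @param dropout_prob Probability a patient drops out before contributing an
#'   event (in \eqn{[0, 1)}).
#' @param allocation Two positive integers, control:experimental.
#' @param gsd_inflation Group-sequential inflation already applied to
#'   `required_events`; recorded in the result.
#' @param method Label of the event formula used; recorded in the result.
#' @return An `event_size_result`: a one-row tibble with
#'   `required_events`, `required_n_per_arm`, `required_n_total`,
#'   `event_prob_control`, `event_prob_experimental`, `dropout_inflation`,
#'   `gsd_inflation` and `method`.
#' @examples
#' required_n(379, event_probability(4.5, 4, 4), event_probability(6, 4, 4),
#'            dropout_prob = 0.05)
#' @export
required_n <- function(required_events, event_prob_control,
                       event_prob_experimental, dropout_prob = 0,
                       allocation = c(1, 1), gsd_inflation = 1,
                       method = "schoenfeld") {
  stopifnot(required_events > 0, dropout_prob >= 0, dropout_prob < 1,
            length(allocation) == 2, all(allocation > 0))
  if (event_prob_control <= 0 || event_prob_experimental <= 0)
    abort("event probabilities must be positive")
  w <- allocation / sum(allocation)
  pbar <- w[1] * event_prob_control + w[2] * event_prob_experimental
  n_raw <- required_events / pbar / (1 - dropout_prob)
  # round up to a whole multiple of the allocation block
  block <- sum(allocation)
  n_total <- as.integer(base::ceiling(n_raw / block - 1e-9) * block)
  n_arm <- as.integer(n_total * w)
  out <- tibble(
    required_events = as.integer(base::ceiling(required_events - 1e-9)),
    required_n_per_arm = n_arm[2],
    required_n_total = n_total,
    event_prob_control = event_prob_control,
    event_prob_experimental = event_prob_experimental,
    dropout_inflation = 1 / (1 - dropout_prob),
    gsd_inflation = gsd_inflation,
    method = method
  )
  class(out) <- c("event_size_result", class(out))
  out
}

#' Power of a two-sample proportion test
#'
#' Normal-approximation power of the two-sided two-sample z-test for
#' proportions with `n_per_arm` patients per arm, control rate `p0` and
#' experimental rate `p1`.  The `pooled_z` variant uses the pooled variance
#' under the null in the rejection rule (the usual test statistic);
#' `unpooled_z` uses the unpooled null variance; `exact_sim` estimates power
#' by Monte Carlo of binomial draws analysed with the pooled z-test.
#'
#' @param n_per_arm Evaluable patients per arm (\eqn{\ge 2}).
#' @param p0,p1 Control and experimental response probabilities, in (0, 1).
#' @param alpha_two_sided Two-sided significance level.
#' @param test `"pooled_z"` (default), `"unpooled_z"` or `"exact_sim"`.
#' @param reps Monte-Carlo replicates for `exact_sim`.
#' @param seed Optional seed for `exact_sim`.
#' @return A `binary_power_result`: one-row tibble with `power`, `n_per_arm`,
#'   `p0`, `p1`, `alpha_two_sided`, `test` and (for `exact_sim`) `mc_se`.
#' @examples
#' binary_power(260, 0.10, 0.20)   # ~0.89
#' binary_power(260, 0.20, 0.325)  # ~0.90
#' @export
binary_power <- function(n_per_arm, p0, p1, alpha_two_sided = 0.05,
                         test = c("pooled_z", "unpooled_z", "exact_sim"),
                         reps = 1e5, seed = NULL) {
  test <- match.arg(test)
  stopifnot(n_per_arm >= 2, p0 > 0, p0 < 1, p1 > 0, p1 < 1,
            alpha_two_sided > 0, alpha_two_sided < 1)
  z_a <- qnorm(1 - alpha_two_sided / 2)
  null_case <- isTRUE(all.equal(p0, p1))
  mc_se <- NA_real_
  if (test == "exact_sim") {
    pw <- with_seed(seed, {
      x0 <- rbinom(reps, n_per_arm, p0)
      x1 <- rbinom(reps, n_per_arm, p1)
      pb <- (x0 + x1) / (2 * n_per_arm)
      se0 <- sqrt(pmax(pb * (1 - pb), 1e-12) * 2 / n_per_arm)
      z <- (x1 - x0) / n_per_arm / se0
      mean(abs(z) > z_a)
    })
    mc_se <- sqrt(pw * (1 - pw) / reps)
  } else {
    pbar <- (p0 + p1) / 2
    se_null <- switch(test,
      pooled_z = sqrt(2 * pbar * (1 - pbar) / n_per_arm),
      unpooled_z = sqrt((p0 * (1 - p0) + p1 * (1 - p1)) / n_per_arm)
    )
    se_alt <- sqrt((p0 * (1 - p0) + p1 * (1 - p1)) / n_per_arm)
    delta <- p1 - p0
    # both rejection tails under the alternative
    pw <- pnorm((delta - z_a * se_null) / se_alt) +
      pnorm((-delta - z_a * se_null) / se_alt)
  }
  out <- tibble(power = pw, n_per_arm = as.integer(n_per_arm), p0 = p0,
                p1 = p1, alpha_two_sided = alpha_two_sided, test = test,
                mc_se = mc_se, null_case = null_case)
  class(out) <- c("binary_power_result", class(out))
  out
}
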