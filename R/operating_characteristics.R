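# Monte-Carlo operating characteristics of a staged platform design:
# per-hypothesis type-I error / power under a scenario of true per-arm
# parameters, family-wise error across hypotheses sharing control data,
# intersection-union success rates, and the correlation between test
# statistics induced by shared controls.

apply_scenario <- function(spec, scenario) {
  if (is.null(scenario)) return(spec)
  unknown <- setdiff(names(scenario), spec$arms$name)
  if (length(unknown))
    abort(sprintf("scenario references unknown arm(s): %s",
                  paste(unknown, collapse = ", ")))
  for (a in names(scenario)) {
    i <- match(a, spec$arms$name)
    for (fld in intersect(names(scenario[[a]]), c("median_pfs", "mrd_neg_prob")))
      spec$arms[[fld]][i] <- scenario[[a]][[fld]]
  }
  validate_design(spec)
  spec
}

test_hypothesis <- function(run, h, plan, look_events, analysis, covariates) {
  if (h$endpoint == "binary") {
    ds <- analysis_dataset(run, h$label, cutoff_years = run$horizon + 1)
    x1 <- sum(ds$mrd_negative[ds$treat == 1])
    n1 <- sum(ds$treat == 1)
    x0 <- sum(ds$mrd_negative[ds$treat == 0])
    n0 <- sum(ds$treat == 0)
    tp <- two_prop_test(x0, n0, x1, n1)
    return(list(reject = tp$p_two_sided <= h$alpha_two_sided, z = tp$z))
  }
  reject <- FALSE
  z_final <- NA_real_
  for (k in seq_along(look_events)) {
    ds <- analysis_dataset(run, h$label, cutoff_events = look_events[k])
    if (analysis == "score") {
      lr <- logrank(ds)
      p <- lr$p_two_sided
      z_final <- lr$z
    } else {
      fit <- fit_ph(ds, covariates = covariates)
      p <- fit$wald_p_two_sided
      z_final <- unname(fit$coefficients[1] / fit$std_errors[1])
    }
    if (p <= plan$nominal_p_two_sided[k]) { reject <- TRUE; break }
  }
  list(reject = reject, z = z_final)
}

#' Monte-Carlo operating characteristics of a platform design
#'
#' Simulates the full design `reps` times under a scenario of true per-arm
#' parameters, analyses every hypothesis on its concurrent-comparator set
#' with its group-sequential boundaries, and aggregates rejection rates with
#' Monte-Carlo standard errors.  Also reports the family-wise error rate
#' (any rejection among `family`), the intersection-union success rate (all
#' of `iu` rejected), the empirical correlation between the two family test
#' statistics, and — as the no-sharing reference — the family-wise rate
#' under an independence coupling of the same marginal rejections (pairing
#' each replicate's first-family rejection with the next replicate's
#' second-family rejection).
#'
#' @param spec A [design_spec()].
#' @param scenario Named list of per-arm true-parameter overrides, e.g.
#'   `list(IR = list(median_pfs = 4.5))`; `NULL` keeps the design values.
#' @param reps Number of simulated trials (>= 1).
#' @param seed RNG seed.
#' @param analysis `"score"` (log-rank at each look; default) or `"cox"`
#'   (Wald test from [fit_ph()] with stage + stratification covariates).
#' @param family Hypothesis labels over which the family-wise error is
#'   taken; defaults to the time-to-event hypotheses sharing the most common
#'   control arm.
#' @param iu Hypothesis labels that must all reject for intersection-union
#'   "success"; defaults to the hypotheses sharing an experimental arm, if
#'   any.
#' @param covariates Covariates for `analysis = "cox"`; defaults to trial
#'   stage plus every stratification factor with fewer than 10 levels
#'   (centre, with its many levels, stays out of the regression).
#' @param n_max Per-trial recruitment cap passed to [run_trial()].
#' @return An `oc_report`; `tidy()` gives the per-hypothesis table,
#'   `glance()` the family-level rates.
#' @export
evaluate_oc <- function(spec, scenario = NULL, reps = 1000, seed = NULL,
                        analysis = c("score", "cox"), family = NULL,
                        iu = NULL, covariates = NULL, n_max = 10000) {
  analysis <- match.arg(analysis)
  stopifnot(reps >= 1)
  spec <- apply_scenario(spec, scenario)
  hy <- spec$hypotheses
  labs <- hy$label

  if (is.null(family)) {
    tte <- hy[hy$endpoint == "time_to_event", ]
    if (nrow(tte) >= 2) {
      ctrl <- names(sort(table(tte$control_arm), decreasing = TRUE))[1]
      family <- tte$label[tte$control_arm == ctrl]
    } else family <- tte$label
  }
  if (is.null(iu)) {
    shared_exp <- names(which(table(hy$experimental_arm) >= 2))
    if (length(shared_exp))
      iu <- hy$label[hy$experimental_arm == shared_exp[1]]
  }
  if (is.null(covariates)) {
    small <- names(spec$stratification)[lengths(spec$stratification) < 10]
    covariates <- c("stage", small)
  }

  plans <- look_events <- vector("list", nrow(hy))
  for (i in seq_len(nrow(hy))) {
    if (hy$endpoint[i] != "time_to_event") next
    plans[[i]] <- obf_boundaries(hy$interim_fractions[[i]],
                                 hy$alpha_two_sided[i])
    d <- hy$target_events[i]
    if (is.na(d))
      d <- required_events(hy$target_hr[i], hy$alpha_two_sided[i], hy$power[i])
    look_events[[i]] <- interim_trigger(plans[[i]], d)$events
  }

  rej <- matrix(NA, reps, nrow(hy), dimnames = list(NULL, labs))
  zst <- matrix(NA_real_, reps, nrow(hy), dimnames = list(NULL, labs))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      run <- run_trial(spec, n_max = n_max)
      for (i in seq_len(nrow(hy))) {
        res <- test_hypothesis(run, hy[i, ], plans[[i]], look_events[[i]],
                               analysis, covariates)
        rej[r, i] <- res$reject
        zst[r, i] <- res$z
      }
    }
  })

  rate <- colMeans(rej)
  mc_se <- if (reps > 1) sqrt(rate * (1 - rate) / reps) else rep(NA_real_, ncol(rej))
  per_hyp <- tibble(hypothesis = labs, rejections = colSums(rej),
                    rate = rate, mc_se = mc_se)

  fam_rej <- rowSums(rej[, family, drop = FALSE]) > 0
  fwer <- mean(fam_rej)
  # independence coupling: shift the second family member by one replicate
  fwer_indep <- NA_real_
  cor_family <- NA_real_
  if (length(family) == 2 && reps > 1) {
    r1 <- rej[, family[1]]
    r2 <- rej[, family[2]]
    fwer_indep <- mean(r1 | r2[c(2:reps, 1)])
    cor_family <- suppressWarnings(cor(zst[, family[1]], zst[, family[2]]))
  }
  iu_rate <- if (length(iu)) mean(rowSums(rej[, iu, drop = FALSE]) == length(iu))
             else NA_real_

  structure(list(
    per_hypothesis = per_hyp,
    fwer = fwer,
    fwer_mc_se = if (reps > 1) sqrt(fwer * (1 - fwer) / reps) else NA_real_,
    fwer_independent = fwer_indep,
    iu_rate = iu_rate,
    iu_mc_se = if (reps > 1 && length(iu)) sqrt(iu_rate * (1 - iu_rate) / reps)
               else NA_real_,
    statistic_correlation = cor_family,
    family = family, iu = iu, reps = reps, seed = seed,
    analysis = analysis, scenario = scenario,
    degenerate = reps == 1,
    rejections = as_tibble(cbind(rep = seq_len(reps), rej * 1)),
    statistics = as_tibble(cbind(rep = seq_len(reps), zst))
  ), class = "oc_report")
}

#' @export
print.oc_report <- function(x, ...) {
  cat(sprintf("<oc_report> %d replicate(s)%s, analysis = %s\n", x$reps,
              if (x$degenerate) " [degenerate: MC SE undefined]" else "",
              x$analysis))
  print(x$per_hypothesis, ...)
  cat(sprintf("  FWER {%s}: %.4f (indep. coupling %.4f); IU success {%s}: %.4f\n",
              paste(x$family, collapse = ", "), x$fwer, x$fwer_independent,
              paste(x$iu, collapse = ", "), x$iu_rate))
  cat(sprintf("  family statistic correlation: %.3f\n", x$statistic_correlation))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.oc_report <- function(x, ...) x$per_hypothesis

#' @exportS3Method generics::glance
glance.oc_report <- function(x, ...) {
  tibble(reps = x$reps, fwer = x$fwer, fwer_mc_se = x$fwer_mc_se,
         fwer_independent = x$fwer_independent, iu_rate = x$iu_rate,
         statistic_correlation = x$statistic_correlation,
         degenerate = x$degenerate)
}

#' Empirical power across a grid of true effect sizes
#'
#' Re-evaluates one hypothesis's rejection rate while sliding its
#' experimental arm's true parameter along a grid: hazard ratios for a
#' time-to-event hypothesis (the experimental median is set to the control
#' arm's true median divided by the hazard ratio), response probabilities
#' for a binary one.
#'
#' @param spec A [design_spec()].
#' @param hypothesis Hypothesis label.
#' @param grid Numeric grid of hazard ratios or response probabilities.
#' @param reps Replicates per grid point.
#' @param seed RNG seed (each grid point gets an offset sub-seed).
#' @param ... Passed to [evaluate_oc()].
#' @return Tibble with `value`, `rate`, `mc_se`.
#' @export
power_curve <- function(spec, hypothesis, grid, reps = 500, seed = NULL, ...) {
  stopifnot(length(grid) >= 1)
  hy <- spec$hypotheses
  i <- match(hypothesis, hy$label)
  if (is.na(i)) abort(sprintf("unknown hypothesis '%s'", hypothesis))
  exp_arm <- hy$experimental_arm[i]
  ctrl_arm <- hy$control_arm[i]
  purrr::map_dfr(seq_along(grid), function(g) {
    ov <- if (hy$endpoint[i] == "time_to_event") {
      ctrl_med <- spec$arms$median_pfs[match(ctrl_arm, spec$arms$name)]
      list(median_pfs = ctrl_med / grid[g])
    } else {
      list(mrd_neg_prob = grid[g])
    }
    oc <- evaluate_oc(spec, scenario = setNames(list(ov), exp_arm),
                      reps = reps,
                      seed = if (is.null(seed)) NULL else seed + g, ...)
    row <- oc$per_hypothesis[oc$per_hypothesis$hypothesis == hypothesis, ]
    tibble(value = grid[g], rate = row$rate, mc_se = row$mc_se)
  })
}
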