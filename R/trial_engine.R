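# Staged trial execution: recruit patients at the accrual rate, randomise
# them by minimisation under the stage active at their entry, fire stage
# transitions when their entry triggers hold, stop when the stop rule fires,
# and book-keep the concurrent-comparator set of every hypothesis.

trigger_to_cpp <- function(tr, arm_names) {
  switch(tr$type,
    none = list(type = 0L),
    arm_recruitment = list(type = 1L,
                           arm = match(tr$arm, arm_names) - 1L,
                           n = as.integer(tr$n),
                           from_stage = tr$from_stage - 1L),
    calendar = list(type = 2L, time = tr$time)
  )
}

#' Simulate one staged platform trial
#'
#' Recruits patients as a Poisson stream at the design's accrual rate, draws
#' their stratification profiles, randomises each by minimisation (with the
#' state reset at every stage transition), fires stage transitions and the
#' recruitment stop rule from the design's triggers, draws latent outcomes
#' per the assigned arm, and computes the concurrent-comparator set of every
#' hypothesis: a patient belongs to a hypothesis's set precisely when both of
#' its arms were open to allocation at the patient's randomisation and the
#' patient was randomised to one of them.  Control patients appearing in
#' more than one concurrent set are the shared controls.
#'
#' Outcome draws use per-patient inverse-transform uniforms, so a patient's
#' latent outcomes depend only on their position in the entry stream and the
#' parameters of their assigned arm — adding arms to the design does not
#' perturb earlier patients' outcomes.
#'
#' @param spec A [design_spec()].
#' @param seed Optional RNG seed; identical seeds reproduce the identical
#'   trial.
#' @param n_max Recruitment cap; if the stop rule has not fired by then the
#'   run aborts naming the stage that was still open.
#' @param dropout_prob Probability of dropout within `dropout_horizon`;
#'   defaults to the largest hypothesis dropout probability.
#' @param dropout_horizon Calibration horizon in years; defaults to the
#'   longest hypothesis accrual + follow-up period (or 8).
#' @param factor_distribution Optional named list of level distributions
#'   (see [draw_profile()]); uniform over the declared levels by default.
#' @return A `trial_run`: list with `patients` (tibble: id, entry_time,
#'   stage, one column per stratification factor, arm, latent
#'   `pfs_time`/`dropout_time`, `mrd_negative`, and `observed_time`/
#'   `event_flag` administratively censored at the trial horizon),
#'   `stages` (tibble of stage start indices/times), `concurrent` (named
#'   list of patient-id vectors per hypothesis), `shared_control_ids`,
#'   `horizon`, and the `spec`.
#' @export
run_trial <- function(spec, seed = NULL, n_max = 10000,
                      dropout_prob = NULL, dropout_horizon = NULL,
                      factor_distribution = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  hy <- spec$hypotheses
  if (is.null(dropout_prob))
    dropout_prob <- if (nrow(hy)) max(hy$dropout_prob, na.rm = TRUE) else 0
  if (is.null(dropout_horizon)) {
    span <- hy$accrual_years + hy$min_followup_years
    dropout_horizon <- if (length(span) && any(!is.na(span)))
      max(span, na.rm = TRUE) else 8
  }
  if (is.null(factor_distribution)) factor_distribution <- spec$stratification

  layout <- strat_layout(spec$stratification)
  arm_names <- spec$arms$name
  stages_cpp <- purrr::pmap(spec$stages, function(index, active_arms,
                                                  allocation, entry_trigger) {
    list(active = match(active_arms, arm_names) - 1L,
         weights = as.numeric(allocation),
         trigger = trigger_to_cpp(entry_trigger, arm_names))
  })
  stop_cpp <- trigger_to_cpp(spec$stop_rule, arm_names)

  with_seed(seed, {
    entry <- cumsum(rexp(n_max, rate = spec$accrual_rate))
    # profile draws, vectorised: one uniform per patient and factor
    dist <- purrr::map(factor_distribution, function(d) {
      if (is.character(d)) setNames(rep(1 / length(d), length(d)), d) else d
    })
    fac <- names(spec$stratification)
    lvl_idx <- matrix(0L, n_max, length(fac))
    for (j in seq_along(fac)) {
      pr <- dist[[fac[j]]]
      # order probabilities by the declared level order
      pr <- pr[spec$stratification[[fac[j]]]]
      cp <- cumsum(pr)
      cp[length(cp)] <- Inf  # guard against cumulative rounding at 1
      lvl_idx[, j] <- findInterval(runif(n_max), cp) + 1L
    }
    rows0 <- sweep(lvl_idx - 1L, 2L,
                   as.integer(layout$offsets[fac]), "+")
    res <- cpp_run_recruitment(rows0, entry, stages_cpp, stop_cpp,
                               length(arm_names), layout$n_rows,
                               spec$minimisation_p)
    if (!res$stopped)
      abort(sprintf(
        "recruitment stop rule did not fire within %d patients (stage %d still open)",
        n_max, res$last_stage))
    n <- res$n
    idx <- seq_len(n)
    u <- matrix(runif(3 * n), ncol = 3)

    arm_i <- res$arm[idx]
    pat <- tibble(id = idx, entry_time = entry[idx],
                  stage = res$stage[idx])
    for (j in seq_along(fac))
      pat[[fac[j]]] <- spec$stratification[[fac[j]]][lvl_idx[idx, j]]
    pat$arm <- arm_names[arm_i]

    out <- vector("list", length(arm_names))
    pfs <- drop_t <- numeric(n)
    mrd <- logical(n)
    for (a in seq_along(arm_names)) {
      sel <- which(arm_i == a)
      if (!length(sel)) next
      oc <- draw_outcomes(spec$arms[a, ], length(sel), dropout_prob,
                          dropout_horizon, u = u[sel, , drop = FALSE])
      pfs[sel] <- oc$pfs_time
      drop_t[sel] <- oc$dropout_time
      mrd[sel] <- oc$mrd_negative
    }
    pat$pfs_time <- pfs
    pat$dropout_time <- drop_t
    pat$mrd_negative <- mrd

    # administrative horizon: end of recruitment plus the longest follow-up
    fu <- hy$min_followup_years
    horizon <- max(pat$entry_time) +
      (if (length(fu) && any(!is.na(fu))) max(fu, na.rm = TRUE) else 0)
    fol <- pmax(horizon - pat$entry_time, 0)
    pat$observed_time <- pmin(pat$pfs_time, pat$dropout_time, fol)
    pat$event_flag <- pat$pfs_time <= pmin(pat$dropout_time, fol)

    concurrent <- purrr::map(seq_len(nrow(hy)), function(i) {
      pair <- c(hy$experimental_arm[i], hy$control_arm[i])
      open <- which(vapply(spec$stages$active_arms,
                           function(a) all(pair %in% a), logical(1)))
      pat$id[pat$stage %in% spec$stages$index[open] & pat$arm %in% pair]
    })
    names(concurrent) <- hy$label
    all_ids <- unlist(concurrent)
    dup <- unique(all_ids[duplicated(all_ids)])
    ctrl_arms <- spec$arms$name[spec$arms$role == "control"]
    shared <- sort(intersect(dup, pat$id[pat$arm %in% ctrl_arms]))

    first <- res$stage_first
    stages_tbl <- tibble(
      index = spec$stages$index,
      first_id = as.integer(first),
      start_time = ifelse(is.na(first), NA_real_, entry[first]),
      n = as.integer(tabulate(pat$stage, nbins = nrow(spec$stages)))
    )

    structure(list(patients = pat, stages = stages_tbl,
                   concurrent = concurrent, shared_control_ids = shared,
                   horizon = horizon, dropout_prob = dropout_prob,
                   dropout_horizon = dropout_horizon, spec = spec),
              class = "trial_run")
  })
}

#' @export
print.trial_run <- function(x, ...) {
  cat(sprintf("<trial_run> %d patients over %.2f years, %d stage(s)\n",
              nrow(x$patients), max(x$patients$entry_time),
              sum(!is.na(x$stages$first_id))))
  print(dplyr::count(x$patients, .data$stage, .data$arm), n = Inf)
  cat(sprintf("  shared controls: %d\n", length(x$shared_control_ids)))
  invisible(x)
}

#' Analysis dataset for one hypothesis at a cutoff
#'
#' Restricts a simulated trial to the hypothesis's concurrent-comparator set
#' and administratively censors every patient at the analysis cutoff.  The
#' cutoff is either a calendar time (`cutoff_years` from trial start) or an
#' event count (`cutoff_events`): the calendar time at which that many
#' progression/death events have occurred among the concurrent patients —
#' the event-driven interim rule.  With neither given, the hypothesis's
#' planned `target_events` is used.
#'
#' @param run A [run_trial()] result.
#' @param hypothesis A hypothesis label from the design.
#' @param cutoff_events,cutoff_years The analysis cutoff (give at most one).
#' @return Tibble with one row per concurrent patient randomised before the
#'   cutoff: `id`, `arm`, `treat` (1 = experimental), `time`, `event`,
#'   `mrd_negative`, `stage` and the stratification-factor columns.
#' @export
analysis_dataset <- function(run, hypothesis, cutoff_events = NULL,
                             cutoff_years = NULL) {
  stopifnot(inherits(run, "trial_run"))
  hy <- run$spec$hypotheses
  i <- match(hypothesis, hy$label)
  if (is.na(i)) abort(sprintf("unknown hypothesis '%s'", hypothesis))
  if (!is.null(cutoff_events) && !is.null(cutoff_years))
    abort("give only one of `cutoff_events` and `cutoff_years`")

  ids <- run$concurrent[[hypothesis]]
  pat <- run$patients[run$patients$id %in% ids, , drop = FALSE]

  # calendar times at which concurrent events occur
  ev_cal <- pat$entry_time + pat$pfs_time
  ev_cal[pat$pfs_time > pat$dropout_time] <- Inf

  if (is.null(cutoff_events) && is.null(cutoff_years)) {
    cutoff_events <- hy$target_events[i]
    if (is.na(cutoff_events))
      abort("no cutoff given and the hypothesis has no target_events")
  }
  if (!is.null(cutoff_events)) {
    stopifnot(cutoff_events >= 0)
    if (cutoff_events == 0) {
      cutoff_time <- 0
    } else {
      sorted <- sort(ev_cal[is.finite(ev_cal)])
      if (length(sorted) < cutoff_events) {
        warn(sprintf(
          "only %d concurrent events ever occur (requested %d); using all",
          length(sorted), cutoff_events))
        cutoff_events <- length(sorted)
      }
      cutoff_time <- sorted[cutoff_events]
    }
  } else {
    cutoff_time <- cutoff_years
  }

  keep <- pat$entry_time < cutoff_time
  if (!any(keep))
    warn("analysis cutoff precedes the first concurrent randomisation; empty table")
  pat <- pat[keep, , drop = FALSE]
  fol <- cutoff_time - pat$entry_time
  time <- pmin(pat$pfs_time, pat$dropout_time, fol)
  # the tolerance keeps the event whose calendar time defines the cutoff in
  # the event count despite floating-point round-trip through entry + time
  event <- pat$pfs_time <= pmin(pat$dropout_time, fol + 1e-9)

  fac <- names(run$spec$stratification)
  out <- tibble(id = pat$id, arm = pat$arm,
                treat = as.integer(pat$arm == hy$experimental_arm[i]),
                time = time, event = event,
                mrd_negative = pat$mrd_negative,
                stage = pat$stage)
  for (f in fac) out[[f]] <- pat[[f]]
  attr(out, "cutoff_time") <- cutoff_time
  attr(out, "hypothesis") <- hypothesis
  out
}
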