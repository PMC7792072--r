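# Domain model for a staged multi-arm platform design: arms, stages with
# entry triggers, hypotheses, stratification factors, and a recruitment stop
# rule.  A design_spec is a validated list of tibbles; load_design() /
# save_design() round-trip it through a YAML config.

#' Construct a platform-trial design specification
#'
#' A `design_spec` bundles everything needed to simulate and analyse a staged
#' platform trial: the treatment arms with their true (or design-alternative)
#' outcome parameters, the stages with their active arms, allocation ratios
#' and entry triggers, the comparative hypotheses, the stratification factors
#' used by the minimisation randomiser, the accrual rate, and the rule that
#' ends recruitment.
#'
#' @param arms Tibble/data frame with columns `name`, `role`
#'   (`"control"`/`"experimental"`), `median_pfs` (years, > 0) and optionally
#'   `mrd_neg_prob` (probability of minimal-residual-disease negativity at the
#'   binary-endpoint assessment).
#' @param stages Tibble with columns `index`, `active_arms` (list-column of
#'   arm-name vectors), `allocation` (list-column of positive integer
#'   weights), `entry_trigger` (list-column of triggers; see [trigger()]).
#' @param hypotheses Tibble with one row per comparative hypothesis; columns
#'   `label`, `experimental_arm`, `control_arm`, `endpoint`
#'   (`"time_to_event"`/`"binary"`), `alpha_two_sided`, `power`, and the
#'   endpoint parameters (`target_hr`, `control_median`,
#'   `experimental_median`, `p_control`, `p_experimental`, `accrual_years`,
#'   `min_followup_years`, `dropout_prob`, `interim_fractions` list-column,
#'   optional `target_events`).
#' @param stratification Named list mapping each stratification factor to its
#'   character vector of levels.
#' @param accrual_rate Patients recruited per year.
#' @param minimisation_p Probability that the minimisation randomiser follows
#'   the imbalance-minimising arm; must lie in (0.5, 1].
#' @param stop_rule Trigger ending recruitment (see [trigger()]).
#' @param description Optional free-text description.
#'
#' @return A validated object of class `design_spec`.
#' @seealso [load_design()], [save_design()], [flair_design()], [run_trial()]
#' @export
design_spec <- function(arms, stages, hypotheses, stratification,
                        accrual_rate, minimisation_p = 0.8,
                        stop_rule = trigger("none"), description = NULL) {
  spec <- structure(
    list(
      arms = as_tibble(arms),
      stages = as_tibble(stages),
      hypotheses = as_tibble(hypotheses),
      stratification = stratification,
      accrual_rate = as.numeric(accrual_rate),
      minimisation_p = as.numeric(minimisation_p),
      stop_rule = stop_rule,
      description = description
    ),
    class = "design_spec"
  )
  validate_design(spec)
  spec
}

#' Stage-transition or stop trigger
#'
#' Triggers come in three kinds: `"none"` (never fires; the first stage),
#' `"arm_recruitment"` (fires once the cumulative number of patients
#' randomised to `arm` in stages `from_stage` onwards reaches `n`) and
#' `"calendar"` (fires at `time` years after trial start).  Recruitment-count
#' triggers are the natural encoding when stage targets are stated as
#' participant numbers.
#'
#' @param type One of `"none"`, `"arm_recruitment"`, `"calendar"`.
#' @param arm,n,from_stage Arm name, count threshold and first counted stage
#'   (for `"arm_recruitment"`).
#' @param time Years from trial start (for `"calendar"`).
#' @return A trigger (named list) usable in `design_spec` stages/stop rule.
#' @export
trigger <- function(type = c("none", "arm_recruitment", "calendar"),
                    arm = NULL, n = NULL, from_stage = 1L, time = NULL) {
  type <- match.arg(type)
  if (type == "arm_recruitment" && (is.null(arm) || is.null(n)))
    abort("an arm_recruitment trigger needs `arm` and `n`")
  if (type == "calendar" && is.null(time))
    abort("a calendar trigger needs `time`")
  structure(list(type = type, arm = arm,
                 n = if (is.null(n)) NULL else as.integer(n),
                 from_stage = as.integer(from_stage), time = time),
            class = "pt_trigger")
}

fail <- function(msgs, ...) c(msgs, sprintf(...))

#' Validate a design specification
#'
#' Checks every structural invariant of a `design_spec` and aborts with a
#' bullet list naming each violated constraint.  Called by [design_spec()] and
#' [load_design()]; exported so edited specs can be re-checked.
#'
#' @param spec A `design_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_design <- function(spec) {
  m <- character()
  arms <- spec$arms
  if (nrow(arms) == 0) m <- fail(m, "arms: at least one arm is required")
  if (anyDuplicated(arms$name)) m <- fail(m, "arms: names must be unique")
  if (!all(arms$role %in% c("control", "experimental")))
    m <- fail(m, "arms: role must be 'control' or 'experimental'")
  if (!all(arms$median_pfs > 0, na.rm = TRUE) || anyNA(arms$median_pfs))
    m <- fail(m, "arms: median_pfs must be positive for every arm")
  if ("mrd_neg_prob" %in% names(arms)) {
    bad <- !is.na(arms$mrd_neg_prob) &
      (arms$mrd_neg_prob < 0 | arms$mrd_neg_prob > 1)
    if (any(bad)) m <- fail(m, "arms: mrd_neg_prob must lie in [0, 1]")
  }

  st <- spec$stages
  if (nrow(st) == 0) {
    m <- fail(m, "stages: at least one stage is required")
  } else {
    for (i in seq_len(nrow(st))) {
      act <- st$active_arms[[i]]
      alloc <- st$allocation[[i]]
      if (length(act) < 2)
        m <- fail(m, "stage %d: needs at least 2 active arms", i)
      if (length(alloc) != length(act))
        m <- fail(m, "stage %d: allocation length must match active arms", i)
      if (any(alloc <= 0) || any(alloc != round(alloc)))
        m <- fail(m, "stage %d: allocation weights must be positive integers", i)
      if (!all(act %in% arms$name))
        m <- fail(m, "stage %d: undeclared arm(s) %s", i,
                  paste(setdiff(act, arms$name), collapse = ", "))
      if (i > 1) {
        ctrl <- arms$name[arms$role == "control"]
        shared <- intersect(intersect(st$active_arms[[i - 1]], act), ctrl)
        if (length(shared) == 0)
          m <- fail(m, "stages %d-%d: consecutive stages must share a control arm",
                    i - 1, i)
        if (spec$stages$entry_trigger[[i]]$type == "none")
          m <- fail(m, "stage %d: entry trigger must not be 'none'", i)
      }
    }
  }

  hy <- spec$hypotheses
  for (i in seq_len(nrow(hy))) {
    h <- hy[i, ]
    for (a in c(h$experimental_arm, h$control_arm))
      if (!a %in% arms$name)
        m <- fail(m, "hypothesis '%s': undeclared arm '%s'", h$label, a)
    if (nrow(st) > 0 && all(c(h$experimental_arm, h$control_arm) %in% arms$name)) {
      together <- any(vapply(st$active_arms, function(a)
        all(c(h$experimental_arm, h$control_arm) %in% a), logical(1)))
      if (!together)
        m <- fail(m, "hypothesis '%s': its two arms are never simultaneously active",
                  h$label)
    }
    fr <- h$interim_fractions[[1]]
    if (length(fr) == 0 || any(diff(c(0, fr)) <= 0) || abs(fr[length(fr)] - 1) > 1e-12)
      m <- fail(m, "hypothesis '%s': interim_fractions must be strictly increasing and end at 1",
                h$label)
    if (h$endpoint == "time_to_event") {
      ok_med <- !is.na(h$control_median) && !is.na(h$experimental_median)
      if (ok_med && abs(h$target_hr - h$control_median / h$experimental_median) > 1e-9)
        m <- fail(m, "hypothesis '%s': target_hr must equal control_median/experimental_median under exponential survival",
                  h$label)
      if (!is.na(h$target_hr) && (h$target_hr <= 0 || h$target_hr >= 1))
        m <- fail(m, "hypothesis '%s': target_hr must lie in (0, 1)", h$label)
    }
    if (h$endpoint == "binary") {
      for (p in c("p_control", "p_experimental"))
        if (is.na(h[[p]]) || h[[p]] <= 0 || h[[p]] >= 1)
          m <- fail(m, "hypothesis '%s': %s must lie in (0, 1)", h$label, p)
    }
  }

  if (is.null(spec$stratification) || length(spec$stratification) == 0)
    m <- fail(m, "stratification: at least one factor is required")
  if (!is.numeric(spec$accrual_rate) || spec$accrual_rate <= 0)
    m <- fail(m, "accrual_rate: must be positive")
  p <- spec$minimisation_p
  if (!is.numeric(p) || p <= 0.5 || p > 1)
    m <- fail(m, "minimisation_p: must lie in (0.5, 1]")

  if (length(m) > 0)
    abort(c("invalid design specification", setNames(m, rep("x", length(m)))),
          class = "platformtrial_validation_error")
  invisible(spec)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", if (!is.null(x$description)) x$description else "", "\n")
  cat(sprintf("  %d arms: %s\n", nrow(x$arms), paste(x$arms$name, collapse = ", ")))
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  stage %d: %s (%s)\n", x$stages$index[i],
                paste(x$stages$active_arms[[i]], collapse = ":"),
                paste(x$stages$allocation[[i]], collapse = ":")))
  cat(sprintf("  %d hypotheses: %s\n", nrow(x$hypotheses),
              paste(x$hypotheses$label, collapse = ", ")))
  cat(sprintf("  accrual %g/yr, minimisation p = %g\n",
              x$accrual_rate, x$minimisation_p))
  invisible(x)
}

hypothesis_defaults <- function(h) {
  defs <- list(target_hr = NA_real_, control_median = NA_real_,
               experimental_median = NA_real_, p_control = NA_real_,
               p_experimental = NA_real_, accrual_years = NA_real_,
               min_followup_years = NA_real_, dropout_prob = 0,
               target_events = NA_integer_)
  for (nm in names(defs)) if (is.null(h[[nm]])) h[[nm]] <- defs[[nm]]
  h
}

trigger_from_config <- function(x, key) {
  if (is.null(x$type))
    abort(sprintf("config key '%s': trigger needs a 'type'", key),
          class = "platformtrial_schema_error")
  if (identical(x$type, "trial_start")) x$type <- "none"
  trigger(x$type, arm = x$arm, n = x$count %||% x$n,
          from_stage = x$from_stage %||% 1L, time = x$time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need <- function(x, key, parent) {
  if (is.null(x[[key]]))
    abort(sprintf("config key '%s': missing required entry '%s'", parent, key),
          class = "platformtrial_schema_error")
  x[[key]]
}

#' Read a design specification from a YAML config
#'
#' The config is a nested mapping with top-level keys `arms`, `stages`,
#' `hypotheses`, `stratification`, `accrual_rate`, `minimisation` and
#' `stop_rule`.  Stratification factors may be given either as explicit level
#' lists or as an integer level count (levels are then generated as
#' `L001, L002, ...` — convenient for a many-centre factor).  Parse problems
#' raise a schema error naming the offending key; structural problems raise a
#' validation error listing every violated invariant.
#'
#' @param path Path to the YAML file.
#' @return A validated [design_spec()].
#' @export
load_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("design file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("arms", "stages", "hypotheses", "stratification", "accrual_rate"))
    if (is.null(cfg[[key]]))
      abort(sprintf("config key '%s': missing at top level", key),
            class = "platformtrial_schema_error")

  arms <- dplyr::bind_rows(lapply(cfg$arms, function(a) tibble(
    name = need(a, "name", "arms"), role = need(a, "role", "arms"),
    median_pfs = as.numeric(need(a, "median_pfs", "arms")),
    mrd_neg_prob = as.numeric(a$mrd_neg_prob %||% NA_real_))))

  stages <- dplyr::bind_rows(lapply(cfg$stages, function(s) tibble(
    index = as.integer(need(s, "index", "stages")),
    active_arms = list(as.character(need(s, "active_arms", "stages"))),
    allocation = list(as.integer(need(s, "allocation", "stages"))),
    entry_trigger = list(trigger_from_config(
      s$entry_trigger %||% list(type = "none"), "stages.entry_trigger")))))

  hypotheses <- dplyr::bind_rows(lapply(cfg$hypotheses, function(h) {
    h <- hypothesis_defaults(h)
    tibble(
      label = need(h, "label", "hypotheses"),
      experimental_arm = need(h, "experimental_arm", "hypotheses"),
      control_arm = need(h, "control_arm", "hypotheses"),
      endpoint = need(h, "endpoint", "hypotheses"),
      alpha_two_sided = as.numeric(need(h, "alpha_two_sided", "hypotheses")),
      power = as.numeric(need(h, "power", "hypotheses")),
      target_hr = as.numeric(h$target_hr),
      control_median = as.numeric(h$control_median),
      experimental_median = as.numeric(h$experimental_median),
      p_control = as.numeric(h$p_control),
      p_experimental = as.numeric(h$p_experimental),
      accrual_years = as.numeric(h$accrual_years),
      min_followup_years = as.numeric(h$min_followup_years),
      dropout_prob = as.numeric(h$dropout_prob),
      interim_fractions = list(as.numeric(h$interim_fractions %||% 1)),
      target_events = as.integer(h$target_events))
  }))

  strat <- purrr::imap(cfg$stratification, function(lv, nm) {
    if (length(lv) == 1 && is.numeric(lv))
      sprintf("L%03d", seq_len(lv))
    else as.character(lv)
  })

  design_spec(
    arms = arms, stages = stages, hypotheses = hypotheses,
    stratification = strat,
    accrual_rate = as.numeric(cfg$accrual_rate),
    minimisation_p = as.numeric(cfg$minimisation$p %||% 0.8),
    stop_rule = trigger_from_config(cfg$stop_rule %||% list(type = "none"),
                                    "stop_rule"),
    description = cfg$description
  )
}

trigger_to_config <- function(tr) {
  out <- list(type = tr$type)
  if (tr$type == "arm_recruitment")
    out <- c(out, list(arm = tr$arm, count = tr$n, from_stage = tr$from_stage))
  if (tr$type == "calendar") out$time <- tr$time
  out
}

#' Write a design specification to a YAML config
#'
#' The written file reproduces the spec exactly under [load_design()]
#' (round-trip identity).  An invalid spec is refused.
#'
#' @param spec A [design_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_design <- function(spec, path) {
  validate_design(spec)
  cfg <- list(
    description = spec$description,
    accrual_rate = spec$accrual_rate,
    minimisation = list(p = spec$minimisation_p),
    stratification = spec$stratification,
    arms = purrr::pmap(spec$arms, function(name, role, median_pfs, mrd_neg_prob) {
      out <- list(name = name, role = role, median_pfs = median_pfs)
      if (!is.na(mrd_neg_prob)) out$mrd_neg_prob <- mrd_neg_prob
      out
    }),
    stages = purrr::pmap(spec$stages, function(index, active_arms, allocation,
                                               entry_trigger) {
      list(index = index, active_arms = as.list(active_arms),
           allocation = as.list(allocation),
           entry_trigger = trigger_to_config(entry_trigger))
    }),
    stop_rule = trigger_to_config(spec$stop_rule),
    hypotheses = purrr::pmap(spec$hypotheses, function(...) {
      h <- list(...)
      h$interim_fractions <- as.list(h$interim_fractions)
      h[!vapply(h, function(x) length(x) == 1 && is.na(x), logical(1))]
    })
  )
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' The bundled four-arm staged platform-design fixture
#'
#' A three-stage chronic lymphocytic leukaemia platform design: stage 1
#' randomises 1:1 between chemo-immunotherapy control (FCR) and
#' ibrutinib+rituximab (IR); stage 2 adds ibrutinib monotherapy (I, a second
#' control) and ibrutinib+venetoclax (I+V) at 1:1:1:1; stage 3 drops IR once
#' its recruitment target is met and continues 1:1:1.  Three hypotheses are
#' declared: IR vs FCR on progression-free survival (hazard ratio 0.75,
#' medians 4.5 to 6 years, 379 events), I+V vs FCR on progression-free
#' survival (hazard ratio 4.5/6.5, 232 events, interim at half the events)
#' and I+V vs I on minimal-residual-disease negativity.  Stage triggers are
#' recruitment counts chosen so that the comparisons reach 754 (FCR+IR) and
#' 274-per-arm (FCR/I/I+V) concurrently randomised participants, with around
#' 61 stage-2 control patients shared between the two control comparisons.
#'
#' @return A validated [design_spec()].
#' @export
flair_design <- function() {
  load_design(system.file("extdata", "flair.yaml", package = "platformtrial"))
}
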