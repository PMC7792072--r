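# Minimisation randomisation with a random element (Pocock-Simon range
# variant) over the declared stratification factors, with per-stage resets,
# plus simple ratio randomisation as a comparator.  The scoring rule lives in
# compiled code (src/recruit.cpp) and is shared with the staged trial engine
# so that single-step assignment and bulk recruitment are bit-identical.

strat_layout <- function(factors) {
  lv <- lengths(factors)
  offsets <- as.integer(cumsum(c(0L, lv[-length(lv)])))
  names(offsets) <- names(factors)
  list(levels = factors, offsets = offsets, n_rows = sum(lv))
}

profile_rows0 <- function(layout, profile) {
  fac <- names(layout$levels)
  if (!all(fac %in% names(profile)))
    abort(sprintf("profile is missing factor(s): %s",
                  paste(setdiff(fac, names(profile)), collapse = ", ")))
  vapply(fac, function(f) {
    i <- match(profile[[f]], layout$levels[[f]])
    if (is.na(i))
      abort(sprintf("level '%s' is not declared for factor '%s'",
                    profile[[f]], f))
    layout$offsets[[f]] + i - 1L
  }, integer(1))
}

#' Create a minimisation randomiser state
#'
#' @param active_arms Arm names open to allocation (at least 2).
#' @param allocation Positive integer allocation weights, one per arm.
#' @param factors Named list of stratification factors (name -> level
#'   vector).
#' @param p Random element: probability of following the
#'   imbalance-minimising arm, in (0.5, 1].
#' @return A `minimisation_state` with zeroed counts.
#' @seealso [assign_minimisation()], [reset_for_stage()]
#' @export
minimisation_state <- function(active_arms, allocation = rep(1L, length(active_arms)),
                               factors, p = 0.8) {
  if (length(active_arms) < 2) abort("minimisation needs at least 2 active arms")
  stopifnot(length(allocation) == length(active_arms), all(allocation > 0),
            p > 0.5, p <= 1, length(factors) >= 1)
  layout <- strat_layout(factors)
  counts <- matrix(0L, layout$n_rows, length(active_arms),
                   dimnames = list(
                     unlist(purrr::imap(factors, function(lv, f) paste(f, lv, sep = ":"))),
                     active_arms))
  structure(list(active_arms = active_arms, allocation = as.integer(allocation),
                 factors = factors, layout = layout, p = p, counts = counts,
                 n_assigned = 0L),
            class = "minimisation_state")
}

#' Assign one patient by minimisation with a random element
#'
#' The imbalance score of each candidate arm is the sum, over stratification
#' factors, of the running count of patients sharing the new patient's level
#' already on that arm (including the candidate patient), divided by the
#' arm's allocation weight.  The minimising arm is selected with probability
#' `p`; otherwise one of the remaining arms is selected uniformly.  Ties
#' among minima are broken uniformly before the random element is applied, so
#' the very first patient of a stage is assigned uniformly.
#'
#' @param state A [minimisation_state()].
#' @param profile Named list or one-row data frame giving the patient's level
#'   on every declared factor.
#' @return List with `arm` (selected arm name), `scores` (named imbalance
#'   scores) and `state` (updated counts).
#' @export
assign_minimisation <- function(state, profile) {
  stopifnot(inherits(state, "minimisation_state"))
  rows <- profile_rows0(state$layout, profile)
  res <- cpp_minimisation_step(state$counts, rows, as.numeric(state$allocation),
                               state$p)
  arm_i <- res$arm
  state$counts[rows + 1L, arm_i] <- state$counts[rows + 1L, arm_i] + 1L
  state$n_assigned <- state$n_assigned + 1L
  list(arm = state$active_arms[arm_i],
       scores = setNames(res$scores, state$active_arms),
       state = state)
}

#' Reset a minimisation state for a new stage
#'
#' Zeroes every running count and replaces the active arms and allocation
#' ratio with the new stage's — the behaviour required when an arm is added,
#' since carrying counts forward would distort the algorithm against the new
#' arm.  Resetting is idempotent.
#'
#' @param state A [minimisation_state()].
#' @param active_arms,allocation The new stage's arms and weights.
#' @return A fresh `minimisation_state`.
#' @export
reset_for_stage <- function(state, active_arms = state$active_arms,
                            allocation = NULL) {
  stopifnot(inherits(state, "minimisation_state"))
  if (is.null(allocation)) {
    allocation <- if (identical(active_arms, state$active_arms))
      state$allocation else rep(1L, length(active_arms))
  }
  minimisation_state(active_arms, allocation, state$factors, state$p)
}

#' @export
print.minimisation_state <- function(x, ...) {
  cat(sprintf("<minimisation_state> %d arm(s) [%s], p = %g, %d assigned\n",
              length(x$active_arms), paste(x$active_arms, collapse = ", "),
              x$p, x$n_assigned))
  invisible(x)
}

#' Randomise a whole cohort sequentially by minimisation
#'
#' Convenience wrapper running the compiled sequential assignment over a
#' tibble of patient profiles (one column per stratification factor).
#'
#' @param profiles Tibble of factor levels, one row per patient in
#'   randomisation order.
#' @param state A [minimisation_state()].
#' @param seed Optional RNG seed.
#' @return Character vector of assigned arm names.
#' @export
randomise_cohort <- function(profiles, state, seed = NULL) {
  stopifnot(inherits(state, "minimisation_state"))
  if (nrow(profiles) == 0) return(character(0))
  fac <- names(state$layout$levels)
  rows <- vapply(fac, function(f) {
    i <- match(profiles[[f]], state$layout$levels[[f]])
    if (anyNA(i)) abort(sprintf("undeclared level(s) for factor '%s'", f))
    state$layout$offsets[[f]] + i - 1L
  }, integer(nrow(profiles)))
  rows <- matrix(rows, nrow = nrow(profiles))
  stage <- list(active = seq_along(state$active_arms) - 1L,
                weights = as.numeric(state$allocation),
                trigger = list(type = 0L))
  res <- with_seed(seed, cpp_run_recruitment(
    rows, rep(0, nrow(profiles)), list(stage), list(type = 0L),
    length(state$active_arms), state$layout$n_rows, state$p))
  state$active_arms[res$arm]
}

#' Simple (ratio) randomisation
#'
#' Independent allocation with probabilities proportional to the allocation
#' weights; the comparator against which minimisation's balance gain is
#' measured.
#'
#' @param n Number of patients.
#' @param active_arms Arm names.
#' @param allocation Positive weights.
#' @param seed Optional RNG seed.
#' @return Character vector of assigned arm names.
#' @export
simple_randomisation <- function(n, active_arms, allocation = rep(1, length(active_arms)),
                                 seed = NULL) {
  with_seed(seed, sample(active_arms, n, replace = TRUE,
                         prob = allocation / sum(allocation)))
}

#' Per-factor imbalance report for a set of assignments
#'
#' Cross-tabulates assignments against every stratification-factor level and
#' reports, per level, the arm counts and the maximum pairwise absolute
#' count difference, plus the overall arm totals (factor `"(overall)"`).
#'
#' @param assignments Character vector of assigned arms.
#' @param profiles Tibble of factor levels, same length.
#' @return Tibble with columns `factor`, `level`, `arm`, `n`, `max_diff`
#'   (the maximum pairwise difference within the factor level).
#' @export
balance_report <- function(assignments, profiles) {
  if (length(assignments) != nrow(profiles))
    abort("`assignments` and `profiles` must have the same length")
  if (length(assignments) == 0)
    return(tibble(factor = character(), level = character(),
                  arm = character(), n = integer(), max_diff = integer()))
  arms <- sort(unique(assignments))
  long <- as_tibble(profiles)
  long$arm <- assignments
  long <- tidyr::pivot_longer(long, cols = -"arm",
                              names_to = "factor", values_to = "level")
  tab <- dplyr::count(long, .data$factor, .data$level, .data$arm)
  tab <- tidyr::complete(tab, tidyr::nesting(!!rlang::sym("factor"),
                                             !!rlang::sym("level")),
                         arm = arms, fill = list(n = 0L))
  ov <- table(factor(assignments, levels = arms))
  overall <- tibble(factor = "(overall)", level = "", arm = arms,
                    n = as.integer(ov))
  out <- dplyr::bind_rows(tab, overall)
  out <- dplyr::group_by(out, .data$factor, .data$level)
  out <- dplyr::mutate(out, max_diff = max(.data$n) - min(.data$n))
  dplyr::ungroup(out)
}
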