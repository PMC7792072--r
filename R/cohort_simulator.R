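# Synthetic cohort generation with the statistical structure the design
# assumes: independent stratification-factor draws, exponential
# progression-free survival per arm, independent exponential dropout
# calibrated to a by-horizon dropout probability, and Bernoulli
# minimal-residual-disease negativity.

#' Draw stratification-factor profiles
#'
#' Independent draws per factor from the given level distributions.
#'
#' @param factor_distribution Named list: one entry per factor, either a
#'   named probability vector over levels (must sum to 1) or a bare character
#'   vector of levels (taken as uniform).
#' @param n Number of profiles.
#' @param seed Optional RNG seed.
#' @param correlated Must be `FALSE`; correlated factor draws are not
#'   supported and requesting them is an explicit error.
#' @return Tibble with one column per factor, `n` rows.
#' @export
draw_profile <- function(factor_distribution, n, seed = NULL,
                         correlated = FALSE) {
  if (!isFALSE(correlated))
    abort("correlated factor draws are not supported")
  dist <- purrr::map(factor_distribution, function(d) {
    if (is.character(d)) d <- setNames(rep(1 / length(d), length(d)), d)
    if (is.null(names(d)) || any(d < 0) || abs(sum(d) - 1) > 1e-8)
      abort("each factor distribution must be a named probability vector summing to 1")
    d
  })
  with_seed(seed, as_tibble(purrr::map(dist, function(d)
    names(d)[sample.int(length(d), n, replace = TRUE, prob = d)])))
}

dropout_rate <- function(dropout_prob, horizon) {
  if (dropout_prob <= 0) return(0)
  -log(1 - dropout_prob) / horizon
}

#' Draw latent outcomes for patients on one arm
#'
#' Progression-free survival times are exponential with rate
#' \eqn{\log 2 / \mathrm{median}}; dropout times are exponential with the
#' rate solved so that the probability of dropping out within `horizon`
#' years equals `dropout_prob` (`dropout_prob = 0` gives `Inf`, no dropout);
#' minimal-residual-disease negativity is Bernoulli with the arm's
#' probability.  When `u` (a 3-column matrix of uniforms: survival, dropout,
#' response) is supplied the outcomes are produced by inverse transform,
#' which keeps a patient's outcomes tied to their own uniform draws no
#' matter which arm they are assigned to.
#'
#' @param arm One-row data frame or list with `median_pfs` and optionally
#'   `mrd_neg_prob`.
#' @param n Number of patients.
#' @param dropout_prob Probability of dropout within `horizon` years.
#' @param horizon Calibration horizon (years, > 0).
#' @param u Optional `n x 3` matrix of uniforms for inverse-transform draws.
#' @param seed Optional RNG seed (ignored when `u` is given).
#' @return Tibble with `pfs_time`, `dropout_time`, `mrd_negative`.
#' @export
draw_outcomes <- function(arm, n, dropout_prob = 0, horizon = 8,
                          u = NULL, seed = NULL) {
  stopifnot(dropout_prob >= 0, dropout_prob < 1)
  if (horizon <= 0) abort("`horizon` must be positive")
  med <- arm$median_pfs
  if (is.null(med) || is.na(med) || med <= 0)
    abort("arm must have a positive `median_pfs`")
  mrd_p <- arm$mrd_neg_prob %||% NA_real_
  lam <- log(2) / med
  drate <- dropout_rate(dropout_prob, horizon)
  if (is.null(u)) {
    u <- with_seed(seed, matrix(runif(3 * n), ncol = 3))
  }
  tibble(
    pfs_time = qexp(u[, 1], rate = lam),
    dropout_time = if (drate > 0) qexp(u[, 2], rate = drate) else rep(Inf, n),
    mrd_negative = if (is.na(mrd_p)) rep(NA, n) else u[, 3] < mrd_p
  )
}
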