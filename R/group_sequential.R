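# O'Brien-Fleming group-sequential boundaries.  Crossing probabilities of the
# score process (Brownian motion in information time) are computed by the
# classical recursive numerical integration over the density of the process
# confined within the continuation region, look by look.

# Composite Simpson weights for a uniform grid with an odd number of nodes.
simpson_w <- function(x) {
  n <- length(x)
  h <- x[2] - x[1]
  w <- rep(c(2, 4), length.out = n)
  w[c(1, n)] <- 1
  w * h / 3
}

# P(|Z_k| > z_bounds[k] for some k) for the canonical score process observed
# at information fractions t, with drift theta (E S_k = theta * t_k).
# Returns the overall crossing probability and the per-look increments.
gsd_crossing <- function(z_bounds, t, drift = 0, grid_n = 1024) {
  k_looks <- length(t)
  a <- z_bounds * sqrt(t)  # score-scale bounds
  # the grid must resolve the narrowest increment kernel (sd = sqrt(min dt))
  dt_min <- min(diff(c(0, t)))
  grid_n <- max(grid_n, min(4097, ceiling(8 * max(a) / sqrt(dt_min))))
  if (grid_n %% 2 == 0) grid_n <- grid_n + 1  # Simpson needs an odd count
  x <- seq(-a[1], a[1], length.out = grid_n)
  f <- dnorm(x, mean = drift * t[1], sd = sqrt(t[1]))
  surv <- sum(f * simpson_w(x))
  increments <- numeric(k_looks)
  increments[1] <- 1 - surv
  if (k_looks > 1) {
    for (k in 2:k_looks) {
      dt <- t[k] - t[k - 1]
      y <- seq(-a[k], a[k], length.out = grid_n)
      kern <- dnorm(outer(y, x, "-"), mean = drift * dt, sd = sqrt(dt))
      f <- as.vector(kern %*% (f * simpson_w(x)))
      x <- y
      new_surv <- sum(f * simpson_w(x))
      increments[k] <- surv - new_surv
      surv <- new_surv
    }
  }
  list(crossing = 1 - surv, increments = increments)
}

check_fractions <- function(info_fractions) {
  if (length(info_fractions) == 0 || any(info_fractions <= 0) ||
      any(info_fractions > 1) || any(diff(info_fractions) <= 0) ||
      abs(info_fractions[length(info_fractions)] - 1) > 1e-12)
    abort("`info_fractions` must be strictly increasing within (0, 1] and end at 1")
  info_fractions
}

#' O'Brien-Fleming group-sequential boundaries
#'
#' Computes efficacy stopping boundaries for looks at the given information
#' fractions, controlling the overall two-sided type-I error at
#' `alpha_two_sided`.  The default `"classic"` shape uses the original
#' O'Brien-Fleming boundary \eqn{z_k = C / \sqrt{t_k}} (constant on the score
#' scale) with the constant \eqn{C} solved so that the overall null crossing
#' probability — computed by recursive numerical integration over the
#' correlated Gaussian increments, with the grid refined until the boundary
#' is stable to 1e-5 — equals the nominal level.  The `"spending"` shape
#' instead uses the O'Brien-Fleming-like alpha-spending function
#' \eqn{\alpha^*(t) = 2 - 2\Phi(z_{1-\alpha/2}/\sqrt{t})} and solves each
#' look's boundary so the cumulative crossing probability matches the spend.
#'
#' With a single interim at half the information and `alpha_two_sided =
#' 0.05`, the classic boundaries correspond to nominal two-sided p-value
#' thresholds of 0.005 (interim) and 0.048 (final).
#'
#' @param info_fractions Strictly increasing information fractions in (0, 1],
#'   ending at 1 (for an event-driven trial: events observed / events
#'   planned).
#' @param alpha_two_sided Overall two-sided type-I error.
#' @param shape `"classic"` (default) or `"spending"`.
#' @param power Power at which the information inflation factor of the plan
#'   (required information relative to a fixed design) is evaluated.
#' @return A `gsd_plan`: a tibble with one row per look (`look`,
#'   `info_fraction`, `z_bound`, `nominal_p_two_sided`,
#'   `cumulative_alpha_spent`) and attributes `alpha_two_sided`, `shape`,
#'   `inflation_factor`.
#' @examples
#' obf_boundaries(c(0.5, 1))            # nominal p 0.0052 / 0.0480
#' obf_boundaries(c(1/3, 2/3, 1))
#' @export
obf_boundaries <- function(info_fractions, alpha_two_sided = 0.05,
                           shape = c("classic", "spending"), power = 0.80) {
  shape <- match.arg(shape)
  t <- check_fractions(info_fractions)
  stopifnot(alpha_two_sided > 0, alpha_two_sided < 1)
  k_looks <- length(t)

  solve_bounds <- function(grid_n) {
    if (shape == "classic") {
      if (k_looks == 1) {
        qnorm(1 - alpha_two_sided / 2)
      } else {
        cc <- uniroot(function(C)
          gsd_crossing(C / sqrt(t), t, grid_n = grid_n)$crossing - alpha_two_sided,
          c(0.5, 6), tol = 1e-8)$root
        cc / sqrt(t)
      }
    } else {
      spend <- 2 - 2 * pnorm(qnorm(1 - alpha_two_sided / 2) / sqrt(t))
      spend[k_looks] <- alpha_two_sided
      b <- numeric(k_looks)
      b[1] <- qnorm(1 - spend[1] / 2)
      if (k_looks > 1) for (k in 2:k_looks) {
        b[k] <- uniroot(function(z) {
          zb <- c(b[1:(k - 1)], z)
          gsd_crossing(zb, t[1:k], grid_n = grid_n)$crossing - spend[k]
        }, c(0.5, 10), tol = 1e-8)$root
      }
      b
    }
  }

  # refine the integration grid until the boundary is stable to 1e-5
  z <- solve_bounds(256)
  for (gn in c(384, 512, 1024, 2048, 4096)) {
    z_new <- solve_bounds(gn)
    done <- max(abs(z_new - z)) < 1e-5
    z <- z_new
    if (done) break
  }

  cross <- if (k_looks == 1) list(increments = alpha_two_sided)
           else gsd_crossing(z, t, grid_n = 1024)
  cum_spent <- cumsum(cross$increments)
  cum_spent[k_looks] <- alpha_two_sided  # conserved by construction

  # information inflation: drift needed for `power`, relative to fixed design
  theta_fixed <- qnorm(1 - alpha_two_sided / 2) + qnorm(power)
  inflation <- if (k_looks == 1) 1 else {
    theta <- uniroot(function(th)
      gsd_crossing(z, t, drift = th, grid_n = 512)$crossing - power,
      c(theta_fixed * 0.8, theta_fixed * 1.5), tol = 1e-6)$root
    (theta / theta_fixed)^2
  }

  out <- tibble(
    look = seq_len(k_looks),
    info_fraction = t,
    z_bound = z,
    nominal_p_two_sided = 2 * pnorm(-z),
    cumulative_alpha_spent = cum_spent
  )
  attr(out, "alpha_two_sided") <- alpha_two_sided
  attr(out, "shape") <- shape
  attr(out, "inflation_factor") <- inflation
  class(out) <- c("gsd_plan", class(out))
  out
}

#' @export
print.gsd_plan <- function(x, ...) {
  cat(sprintf("<gsd_plan> %s O'Brien-Fleming, two-sided alpha %.4g, inflation %.4f\n",
              attr(x, "shape"), attr(x, "alpha_two_sided"),
              attr(x, "inflation_factor")))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Event counts at which each planned look occurs
#'
#' Translates a group-sequential plan's information fractions into the
#' event counts that trigger each analysis of an event-driven trial.
#'
#' @param plan A [obf_boundaries()] plan.
#' @param total_events Planned total events at the final analysis.
#' @return Tibble with `look`, `info_fraction`, `events`
#'   (`round(fraction * total_events)`).
#' @examples
#' interim_trigger(obf_boundaries(c(0.5, 1)), 232)  # 116, 232
#' @export
interim_trigger <- function(plan, total_events) {
  stopifnot(inherits(plan, "gsd_plan"))
  if (total_events < nrow(plan))
    abort("`total_events` must be at least the number of looks")
  tibble(look = plan$look, info_fraction = plan$info_fraction,
         events = as.integer(round(plan$info_fraction * total_events)))
}
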