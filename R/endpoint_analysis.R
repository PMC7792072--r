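# Bespoke comparative analyses: log-rank score test, proportional-hazards
# regression by Newton-Raphson on the Breslow partial likelihood, logistic
# regression by iteratively reweighted least squares, and the two-sample
# proportion z-test.  The survival package is used only as an independent
# cross-check in the test suite, never here.

#' Two-sample log-rank test
#'
#' Standard observed-minus-expected log-rank statistic for two groups, with
#' the hypergeometric variance.  Also reports the signed normal deviate
#' (negative when the experimental group has fewer events than expected,
#' i.e. appears superior).
#'
#' @param data Tibble with time, event and group columns (as produced by
#'   [analysis_dataset()]).
#' @param time,event,group Column names.
#' @return One-row tibble: `chi_square`, `z` (signed, experimental vs
#'   reference), `p_two_sided`, `n`, `n_events`.
#' @export
logrank <- function(data, time = "time", event = "event", group = "treat") {
  tt <- data[[time]]
  ev <- as.logical(data[[event]])
  g <- data[[group]]
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("log-rank requires exactly 2 groups")
  if (!any(ev)) abort("log-rank requires at least one event")
  g1 <- g == lev[2]

  o <- order(tt)
  tt <- tt[o]; ev <- ev[o]; g1 <- g1[o]
  ut <- unique(tt[ev])
  n_tot <- length(tt)
  n1_tot <- sum(g1)
  below <- findInterval(ut - 1e-12, tt)   # patients with time < ut
  c1 <- c(0, cumsum(g1))                  # shifted so index below+1 is safe
  n_j <- n_tot - below
  n1_j <- n1_tot - c1[below + 1L]
  pos <- match(tt[ev], ut)
  d_j <- tabulate(pos, nbins = length(ut))
  d1_j <- tabulate(pos[g1[ev]], nbins = length(ut))

  e1_j <- d_j * n1_j / n_j
  v_j <- ifelse(n_j > 1,
                d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1),
                0)
  u_stat <- sum(d1_j - e1_j)
  v_stat <- sum(v_j)
  if (v_stat <= 0) abort("log-rank variance is zero")
  z <- u_stat / sqrt(v_stat)
  tibble(chi_square = z^2, z = z, p_two_sided = 2 * pnorm(-abs(z)),
         n = n_tot, n_events = sum(ev))
}

ph_risk_index <- function(tt, ut) findInterval(ut - 1e-12, tt) + 1L

# Breslow partial log-likelihood, gradient and information for sorted data.
ph_deriv <- function(x, tt, ev, beta) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  eta <- pmin(eta, 500)
  w <- exp(eta)
  ut <- unique(tt[ev])
  i_u <- ph_risk_index(tt, ut)        # first index at risk for each event time
  rev_cs <- function(v) rev(cumsum(rev(v)))
  s0 <- rev_cs(w)[i_u]
  s1 <- matrix(0, length(ut), p)
  for (j in seq_len(p)) s1[, j] <- rev_cs(w * x[, j])[i_u]
  pos <- match(tt[ev], ut)
  d_u <- tabulate(pos, nbins = length(ut))
  # per-event-time sums of covariates (every ut has >= 1 event, so rowsum
  # groups are exactly 1..K in order)
  sx <- rowsum(x[ev, , drop = FALSE], group = pos)
  ll <- sum(x[ev, , drop = FALSE] %*% beta) - sum(d_u * log(s0))
  grad <- colSums(sx) - colSums(d_u * s1 / s0)
  info <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in j:p) {
    s2jk <- rev_cs(w * x[, j] * x[, k])[i_u]
    v <- sum(d_u * (s2jk / s0 - (s1[, j] / s0) * (s1[, k] / s0)))
    info[j, k] <- info[k, j] <- v
  }
  list(ll = ll, grad = grad, info = info)
}

build_design_matrix <- function(data, covariates) {
  if (length(covariates) == 0) return(NULL)
  df <- as.data.frame(data[covariates])
  # constant columns carry no information and would break the contrasts
  df <- df[vapply(df, function(v) length(unique(v)) > 1, logical(1))]
  if (ncol(df) == 0) return(NULL)
  # stage and factor covariates enter as unordered indicator contrasts
  for (nm in names(df))
    if (!is.numeric(df[[nm]]) || nm == "stage") df[[nm]] <- factor(df[[nm]])
  mm <- stats::model.matrix(~ ., df)
  mm[, -1, drop = FALSE]
}

#' Proportional-hazards regression (Breslow partial likelihood)
#'
#' Fits a Cox proportional-hazards model by Newton-Raphson on the Breslow
#' partial likelihood, with the treatment indicator first and any further
#' covariates (trial stage and stratification factors, entered as unordered
#' indicator contrasts) after it.  Standard errors come from the inverse
#' observed information; the global score test at the null is reported (for
#' a single binary covariate it equals the log-rank chi-square).
#' Non-convergence and monotone-likelihood divergence (e.g. all events on
#' one arm) are flagged, never returned silently.
#'
#' @param data Analysis table (see [analysis_dataset()]).
#' @param covariates Character vector of additional covariate columns.
#' @param time,event,treat Column names.
#' @param max_iter,tol Newton-Raphson controls (gradient max-norm
#'   tolerance).
#' @return A `ph_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_ph <- function(data, covariates = character(), time = "time",
                   event = "event", treat = "treat", max_iter = 25,
                   tol = 1e-9) {
  ev <- as.logical(data[[event]])
  if (!any(ev)) abort("proportional-hazards fit requires at least one event")
  x1 <- matrix(as.numeric(data[[treat]]), ncol = 1,
               dimnames = list(NULL, treat))
  xc <- build_design_matrix(data, covariates)
  x <- if (is.null(xc)) x1 else cbind(x1, xc)
  o <- order(data[[time]])
  x <- x[o, , drop = FALSE]
  tt <- data[[time]][o]
  ev <- ev[o]
  p <- ncol(x)

  beta <- rep(0, p)
  d0 <- ph_deriv(x, tt, ev, beta)
  score_stat <- tryCatch(
    drop(t(d0$grad) %*% solve(d0$info, d0$grad)),
    error = function(e) NA_real_)

  converged <- FALSE
  diverged <- FALSE
  iter <- 0
  d <- d0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(d$info, d$grad), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    beta_new <- beta + step
    d_new <- ph_deriv(x, tt, ev, beta_new)
    halve <- 0
    while ((!is.finite(d_new$ll) || d_new$ll < d$ll - 1e-12) && halve < 20) {
      halve <- halve + 1
      beta_new <- beta + step / 2^halve
      d_new <- ph_deriv(x, tt, ev, beta_new)
    }
    beta <- beta_new
    d <- d_new
    if (max(abs(beta)) > 15) { diverged <- TRUE; break }
    if (max(abs(d$grad)) < tol) { converged <- TRUE; break }
  }

  vcov <- tryCatch(solve(d$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  zval <- beta / se
  structure(list(
    coefficients = setNames(beta, colnames(x)),
    std_errors = setNames(se, colnames(x)),
    vcov = vcov,
    loglik = d$ll,
    score_statistic = score_stat,
    wald_p_two_sided = 2 * pnorm(-abs(zval[1])),
    n = length(tt), n_events = sum(ev),
    converged = converged, diverged = diverged, iterations = iter
  ), class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("<ph_fit> n = %d, events = %d, %s (%d iterations)\n",
              x$n, x$n_events,
              if (x$diverged) "DIVERGED (monotone likelihood?)"
              else if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(tidy(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ph_fit <- function(x, ...) {
  est <- x$coefficients
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(x$std_errors),
         statistic = unname(est / x$std_errors),
         p.value = 2 * pnorm(-abs(unname(est / x$std_errors))),
         hazard.ratio = exp(unname(est)))
}

#' @exportS3Method generics::glance
glance.ph_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         score_statistic = x$score_statistic,
         wald_p_two_sided = x$wald_p_two_sided,
         converged = x$converged, iterations = x$iterations)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Binary-endpoint analogue of [fit_ph()]: the treatment indicator first,
#' optional stage/stratification covariates after.  Complete separation is
#' detected (diverging coefficients or degenerate fitted probabilities) and
#' flagged.
#'
#' @param data Analysis table with a logical/0-1 response column.
#' @param covariates Additional covariate columns.
#' @param response,treat Column names.
#' @param max_iter,tol IRLS controls.
#' @return A `logistic_fit` object with [tidy()] / [glance()] methods.
#' @export
fit_logistic <- function(data, covariates = character(),
                         response = "mrd_negative", treat = "treat",
                         max_iter = 50, tol = 1e-10) {
  y <- as.numeric(data[[response]])
  if (anyNA(y)) abort("response contains missing values")
  x1 <- matrix(as.numeric(data[[treat]]), ncol = 1,
               dimnames = list(NULL, treat))
  xc <- build_design_matrix(data, covariates)
  x <- cbind(`(Intercept)` = 1, if (is.null(xc)) x1 else cbind(x1, xc))
  if (length(unique(data[[treat]])) < 2)
    abort("both arms must be represented")
  p <- ncol(x)

  # efficient score test for the treatment effect at the null (no-treatment
  # model); with no further covariates it reduces to the pooled-variance
  # two-proportion chi-square
  x_red <- x[, -2, drop = FALSE]
  b_red <- rep(0, ncol(x_red))
  for (it in 1:50) {
    mu_r <- 1 / (1 + exp(-drop(x_red %*% b_red)))
    w_r <- mu_r * (1 - mu_r)
    st <- tryCatch(solve(t(x_red * w_r) %*% x_red, t(x_red) %*% (y - mu_r)),
                   error = function(e) NULL)
    if (is.null(st)) break
    b_red <- b_red + drop(st)
    if (max(abs(st)) < 1e-10) break
  }
  mu_r <- 1 / (1 + exp(-drop(x_red %*% b_red)))
  w_r <- mu_r * (1 - mu_r)
  u_full <- drop(t(x) %*% (y - mu_r))
  i_full <- t(x * w_r) %*% x
  score_stat <- tryCatch(drop(t(u_full) %*% solve(i_full, u_full)),
                         error = function(e) NA_real_)

  beta <- rep(0, p)
  converged <- FALSE
  separated <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    if (any(w < 1e-10 & (y - mu)^2 > 0.25)) { separated <- TRUE }
    xtw <- t(x * w)
    step <- tryCatch(solve(xtw %*% x, t(x) %*% (y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    beta <- beta + drop(step)
    if (max(abs(beta)) > 15) { separated <- TRUE; break }
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(x %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- t(x * (mu * (1 - mu))) %*% x
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  structure(list(
    coefficients = setNames(drop(beta), colnames(x)),
    std_errors = setNames(se, colnames(x)), vcov = vcov,
    score_statistic = score_stat,
    wald_p_two_sided = 2 * pnorm(-abs(beta[2] / se[2])),
    n = length(y), converged = converged && !separated,
    separated = separated, iterations = iter
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, %s%s\n", x$n,
              if (x$converged) "converged" else "NOT converged",
              if (x$separated) " (separation detected)" else ""))
  print(tidy(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, ...) {
  est <- x$coefficients
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(x$std_errors),
         statistic = unname(est / x$std_errors),
         p.value = 2 * pnorm(-abs(unname(est / x$std_errors))),
         odds.ratio = exp(unname(est)))
}

#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble(n = x$n, score_statistic = x$score_statistic,
         wald_p_two_sided = x$wald_p_two_sided,
         converged = x$converged, separated = x$separated,
         iterations = x$iterations)
}

#' Two-sample proportion z-test
#'
#' Normal-approximation test of equal response probabilities; the pooled
#' variant (default) uses the pooled variance under the null, matching the
#' power formula of [binary_power()].
#'
#' @param x0,n0 Control responders and sample size.
#' @param x1,n1 Experimental responders and sample size.
#' @param pooled Use the pooled null variance.
#' @return One-row tibble: `z` (experimental minus control),
#'   `p_two_sided`, `p0_hat`, `p1_hat`.
#' @export
two_prop_test <- function(x0, n0, x1, n1, pooled = TRUE) {
  stopifnot(n0 > 0, n1 > 0, x0 >= 0, x1 >= 0, x0 <= n0, x1 <= n1)
  p0 <- x0 / n0
  p1 <- x1 / n1
  se <- if (pooled) {
    pb <- (x0 + x1) / (n0 + n1)
    sqrt(pb * (1 - pb) * (1 / n0 + 1 / n1))
  } else {
    sqrt(p0 * (1 - p0) / n0 + p1 * (1 - p1) / n1)
  }
  z <- if (se == 0) 0 else (p1 - p0) / se
  tibble(z = z, p_two_sided = 2 * pnorm(-abs(z)), p0_hat = p0, p1_hat = p1)
}
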