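#' Evaluate a logistic psychometric function
#'
#' \deqn{p(x) = \gamma + \frac{1 - \gamma - \lambda}{1 + e^{-\beta (x - \alpha)}}}
#' where `alpha` is the location, `beta` the slope (sign free, so the same
#' form covers masking tasks in which performance falls with the level),
#' `gamma` the guess rate (chance floor) and `lambda` the lapse rate.
#'
#' @param x Stimulus level(s) on the fitted axis (dB contrast, dB ratio, or
#'   log2 arc seconds).
#' @param alpha Location parameter, same units as `x`.
#' @param beta Slope per unit of `x`.
#' @param gamma Guess rate in `[0, 1)`.
#' @param lambda Lapse rate; requires `gamma < 1 - lambda`.
#' @return Probability of success, in `[gamma, 1 - lambda]`.
#' @export
#' @examples
#' pf_evaluate(0, alpha = 0, beta = 1, gamma = 0.5) # 0.75
pf_evaluate <- function(x, alpha, beta, gamma = 0, lambda = 0) {
  check_rates(gamma, lambda)
  gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))
}

check_rates <- function(gamma, lambda) {
  if (gamma < 0 || lambda < 0 || gamma >= 1 - lambda) {
    rlang::abort("Rates must satisfy 0 <= gamma < 1 - lambda <= 1.")
  }
  invisible(TRUE)
}

# Aggregate trial rows to (level, k successes, n trials); the binomial
# likelihood only depends on these.
aggregate_trials <- function(data) {
  lv <- data$level
  oc <- as.integer(data$outcome)
  if (any(is.na(lv)) || any(!oc %in% c(0L, 1L))) {
    rlang::abort("Trials need finite `level` and binary `outcome` columns.")
  }
  f <- factor(lv)
  k <- as.integer(rowsum(oc, f))
  n <- as.integer(tabulate(f))
  data.frame(level = as.numeric(levels(f)), k = k, n = n)
}

pf_negll <- function(theta, level, k, n, gamma, span) {
  p <- gamma + span / (1 + exp(-theta[2] * (level - theta[1])))
  p[p < 1e-12] <- 1e-12
  p[p > 1 - 1e-12] <- 1 - 1e-12
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit a logistic psychometric function by maximum likelihood
#'
#' Estimates location `alpha` and slope `beta` with the guess rate fixed at
#' the task's chance level and the lapse rate fixed by policy (0 by default,
#' optionally a small fixed value such as 0.02). The likelihood is maximised
#' by Nelder-Mead simplex from a small grid of starting points (location at
#' level quantiles, both slope signs), so masking-style data with falling
#' performance are fitted without special-casing.
#'
#' Degenerate data - all trials correct, all incorrect, or perfectly
#' separated responses - cannot constrain the parameters; the fit is then
#' returned with `converged = FALSE` and `NA` estimates rather than a
#' silent extrapolation.
#'
#' @param data A data frame of trials with numeric `level` and binary
#'   `outcome` columns (1 = success). Repetitions should be pooled at the
#'   trial level before fitting.
#' @param gamma Fixed guess rate (0.5 single-interval two-choice, 0.25 for
#'   4AFC, 0 for appearance judgements).
#' @param lambda Fixed lapse rate.
#' @param beta_max Slope magnitude (per axis unit) beyond which the data are
#'   treated as separated and the fit flagged non-converged.
#' @return An object of class `pf_fit`: list with `alpha`, `beta`, `gamma`,
#'   `lambda`, `logLik`, `converged`, `n_trials`, `n_levels`, and the
#'   aggregated data.
#' @export
fit_pf <- function(data, gamma = 0.5, lambda = 0, beta_max = 50) {
  check_rates(gamma, lambda)
  agg <- aggregate_trials(data)
  n_trials <- sum(agg$n)
  bad <- function(msg) {
    structure(list(alpha = NA_real_, beta = NA_real_, gamma = gamma,
                   lambda = lambda, logLik = NA_real_, converged = FALSE,
                   reason = msg, n_trials = n_trials, n_levels = nrow(agg),
                   data = tibble::as_tibble(agg)),
              class = "pf_fit")
  }
  if (nrow(agg) < 2) return(bad("fewer than two distinct levels"))
  k_tot <- sum(agg$k)
  if (k_tot == 0 || k_tot == n_trials) {
    return(bad("all responses identical"))
  }
  expanded <- rep(agg$level, agg$n)
  spread <- max(stats::sd(expanded), 1e-6)
  # data-driven starts: location near the level whose pooled proportion is
  # closest to the range midpoint; slope sign from the level-outcome trend
  mid_target <- gamma + (1 - gamma - lambda) / 2
  alpha0 <- agg$level[which.min(abs(agg$k / agg$n - mid_target))]
  trend <- stats::cov(agg$level, agg$k / agg$n)
  signs <- if (is.finite(trend) && trend != 0) sign(trend) else c(-1, 1)
  starts <- expand.grid(alpha = c(alpha0, stats::median(expanded)),
                        beta = c(signs / spread, 3 * signs / spread))
  starts <- unique(starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$alpha[i], starts$beta[i]), pf_negll,
                      level = agg$level, k = agg$k, n = agg$n,
                      gamma = gamma, span = 1 - gamma - lambda,
                      method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- best$convergence == 0 &&
    is.finite(best$value) &&
    abs(best$par[2]) < beta_max &&
    abs(best$par[2]) > 1e-8
  structure(
    list(alpha = best$par[1], beta = best$par[2], gamma = gamma,
         lambda = lambda, logLik = -best$value, converged = converged,
         reason = if (converged) NA_character_ else "optimizer at bound",
         n_trials = n_trials, n_levels = nrow(agg),
         data = tibble::as_tibble(agg)),
    class = "pf_fit"
  )
}

#' @export
print.pf_fit <- function(x, ...) {
  cat("Logistic psychometric fit\n")
  if (isTRUE(x$converged)) {
    cat(sprintf("  alpha = %.3f, beta = %.3f (gamma = %g, lambda = %g)\n",
                x$alpha, x$beta, x$gamma, x$lambda))
    cat(sprintf("  logLik = %.2f on %d trials at %d levels\n",
                x$logLik, x$n_trials, x$n_levels))
  } else {
    cat(sprintf("  NOT converged (%s); %d trials at %d levels\n",
                x$reason, x$n_trials, x$n_levels))
  }
  invisible(x)
}

#' Stimulus level at a criterion performance
#'
#' Inverts the fitted logistic at a criterion probability (75% correct for
#' single-interval two-choice tasks, 62.5% for 4AFC). For a zero lapse rate
#' and the criterion at the midpoint of the performance range the threshold
#' equals `alpha` exactly.
#'
#' @param fit A `pf_fit`, or a list with `alpha`, `beta`, `gamma`, `lambda`.
#' @param criterion Probability strictly inside `(gamma, 1 - lambda)`.
#' @return The level at which the fitted function equals `criterion`.
#' @export
threshold_from_fit <- function(fit, criterion) {
  if (inherits(fit, "pf_fit") && !isTRUE(fit$converged)) {
    return(NA_real_)
  }
  g <- fit$gamma
  l <- fit$lambda
  if (criterion <= g || criterion >= 1 - l) {
    rlang::abort("`criterion` must lie strictly inside (gamma, 1 - lambda).")
  }
  fit$alpha - log((1 - g - l) / (criterion - g) - 1) / fit$beta
}

#' Fit the binocular balance point
#'
#' Fits a full-range logistic (`gamma = 0`, `lambda = 0`) to the proportion
#' of left-eye-dominant responses as a function of the interocular contrast
#' ratio in dB (`20 * log10(c_left / c_right)`). The balance point is the
#' fitted 50% point: the ratio at which the two eyes contribute equally to
#' the fused percept (point of subjective equality). 0 dB is perfect
#' balance; a positive balance point means the left eye needed the higher
#' contrast, i.e. right-eye sensory dominance.
#'
#' @param data A data frame with `level` (ratio in dB) and `outcome`
#'   (1 = left-eye-dominant response).
#' @return An object of class `bp_fit`: list with `bp` (dB), `slope`,
#'   `logLik`, `converged`, and the underlying `pf_fit`.
#' @export
fit_balance_point <- function(data) {
  fit <- fit_pf(data, gamma = 0, lambda = 0)
  bp <- if (isTRUE(fit$converged)) threshold_from_fit(fit, 0.5) else NA_real_
  structure(
    list(bp = bp, slope = fit$beta, logLik = fit$logLik,
         converged = fit$converged, pf = fit),
    class = "bp_fit"
  )
}

#' @export
print.bp_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("Balance point: %.2f dB (slope %.3f per dB)\n", x$bp, x$slope))
  } else {
    cat("Balance point fit did not converge\n")
  }
  invisible(x)
}
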