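#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `pf_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`alpha`, `beta`; the fixed
#'   `gamma` and `lambda` are reported with `fixed = TRUE`).
#' @method tidy pf_fit
#' @export
tidy.pf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "lambda"),
    estimate = c(x$alpha, x$beta, x$gamma, x$lambda),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' @rdname tidy.pf_fit
#' @method glance pf_fit
#' @export
glance.pf_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, converged = x$converged,
                 n_trials = x$n_trials, n_levels = x$n_levels)
}

#' Tidy a gain-control fit
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter, giving both the
#'   linear estimate and its dB form.
#' @method tidy gc_fit
#' @export
tidy.gc_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("gR", "gL", "wR", "wL"),
    estimate = c(p$gR, p$gL, p$wR, p$wL),
    estimate_db = c(p$GR, p$GL, p$WR, p$WL)
  )
}

#' @rdname tidy.gc_fit
#' @method glance gc_fit
#' @export
glance.gc_fit <- function(x, ...) {
  s <- suppression_strength(x)
  tibble::tibble(rmse_db = x$rmse_db, converged = x$converged,
                 n_starts = x$n_starts,
                 supstrR = s$supstrR, supstrL = s$supstrL)
}

#' Tidy a balance-point fit
#'
#' @param x A `bp_fit`.
#' @param ... Unused.
#' @return One-row tibble with the balance point (dB), slope, and fit
#'   diagnostics.
#' @method tidy bp_fit
#' @export
tidy.bp_fit <- function(x, ...) {
  tibble::tibble(bp_db = x$bp, slope = x$slope, logLik = x$logLik,
                 converged = x$converged)
}

#' Tidy a group report
#'
#' @param x A `group_report`.
#' @param ... Unused.
#' @return The Mann-Whitney comparison table (one row per measure).
#' @method tidy group_report
#' @export
tidy.group_report <- function(x, ...) {
  x$tests
}

#' @rdname tidy.group_report
#' @method glance group_report
#' @export
glance.group_report <- function(x, ...) {
  tibble::tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    n1 = x$n[[x$groups[1]]], n2 = x$n[[x$groups[2]]],
    n_tests = nrow(x$tests),
    has_anova = !is.null(x$anova),
    schema_version = x$schema_version
  )
}

#' Tidy a two-way ANOVA
#'
#' @param x An `anova_2x3`.
#' @param ... Unused.
#' @return The ANOVA table as a tibble.
#' @method tidy anova_2x3
#' @export
tidy.anova_2x3 <- function(x, ...) {
  x$table
}
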