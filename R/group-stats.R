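#' Two-sided Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Computes the U statistic for the first sample and the tie-corrected,
#' continuity-corrected normal-approximation Z and two-sided p value, the
#' form in which rank tests on cohorts of a few dozen subjects are
#' conventionally reported. For small samples an exact enumeration over
#' rank assignments is the natural cross-check (used in this package's
#' test suite), but the reported statistic is always the asymptotic one.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A one-row tibble: `statistic` (name), `U`, `z`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) rlang::abort("Both samples must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    d <- U - mu
    d <- sign(d) * max(0, abs(d) - 0.5) # continuity correction
    z <- d / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(statistic = "Mann-Whitney U", U = U, z = z, p = p,
                 n1 = n1, n2 = n2)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Midrank-tied Spearman rho with the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Constant input leaves the correlation undefined; `rho` is returned as
#' `NA` with `defined = FALSE` rather than a silent zero.
#'
#' @param x,y Paired numeric samples, `n >= 3` complete pairs.
#' @return A one-row tibble: `rho`, `p`, `n`, `defined`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("Spearman needs at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          defined = FALSE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n, defined = TRUE)
}

#' Compare two correlations with the Fisher r-to-z transformation
#'
#' \deqn{z = \frac{\mathrm{atanh}(\rho_1) - \mathrm{atanh}(\rho_2)}
#'   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}}}
#' with a two-sided normal p value. Applied directly to Spearman rho with
#' the standard error `sqrt(1/(n-3))` (the common applied procedure; no
#' variance adjustment for rank correlations).
#'
#' @param rho1,rho2 Correlations, `|rho| < 1`.
#' @param n1,n2 Sample sizes, each `> 3`.
#' @return A one-row tibble: `z`, `p`, `rho1`, `rho2`, `n1`, `n2`.
#' @export
#' @examples
#' fisher_compare(0.77, 28, 0.40, 28) # z about 2.11
fisher_compare <- function(rho1, n1, rho2, n2) {
  if (abs(rho1) >= 1 || abs(rho2) >= 1) {
    rlang::abort("Correlations must satisfy |rho| < 1.")
  }
  if (n1 <= 3 || n2 <= 3) rlang::abort("Sample sizes must exceed 3.")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)),
                 rho1 = rho1, rho2 = rho2, n1 = n1, n2 = n2)
}

#' Between-subjects two-way ANOVA with Bonferroni post hocs
#'
#' Fits a fully between-subjects two-way ANOVA with interaction (the 2x3
#' group-by-test layout used for comparing stereoacuity across testing
#' methods, where the per-subject test values are treated as independent
#' observations, so the error df is `N - 6`). Sums of squares are
#' sequential (they coincide with every other type in the balanced case).
#' Post-hoc pairwise comparisons among the levels of the second factor use
#' the ANOVA error term with Bonferroni-adjusted p values.
#'
#' @param data Data frame with the response and two factor columns.
#' @param value,group,test Column names (strings) of the response, the
#'   2-level factor, and the 3-level factor.
#' @return An object of class `anova_2x3`: list with `table` (tibble:
#'   `term`, `df`, `sumsq`, `F`, `p`) and `posthoc` (tibble of pairwise
#'   test-factor comparisons with Bonferroni-adjusted p).
#' @export
two_way_anova <- function(data, value = "value", group = "group",
                          test = "test") {
  df <- data.frame(
    y = data[[value]],
    A = factor(data[[group]]),
    B = factor(data[[test]])
  )
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    rlang::abort("Each factor needs at least 2 levels.")
  }
  fit <- stats::aov(y ~ A * B, data = df)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  tab <- tibble::tibble(
    term = dplyr::recode(terms, A = "group", B = "test", `A:B` = "group:test",
                         Residuals = "residuals"),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    F = s$`F value`,
    p = s$`Pr(>F)`
  )
  # a zero effect sum of squares is a zero F even when the error term
  # vanishes too (constant data); "zero" judged relative to the data scale
  scale <- sum(df$y^2) + 1
  zero <- tab$term != "residuals" & tab$sumsq < 1e-12 * scale
  tab$F[zero] <- 0
  tab$p[zero] <- 1
  mse <- tab$sumsq[tab$term == "residuals"] / tab$df[tab$term == "residuals"]
  dfe <- tab$df[tab$term == "residuals"]
  lev <- levels(df$B)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  posthoc <- purrr::map_dfr(pairs, function(pr) {
    yi <- df$y[df$B == pr[1]]; yj <- df$y[df$B == pr[2]]
    se <- sqrt(mse * (1 / length(yi) + 1 / length(yj)))
    tstat <- (mean(yi) - mean(yj)) / se
    tibble::tibble(
      contrast = paste(pr[1], "-", pr[2]),
      estimate = mean(yi) - mean(yj),
      t = tstat, df = dfe,
      p_adj = min(1, n_pairs * 2 * stats::pt(-abs(tstat), dfe))
    )
  })
  structure(list(table = tab, posthoc = posthoc), class = "anova_2x3")
}

#' @export
print.anova_2x3 <- function(x, ...) {
  cat("Two-way between-subjects ANOVA\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat("Bonferroni post hocs (second factor):\n")
  print(as.data.frame(x$posthoc), row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA from per-cell summary statistics
#'
#' Reconstructs, for each cell, a data vector with exactly the given mean
#' and standard deviation (an affine transform of a fixed centred,
#' unit-variance pattern) and runs [two_way_anova()] on it. Every F ratio
#' and sum of squares depends on the data only through the per-cell mean,
#' SD, and n, so this reconstruction is exact, not approximate.
#'
#' @param cells Data frame with one row per cell: factor columns `group`
#'   and `test`, and numeric `mean`, `sd`, `n` (each `n >= 2`).
#' @return An `anova_2x3`, as from [two_way_anova()].
#' @export
two_way_anova_from_summary <- function(cells) {
  need <- c("group", "test", "mean", "sd", "n")
  if (!all(need %in% names(cells))) {
    rlang::abort("`cells` needs columns group, test, mean, sd, n.")
  }
  if (any(cells$n < 2)) rlang::abort("Each cell needs n >= 2.")
  rows <- purrr::pmap_dfr(cells, function(group, test, mean, sd, n, ...) {
    e <- seq_len(n)
    e <- (e - base::mean(e)) / stats::sd(e) # exact zero mean, unit SD
    tibble::tibble(group = group, test = test, value = mean + sd * e)
  })
  two_way_anova(rows, value = "value", group = "group", test = "test")
}

#' Power of the two-sided Wilcoxon-Mann-Whitney test
#'
#' Asymptotic-relative-efficiency approximation with normal parent
#' distributions: the effective per-group sample size is `0.955 * n`
#' (3/pi ARE of the rank test against the t test), the effect size is
#' `d = |mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)`, and power is
#' evaluated from the noncentral t distribution with
#' `df = 2 * (n_eff - 1)` and noncentrality `d * sqrt(n_eff / 2)`.
#'
#' @param mean1,sd1,mean2,sd2 Group summary statistics (`sd > 0`).
#' @param n_per_group Subjects per group (`>= 2`).
#' @param alpha Two-sided significance level.
#' @return Power as a proportion in `[alpha, 1)`; equals `alpha` exactly at
#'   zero effect.
#' @export
#' @examples
#' wmw_power(6.3, 1.0, 5.5, 0.7, 28) # about 0.914
wmw_power <- function(mean1, sd1, mean2, sd2, n_per_group, alpha = 0.05) {
  if (sd1 <= 0 || sd2 <= 0) rlang::abort("SDs must be positive.")
  if (n_per_group < 2) rlang::abort("Need n >= 2 per group.")
  d <- abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
  n_eff <- 0.955 * n_per_group
  df <- 2 * (n_eff - 1)
  ncp <- d * sqrt(n_eff / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}
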