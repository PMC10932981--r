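# independent exact Mann-Whitney oracle: enumerate all assignments of the
# pooled observations to the first group
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  u_obs <- abs(u_of(seq_len(n1)) - mu)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= u_obs - 1e-12)
}

test_that("Mann-Whitney agrees with exhaustive enumeration at small n", {
  set.seed(201)
  cases <- list(
    list(x = c(1.2, 3.4, 0.8, 5.1), y = c(2.2, 6.3, 4.4, 7.0)),
    list(x = stats::rnorm(3), y = stats::rnorm(5)),
    list(x = stats::rnorm(5), y = stats::rnorm(5)),
    list(x = stats::rnorm(4), y = stats::rnorm(6)),
    list(x = c(1, 2, 2, 3), y = c(2, 3, 3, 4)) # ties
  )
  for (cs in cases) {
    res <- mann_whitney(cs$x, cs$y)
    # U from the counting definition (pairs where x beats y, ties half)
    u_count <- sum(outer(cs$x, cs$y, ">")) + 0.5 * sum(outer(cs$x, cs$y, "=="))
    expect_equal(res$U, u_count)
    p_exact <- mw_exact_p(cs$x, cs$y)
    # the exact null at heavily tied tiny samples is very discrete, so
    # allow a wider band there
    tol <- if (anyDuplicated(c(cs$x, cs$y)) > 0) 0.15 else 0.05
    expect_lt(abs(res$p - p_exact), tol)
  }
})

test_that("Mann-Whitney handles identical and fully separated samples", {
  x <- c(1, 2, 3, 4)
  res <- mann_whitney(x, x)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  res2 <- mann_whitney(c(1, 2, 3), c(10, 11, 12, 13))
  expect_equal(res2$U, 0)
  # minimal attainable p at this n (exact minimum is 2/35 = 0.057)
  expect_lt(res2$p, 0.06)
  expect_equal(mann_whitney(c(10, 11, 12, 13), c(1, 2, 3))$U, 12)
  # antisymmetry
  a <- stats::rnorm(6); b <- stats::rnorm(8)
  expect_equal(mann_whitney(a, b)$z, -mann_whitney(b, a)$z,
               tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Spearman matches the rank formula and flags constant input", {
  expect_equal(spearman(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman(1:8, -(1:8))$rho, -1)
  x <- c(3.1, 0.2, 5.5, 2.2, 4.1, 1.0)
  y <- c(0.5, 1.2, 4.0, 2.5, 2.0, 3.3)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  res <- spearman(x, y)
  expect_equal(res$rho, rho_hand, tolerance = 1e-12)
  t_hand <- rho_hand * sqrt(4 / (1 - rho_hand^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_false(spearman(rep(1, 5), stats::rnorm(5))$defined)
  expect_error(spearman(1:2, 1:2), "3")
})

test_that("Fisher r-to-z comparison evaluates its closed form", {
  expect_equal(fisher_compare(0.5, 20, 0.5, 25)$z, 0)
  z1 <- fisher_compare(0.7, 20, 0.3, 25)$z
  z2 <- fisher_compare(0.3, 25, 0.7, 20)$z
  expect_equal(z1, -z2, tolerance = 1e-12)
  expect_equal(fisher_compare(0.77, 28, 0.40, 28)$z, 2.1095782,
               tolerance = 1e-6)
  expect_error(fisher_compare(1, 20, 0.5, 20), "rho")
  expect_error(fisher_compare(0.5, 3, 0.5, 20), "exceed 3")
})

test_that("two-way ANOVA matches a hand-computed 12-observation fixture", {
  df <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 6),
    test = rep(rep(c("t1", "t2", "t3"), each = 2), 2),
    value = c(4, 6, 7, 9, 10, 12, 5, 7, 9, 11, 14, 16)
  )
  res <- two_way_anova(df, "value", "group", "test")
  # independent sums-of-squares decomposition from first principles
  gm <- mean(df$value)
  ss_tot <- sum((df$value - gm)^2)
  mA <- tapply(df$value, df$group, mean)
  ss_a <- 6 * sum((mA - gm)^2)
  mB <- tapply(df$value, df$test, mean)
  ss_b <- 4 * sum((mB - gm)^2)
  cellm <- tapply(df$value, interaction(df$group, df$test), mean)
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- ss_tot - ss_cells
  tab <- res$table
  expect_equal(tab$sumsq[tab$term == "group"], ss_a, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "test"], ss_b, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "group:test"], ss_ab, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "residuals"], ss_err, tolerance = 1e-9)
  expect_equal(tab$df, c(1, 2, 2, 6))
  f_a <- (ss_a / 1) / (ss_err / 6)
  expect_equal(tab$F[tab$term == "group"], f_a, tolerance = 1e-9)
  # post hocs use the pooled error term with a 3-fold Bonferroni factor
  ph <- res$posthoc
  expect_equal(nrow(ph), 3)
  mse <- ss_err / 6
  t12 <- (mB[["t1"]] - mB[["t2"]]) / sqrt(mse * (1 / 4 + 1 / 4))
  expect_equal(ph$t[ph$contrast == "t1 - t2"], t12, tolerance = 1e-9)
  expect_equal(ph$p_adj[ph$contrast == "t1 - t2"],
               min(1, 3 * 2 * stats::pt(-abs(t12), 6)), tolerance = 1e-9)
})

test_that("balanced sums of squares decompose exactly", {
  set.seed(202)
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 15),
    test = rep(rep(c("x", "y", "z"), each = 5), 2),
    value = stats::rnorm(30)
  )
  tab <- two_way_anova(df, "value", "group", "test")$table
  ss_tot <- sum((df$value - mean(df$value))^2)
  expect_equal(sum(tab$sumsq), ss_tot, tolerance = 1e-9)
})

test_that("constant data produce zero effect sums of squares", {
  df <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                       test = rep(rep(c("x", "y", "z"), each = 2), 2),
                       value = 5)
  tab <- two_way_anova(df, "value", "group", "test")$table
  expect_equal(tab$F[tab$term != "residuals"], c(0, 0, 0))
  expect_error(two_way_anova(df[df$group == "a", ], "value", "group",
                             "test"), "levels")
})

test_that("summary-statistic ANOVA is exact, not approximate", {
  set.seed(203)
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 12),
    test = rep(rep(c("x", "y", "z"), each = 4), 2),
    value = stats::rnorm(24, mean = rep(1:6, each = 4))
  )
  raw <- two_way_anova(df, "value", "group", "test")
  cells <- dplyr::summarise(
    dplyr::group_by(df, group, test),
    mean = mean(value), sd = stats::sd(value), n = dplyr::n(),
    .groups = "drop"
  )
  summ <- two_way_anova_from_summary(cells)
  expect_equal(summ$table$sumsq, raw$table$sumsq, tolerance = 1e-9)
  expect_equal(summ$table$F, raw$table$F, tolerance = 1e-9)
  expect_error(two_way_anova_from_summary(dplyr::mutate(cells, n = 1)),
               "n >= 2")
})

test_that("WMW power reproduces the closed-form ARE calculation", {
  expect_equal(wmw_power(5, 1, 5, 1, 28), 0.05, tolerance = 1e-9)
  # monotone in effect size and n
  deltas <- seq(0, 2, by = 0.25)
  pw <- vapply(deltas, function(d) wmw_power(d, 1, 0, 1, 20), numeric(1))
  expect_true(all(diff(pw) > 0))
  ns <- c(5, 10, 20, 40, 80)
  pw_n <- vapply(ns, function(n) wmw_power(0.5, 1, 0, 1, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  expect_error(wmw_power(1, 0, 0, 1, 10), "positive")
})
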