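#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a staircase trajectory
#'
#' Level against trial number, with correct and incorrect responses
#' distinguished.
#'
#' @param object A `staircase_run` from [run_staircase()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot staircase_run
#' @export
autoplot.staircase_run <- function(object, ...) {
  tr <- object$trials
  tr$response <- factor(ifelse(tr$outcome == 1, "correct", "incorrect"),
                        levels = c("correct", "incorrect"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial_index, y = .data$level)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$response), size = 2) +
    ggplot2::scale_shape_manual(values = c(correct = 16, incorrect = 1)) +
    ggplot2::labs(x = "Trial", y = "Level", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Observed proportion correct per level (point area proportional to the
#' number of trials) with the fitted logistic overlaid.
#'
#' @param object A converged `pf_fit` from [fit_pf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_fit
#' @export
autoplot.pf_fit <- function(object, ...) {
  agg <- object$data
  agg$prop <- agg$k / agg$n
  rng <- range(agg$level)
  pad <- 0.1 * diff(rng)
  xs <- seq(rng[1] - pad, rng[2] + pad, length.out = 200)
  curve <- tibble::tibble(
    level = xs,
    prop = pf_evaluate(xs, object$alpha, object$beta, object$gamma,
                       object$lambda)
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$level, y = .data$prop)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    { if (isTRUE(object$converged))
        ggplot2::geom_line(data = curve, colour = "steelblue") } +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Level", y = "Proportion success", size = "Trials") +
    ggplot2::theme_minimal()
}

#' Group comparison box plot for one measure
#'
#' @param summaries Tibble of subject summaries.
#' @param measure One of the measure columns produced by
#'   [analyze_subject()] (e.g. `"det_mean_db"`, `"weight_mean_db"`,
#'   `"abs_bp_db"`, `"stereo_log2"`).
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(summaries, measure = "det_mean_db") {
  if (!measure %in% names(summaries)) {
    rlang::abort(sprintf("No column '%s' in summaries.", measure))
  }
  df <- summaries[is.finite(summaries[[measure]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data[[measure]],
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.5) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Bubble plot of an imbalance correlation matrix
#'
#' @param report A `group_report`.
#' @param dataset `"combined"` or one of the group labels.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(report, dataset = "combined") {
  stopifnot(inherits(report, "group_report"))
  cm <- report$correlations[[dataset]]
  if (is.null(cm)) rlang::abort(sprintf("No dataset '%s'.", dataset))
  cm$var1 <- factor(cm$var1, levels = unique(cm$var1))
  cm$var2 <- factor(cm$var2, levels = rev(levels(cm$var1)))
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$var1, y = .data$var2)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$rho),
                                     colour = .data$rho)) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "white",
                                    high = "firebrick", limits = c(-1, 1)) +
    ggplot2::scale_size_area(max_size = 10, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "rho", size = "|rho|",
                  title = paste("Imbalance correlations:", dataset)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
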