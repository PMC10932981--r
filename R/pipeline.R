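trial_schema <- c("subject_id", "group", "task", "condition",
                  "staircase_id", "trial_index", "level", "level_unit",
                  "outcome")

dichoptics_schema_version <- "1.0"

#' Analyse one subject's trial bundle
#'
#' Runs the full per-subject analysis chain on a tibble of trials in the
#' shared schema:
#' 1. detection trials per eye -> logistic psychometric fits -> 75%-correct
#'    thresholds (dB);
#' 2. masking trials per target eye -> fits with free slope sign ->
#'    75%-correct mask thresholds (dB);
#' 3. the resulting threshold quartet (masking targets recomputed as the
#'    measured detection threshold + 9 dB) -> two-stage gain-control fit ->
#'    gains, weights, suppression strengths;
#' 4. combination trials -> balance-point fit (50% point, dB ratio);
#' 5. stereo trials (crossed and uncrossed pooled) -> 4AFC fit ->
#'    62.5%-correct threshold (log2 arc sec and arc sec);
#' 6. the four sensory eye imbalances.
#'
#' Missing tasks yield `NA` fields (an explicit partial summary); a
#' non-convergent fit is flagged in the corresponding `*_converged` column
#' rather than silently propagated.
#'
#' @param data Tibble of one subject's trials (columns `subject_id`,
#'   `group`, `task`, `condition`, `staircase_id`, `trial_index`, `level`,
#'   `level_unit`, `outcome`).
#' @param protocol A [protocol_config()] (supplies the masking target
#'   offset and the task criteria).
#' @param consts A [gc_constants()] object.
#' @return A one-row tibble (subject summary) with thresholds, model
#'   parameters, suppression strengths, balance point, stereo thresholds,
#'   imbalances, and convergence flags.
#' @export
analyze_subject <- function(data, protocol = protocol_config(),
                            consts = gc_constants()) {
  validate_trials(data)
  sid <- unique(data$subject_id)
  grp <- unique(data$group)
  if (length(sid) != 1 || length(grp) != 1) {
    rlang::abort("`data` must contain exactly one subject.")
  }

  fit_task <- function(task, condition, gamma, criterion) {
    rows <- data[data$task == task & data$condition %in% condition, ]
    if (nrow(rows) == 0) {
      return(list(thr = NA_real_, converged = NA))
    }
    fit <- fit_pf(rows, gamma = gamma, lambda = 0)
    thr <- if (isTRUE(fit$converged)) {
      threshold_from_fit(fit, criterion)
    } else {
      NA_real_
    }
    list(thr = thr, converged = isTRUE(fit$converged))
  }

  detR <- fit_task("detection", "right", 0.5, protocol$criterion_2afc)
  detL <- fit_task("detection", "left", 0.5, protocol$criterion_2afc)
  mskR <- fit_task("masking", "target_right", 0.5, protocol$criterion_2afc)
  mskL <- fit_task("masking", "target_left", 0.5, protocol$criterion_2afc)

  gc <- list(params = NULL, converged = NA)
  thr4 <- c(detR$thr, detL$thr, mskR$thr, mskL$thr)
  if (all(is.finite(thr4)) && all(thr4 <= 0)) {
    gc <- tryCatch({
      quartet <- threshold_quartet(
        detR = db_to_rms(detR$thr), detL = db_to_rms(detL$thr),
        maskR = db_to_rms(mskR$thr), maskL = db_to_rms(mskL$thr),
        targ_offset_db = protocol$targ_offset_db
      )
      fit <- fit_gain_control(quartet, consts)
      list(params = fit$params, converged = fit$converged)
    }, error = function(e) list(params = NULL, converged = FALSE))
  }

  comb <- data[data$task == "combination", ]
  bp <- if (nrow(comb) > 0) fit_balance_point(comb) else NULL

  ste <- fit_task("stereo", c("crossed", "uncrossed"), 0.25,
                  protocol$criterion_4afc)

  p <- gc$params
  imb <- if (!is.null(p)) {
    sensory_imbalances(detR$thr, detL$thr, p,
                       if (!is.null(bp)) bp$bp else NA_real_)
  } else {
    tibble::tibble(
      threshold_imbalance = detR$thr - detL$thr,
      fusion_imbalance = if (!is.null(bp)) bp$bp else NA_real_,
      weight_imbalance = NA_real_, strength_imbalance = NA_real_,
      abs_threshold_imbalance = abs(detR$thr - detL$thr),
      abs_fusion_imbalance = abs(if (!is.null(bp)) bp$bp else NA_real_),
      abs_weight_imbalance = NA_real_, abs_strength_imbalance = NA_real_
    )
  }

  tibble::tibble(
    subject_id = sid, group = grp,
    detR_db = detR$thr, detL_db = detL$thr,
    det_mean_db = (detR$thr + detL$thr) / 2,
    maskR_db = mskR$thr, maskL_db = mskL$thr,
    GR = if (!is.null(p)) p$GR else NA_real_,
    GL = if (!is.null(p)) p$GL else NA_real_,
    WR = if (!is.null(p)) p$WR else NA_real_,
    WL = if (!is.null(p)) p$WL else NA_real_,
    weight_mean_db = if (!is.null(p)) (p$WR + p$WL) / 2 else NA_real_,
    supstrR = if (!is.null(p)) p$GL + p$WR else NA_real_,
    supstrL = if (!is.null(p)) p$GR + p$WL else NA_real_,
    strength_mean_db = if (!is.null(p)) {
      (p$GL + p$WR + p$GR + p$WL) / 2
    } else {
      NA_real_
    },
    bp_db = if (!is.null(bp)) bp$bp else NA_real_,
    abs_bp_db = if (!is.null(bp)) abs(bp$bp) else NA_real_,
    stereo_log2 = ste$thr,
    stereo_arcsec = if (is.finite(ste$thr)) {
      log2_to_arcsec(ste$thr)
    } else {
      NA_real_
    },
    !!!imb,
    det_converged = isTRUE(detR$converged) && isTRUE(detL$converged),
    mask_converged = isTRUE(mskR$converged) && isTRUE(mskL$converged),
    gc_converged = isTRUE(gc$converged),
    bp_converged = !is.null(bp) && isTRUE(bp$converged),
    stereo_converged = isTRUE(ste$converged)
  )
}

#' Analyse all subjects in a trial table
#'
#' Convenience wrapper: splits a multi-subject trial table and binds the
#' per-subject summaries.
#'
#' @inheritParams analyze_subject
#' @return A tibble of subject summaries, one row per subject.
#' @export
analyze_subjects <- function(data, protocol = protocol_config(),
                             consts = gc_constants()) {
  validate_trials(data)
  data |>
    dplyr::group_split(.data$subject_id) |>
    purrr::map(analyze_subject, protocol = protocol, consts = consts) |>
    dplyr::bind_rows()
}

measure_values <- function(summaries) {
  out <- tibble::tibble(
    subject_id = summaries$subject_id,
    group = summaries$group,
    detection = summaries$det_mean_db,
    weight = summaries$weight_mean_db,
    strength = summaries$strength_mean_db,
    abs_bp = summaries$abs_bp_db,
    stereo_4c = summaries$stereo_log2
  )
  for (cl in c("titmus_log2", "tno_log2")) {
    if (cl %in% names(summaries)) {
      out[[sub("_log2", "", cl)]] <- summaries[[cl]]
    }
  }
  out
}

imbalance_vars <- c("threshold_imbalance", "fusion_imbalance",
                    "weight_imbalance", "strength_imbalance")

# Spearman that degrades to NA (rather than an error) on < 3 complete
# pairs or constant input, for small-group report assembly.
safe_spearman <- function(x, y) {
  n_ok <- sum(stats::complete.cases(x, y))
  if (n_ok < 3) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n_ok,
                          defined = FALSE))
  }
  spearman(x, y)
}

cor_matrix_tbl <- function(df, vars) {
  grid <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(var1, var2) {
    if (var1 == var2) {
      tibble::tibble(var1 = var1, var2 = var2, rho = 1, p = 0,
                     n = sum(stats::complete.cases(df[[var1]])))
    } else {
      s <- safe_spearman(df[[var1]], df[[var2]])
      tibble::tibble(var1 = var1, var2 = var2, rho = s$rho, p = s$p,
                     n = s$n)
    }
  })
}

#' Group-level statistical battery
#'
#' Computes, from two groups of subject summaries, the complete group
#' report:
#' * descriptive statistics (mean, SD, n) per group and measure;
#' * two-sided Mann-Whitney comparisons of detection threshold, masking
#'   weight, masking strength, absolute balance point, and 4-C stereoacuity
#'   (one value per subject: eye means where applicable);
#' * the 2x3 group-by-test between-subjects ANOVA on log2 stereoacuity
#'   with Bonferroni post hocs (when clinical Titmus/TNO values are
#'   available);
#' * Spearman correlation matrices of the four *signed* sensory eye
#'   imbalances for the combined data and each group, plus correlations of
#'   the *absolute* imbalances with stereoacuity (a strong preference for
#'   either eye is what is expected to impair stereopsis);
#' * Fisher r-to-z comparisons of each imbalance-pair correlation between
#'   the two groups;
#' * Wilcoxon-Mann-Whitney power for the detection, weight, and 4-C stereo
#'   comparisons at the observed group statistics.
#'
#' @param summaries Tibble of subject summaries from [analyze_subject()] /
#'   [analyze_subjects()] (>= 2 subjects per group, exactly 2 groups).
#'   Optional columns `titmus_log2` and `tno_log2` (e.g. joined from a
#'   cohort ground-truth table) enable the three-test ANOVA.
#' @param groups Optional length-2 character: order of groups; the first is
#'   compared against the second. Defaults to `c("aging", "control")` when
#'   present, else alphabetical.
#' @param alpha Significance level used in the power calculations.
#' @return An object of class `group_report`.
#' @export
analyze_group <- function(summaries, groups = NULL, alpha = 0.05) {
  gs <- unique(summaries$group)
  if (length(gs) != 2) rlang::abort("Exactly two groups are required.")
  if (is.null(groups)) {
    groups <- if (all(c("aging", "control") %in% gs)) {
      c("aging", "control")
    } else {
      sort(gs)
    }
  }
  if (!setequal(groups, gs)) rlang::abort("`groups` must match the data.")
  counts <- table(summaries$group)
  if (any(counts < 2)) rlang::abort("Each group needs >= 2 subjects.")

  mv <- measure_values(summaries)
  measures <- setdiff(names(mv), c("subject_id", "group"))

  long <- tidyr::pivot_longer(mv, dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  descriptives <- long |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$group, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")

  tests <- purrr::map_dfr(measures, function(m) {
    x <- mv[[m]][mv$group == groups[1]]
    y <- mv[[m]][mv$group == groups[2]]
    res <- mann_whitney(x[is.finite(x)], y[is.finite(y)])
    dplyr::mutate(res, measure = m, .before = 1)
  })

  stereo_cols <- intersect(c("stereo_4c", "titmus", "tno"), measures)
  anova <- NULL
  if (length(stereo_cols) == 3) {
    stereo_long <- tidyr::pivot_longer(
      mv[, c("group", stereo_cols)], dplyr::all_of(stereo_cols),
      names_to = "test", values_to = "value"
    )
    stereo_long <- stereo_long[is.finite(stereo_long$value), ]
    anova <- two_way_anova(stereo_long, "value", "group", "test")
  }

  imb <- summaries[, c("group", imbalance_vars)]
  datasets <- c(list(combined = imb),
                stats::setNames(list(imb[imb$group == groups[1], ],
                                     imb[imb$group == groups[2], ]),
                                groups))
  correlations <- purrr::map(datasets, cor_matrix_tbl, vars = imbalance_vars)

  abs_vars <- paste0("abs_", imbalance_vars)
  stereo_measures <- intersect(c("stereo_4c", "titmus", "tno"), measures)
  abs_df <- dplyr::left_join(summaries[, c("subject_id", "group", abs_vars)],
                             mv[, c("subject_id", stereo_measures)],
                             by = "subject_id")
  stereo_correlations <- purrr::map(
    c(list(combined = abs_df),
      stats::setNames(list(abs_df[abs_df$group == groups[1], ],
                           abs_df[abs_df$group == groups[2], ]), groups)),
    function(d) {
      grid <- expand.grid(imbalance = abs_vars, stereo = stereo_measures,
                          stringsAsFactors = FALSE)
      purrr::pmap_dfr(grid, function(imbalance, stereo) {
        s <- safe_spearman(d[[imbalance]], d[[stereo]])
        tibble::tibble(imbalance = imbalance, stereo = stereo,
                       rho = s$rho, p = s$p, n = s$n)
      })
    }
  )

  pairs <- utils::combn(imbalance_vars, 2, simplify = FALSE)
  fisher <- purrr::map_dfr(pairs, function(pr) {
    c1 <- correlations[[groups[1]]]
    c2 <- correlations[[groups[2]]]
    r1 <- c1$rho[c1$var1 == pr[1] & c1$var2 == pr[2]]
    r2 <- c2$rho[c2$var1 == pr[1] & c2$var2 == pr[2]]
    n1 <- c1$n[c1$var1 == pr[1] & c1$var2 == pr[2]]
    n2 <- c2$n[c2$var1 == pr[1] & c2$var2 == pr[2]]
    if (!is.finite(r1) || !is.finite(r2) || abs(r1) >= 1 || abs(r2) >= 1 ||
        n1 <= 3 || n2 <= 3) {
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], z = NA_real_,
                            p = NA_real_, rho1 = r1, rho2 = r2,
                            n1 = n1, n2 = n2))
    }
    res <- fisher_compare(r1, n1, r2, n2)
    dplyr::mutate(res, var1 = pr[1], var2 = pr[2], .before = 1)
  })

  power_measures <- intersect(c("detection", "weight", "stereo_4c"),
                              measures)
  power <- purrr::map_dfr(power_measures, function(m) {
    d1 <- descriptives[descriptives$measure == m &
                         descriptives$group == groups[1], ]
    d2 <- descriptives[descriptives$measure == m &
                         descriptives$group == groups[2], ]
    n <- min(d1$n, d2$n)
    tibble::tibble(
      measure = m,
      power = wmw_power(d1$mean, d1$sd, d2$mean, d2$sd, n, alpha)
    )
  })

  structure(
    list(groups = groups,
         n = as.list(stats::setNames(as.integer(counts[groups]), groups)),
         descriptives = descriptives,
         tests = tests,
         anova = anova,
         correlations = correlations,
         stereo_correlations = stereo_correlations,
         fisher = fisher,
         power = power,
         alpha = alpha,
         schema_version = dichoptics_schema_version),
    class = "group_report"
  )
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("Group report: %s (n = %d) vs %s (n = %d)\n",
              x$groups[1], x$n[[x$groups[1]]],
              x$groups[2], x$n[[x$groups[2]]]))
  cat("\nMann-Whitney comparisons:\n")
  print(as.data.frame(x$tests), row.names = FALSE, digits = 3)
  if (!is.null(x$anova)) {
    cat("\nStereo 2x3 ANOVA:\n")
    print(as.data.frame(x$anova$table), row.names = FALSE, digits = 4)
  }
  cat("\nPower (Wilcoxon-Mann-Whitney, ARE method):\n")
  print(as.data.frame(x$power), row.names = FALSE, digits = 3)
  invisible(x)
}
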