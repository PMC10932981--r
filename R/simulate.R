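#' Protocol configuration for the four-task battery
#'
#' Defaults mirror the measurement protocol the analysis expects:
#' * detection: pair of per-eye 3-down-1-up staircases, 3 dB steps from
#'   -12 dB, 9 reversals or 120 trials, two repetitions;
#' * dichoptic masking: per-target-eye 3-up-1-down staircases on the mask
#'   contrast (correct responses *increase* the mask), 3 dB steps from
#'   -36 dB, target fixed 9 dB above that eye's measured detection
#'   threshold;
#' * binocular combination: seven interocular contrast ratios
#'   (1:4 ... 4:1, i.e. 0, +/-3.01, +/-6.02, +/-12.04 dB), 20 trials per
#'   ratio per repetition, 45% base contrast;
#' * stereo (4-C, 4AFC): pair of crossed/uncrossed 2-down-1-up staircases,
#'   multiplicative sqrt(2) steps (additive 0.5 in log2 arc sec) from
#'   512 arc sec, 9 reversals or 30 trials.
#'
#' Contrast levels are clamped at 0 dB (100% contrast) and disparity at
#' 1 arc sec (0 log2 units).
#'
#' @param n_reps Repetitions of every task (pooled before fitting).
#' @param targ_offset_db Masking target offset above the detection
#'   threshold, dB.
#' @param base_contrast Base contrast of the combination gratings (linear).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(n_reps = 2, targ_offset_db = 9,
                            base_contrast = 0.45) {
  structure(
    list(
      n_reps = as.integer(n_reps),
      targ_offset_db = targ_offset_db,
      base_contrast = base_contrast,
      detection = staircase_config(
        n_consecutive = 3, step = 3, initial_level = -12,
        correct_direction = -1, max_reversals = 9, max_trials = 120,
        max_level = 0
      ),
      masking = staircase_config(
        n_consecutive = 3, step = 3, initial_level = -36,
        correct_direction = +1, max_reversals = 9, max_trials = 120,
        max_level = 0
      ),
      stereo = staircase_config(
        n_consecutive = 2, step = 0.5, initial_level = log2(512),
        correct_direction = -1, max_reversals = 9, max_trials = 30,
        min_level = 0
      ),
      ratios_db = ratio_to_db(c(1 / 4, 1 / 2, 1 / sqrt(2), 1,
                                sqrt(2), 2, 4)),
      n_per_ratio = 20L,
      criterion_2afc = 0.75,
      criterion_4afc = 0.625
    ),
    class = "protocol_config"
  )
}

#' Write or read a protocol configuration as YAML
#'
#' The full protocol (staircase rules, steps, starting levels, caps,
#' repetition counts, ratio set, criteria) round-trips through a plain
#' YAML document, so a measurement configuration can live beside the data
#' it produced.
#'
#' @param protocol A [protocol_config()].
#' @param path File path.
#' @return `write_protocol_config()` the path, invisibly;
#'   `read_protocol_config()` a validated `protocol_config`.
#' @export
write_protocol_config <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_config"))
  doc <- list(
    n_reps = protocol$n_reps,
    targ_offset_db = protocol$targ_offset_db,
    base_contrast = protocol$base_contrast,
    n_per_ratio = protocol$n_per_ratio,
    ratios_db = protocol$ratios_db,
    criterion_2afc = protocol$criterion_2afc,
    criterion_4afc = protocol$criterion_4afc,
    staircases = lapply(protocol[c("detection", "masking", "stereo")],
                        unclass)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("n_reps", "targ_offset_db", "base_contrast", "staircases")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Config '%s' is missing field(s): %s", path,
                         paste(missing, collapse = ", ")))
  }
  pc <- protocol_config(n_reps = doc$n_reps,
                        targ_offset_db = doc$targ_offset_db,
                        base_contrast = doc$base_contrast)
  for (task in c("detection", "masking", "stereo")) {
    sc <- doc$staircases[[task]]
    if (is.null(sc)) {
      rlang::abort(sprintf("Config '%s' lacks staircase '%s'.", path, task))
    }
    pc[[task]] <- staircase_config(
      n_consecutive = sc$n_consecutive, step = sc$step,
      initial_level = sc$initial_level,
      correct_direction = sc$correct_direction,
      max_reversals = sc$max_reversals, max_trials = sc$max_trials,
      min_level = if (is.null(sc$min_level)) -Inf else sc$min_level,
      max_level = if (is.null(sc$max_level)) Inf else sc$max_level
    )
  }
  if (!is.null(doc$ratios_db)) pc$ratios_db <- as.numeric(doc$ratios_db)
  if (!is.null(doc$n_per_ratio)) pc$n_per_ratio <- as.integer(doc$n_per_ratio)
  if (!is.null(doc$criterion_2afc)) pc$criterion_2afc <- doc$criterion_2afc
  if (!is.null(doc$criterion_4afc)) pc$criterion_4afc <- doc$criterion_4afc
  pc
}

#' Per-eye contrasts realising an interocular contrast ratio
#'
#' Both eyes' contrasts are scaled symmetrically about the base contrast so
#' that their ratio equals the requested value: for ratio `r = cL/cR`,
#' `cL = base * sqrt(r)` and `cR = base / sqrt(r)`. At a 45% base, a 4:1
#' ratio therefore shows 90% contrast to one eye and 22.5% to the other.
#'
#' @param ratio_db Interocular ratio `20*log10(cL/cR)` in dB (vectorised).
#' @param base Base (geometric mean) linear contrast.
#' @return A tibble with `ratio_db`, `c_left`, `c_right` (linear contrast).
#' @export
#' @examples
#' combination_contrasts(ratio_to_db(4)) # 0.9 and 0.225
combination_contrasts <- function(ratio_db, base = 0.45) {
  r <- db_to_ratio(ratio_db)
  tibble::tibble(
    ratio_db = ratio_db,
    c_left = base * sqrt(r),
    c_right = base / sqrt(r)
  )
}

# Pool detection trials for one eye and return the 75%-correct threshold
# (dB). Falls back to the mean of late reversal-free levels when the
# psychometric fit cannot converge (degenerate simulated runs).
detection_threshold_from_trials <- function(trials, criterion = 0.75) {
  fit <- fit_pf(trials, gamma = 0.5, lambda = 0)
  thr <- threshold_from_fit(fit, criterion)
  lv <- trials$level
  # an estimate far outside the sampled range is an extrapolation
  # artifact; fall back to the late-trial mean (the staircase's own
  # convergence region) when that happens
  if (!is.finite(thr) || thr < min(lv) - 6 || thr > max(lv) + 6) {
    thr <- mean(utils::tail(lv, max(6L, length(lv) %/% 2L)))
  }
  thr
}

#' Simulate the full four-task protocol for one observer
#'
#' Runs the complete battery against a simulated observer: interleaved
#' per-eye detection staircases, a psychometric fit to set each eye's fixed
#' masking target (measured threshold + 9 dB, exactly as the analysis
#' recomputes it), interleaved masking staircases, the fixed-ratio
#' binocular combination block, and interleaved crossed/uncrossed stereo
#' staircases; everything repeated `n_reps` times.
#'
#' Randomness (interleaving and responses) is drawn from the session RNG;
#' seed upstream (e.g. `withr::with_seed()`) for reproducibility.
#'
#' @param observer A `sim_observer` from [make_observer()].
#' @param protocol A [protocol_config()].
#' @param subject_id,group Identifiers stamped on every trial row.
#' @return A tibble of trials in the shared schema: `subject_id`, `group`,
#'   `task`, `condition`, `staircase_id`, `trial_index`, `level`,
#'   `level_unit`, `outcome`.
#' @export
simulate_full_protocol <- function(observer, protocol = protocol_config(),
                                   subject_id = "s01", group = "control") {
  stopifnot(inherits(observer, "sim_observer"))
  pc <- protocol
  out <- list()

  # --- detection: pair of per-eye staircases, interleaved, n_reps times
  det <- lapply(seq_len(pc$n_reps), function(rep) {
    res <- run_interleaved(
      configs = list(R = pc$detection, L = pc$detection),
      responders = list(
        R = function(lv) observer$respond_detect(lv, "R"),
        L = function(lv) observer$respond_detect(lv, "L")
      )
    )
    res$trials$rep <- rep
    res$trials
  })
  det <- do.call(rbind, det)
  out$detection <- data.frame(
    task = "detection",
    condition = ifelse(det$staircase_id == "R", "right", "left"),
    staircase_id = paste0("det_", det$staircase_id, "_rep", det$rep),
    trial_index = det$trial_index,
    level = det$level,
    level_unit = "dB",
    outcome = det$outcome
  )

  # measured thresholds fix the masking targets (threshold + offset)
  detR_hat <- detection_threshold_from_trials(
    out$detection[out$detection$condition == "right", ])
  detL_hat <- detection_threshold_from_trials(
    out$detection[out$detection$condition == "left", ])
  targR_db <- min(detR_hat + pc$targ_offset_db, 0)
  targL_db <- min(detL_hat + pc$targ_offset_db, 0)

  # --- dichoptic masking: per-target-eye mask staircases
  msk <- lapply(seq_len(pc$n_reps), function(rep) {
    res <- run_interleaved(
      configs = list(R = pc$masking, L = pc$masking),
      responders = list(
        R = function(lv) observer$respond_mask(lv, "R", targR_db),
        L = function(lv) observer$respond_mask(lv, "L", targL_db)
      )
    )
    res$trials$rep <- rep
    res$trials
  })
  msk <- do.call(rbind, msk)
  out$masking <- data.frame(
    task = "masking",
    condition = ifelse(msk$staircase_id == "R", "target_right",
                       "target_left"),
    staircase_id = paste0("mask_", msk$staircase_id, "_rep", msk$rep),
    trial_index = msk$trial_index,
    level = msk$level,
    level_unit = "dB",
    outcome = msk$outcome
  )

  # --- binocular combination: fixed ratios, Bernoulli draws per trial
  comb <- lapply(seq_len(pc$n_reps), function(rep) {
    levels <- rep(pc$ratios_db, each = pc$n_per_ratio)
    levels <- sample(levels) # randomly ordered presentation
    p <- observer$p_left_dominant(levels)
    data.frame(
      task = "combination",
      condition = "fused",
      staircase_id = paste0("comb_rep", rep),
      trial_index = seq_along(levels),
      level = levels,
      level_unit = "dB_ratio",
      outcome = as.integer(stats::runif(length(levels)) < p)
    )
  })
  out$combination <- do.call(rbind, comb)

  # --- stereo: crossed/uncrossed staircase pair (same generating alpha)
  ste <- lapply(seq_len(pc$n_reps), function(rep) {
    res <- run_interleaved(
      configs = list(crossed = pc$stereo, uncrossed = pc$stereo),
      responders = list(
        crossed = observer$respond_stereo,
        uncrossed = observer$respond_stereo
      )
    )
    res$trials$rep <- rep
    res$trials
  })
  ste <- do.call(rbind, ste)
  out$stereo <- data.frame(
    task = "stereo",
    condition = ste$staircase_id,
    staircase_id = paste0("stereo_", ste$staircase_id, "_rep", ste$rep),
    trial_index = ste$trial_index,
    level = ste$level,
    level_unit = "log2_arcsec",
    outcome = ste$outcome
  )

  all <- do.call(rbind, out)
  all <- cbind(data.frame(subject_id = subject_id, group = group), all)
  rownames(all) <- NULL
  tibble::as_tibble(all)
}

#' Simulate trial data for a whole cohort
#'
#' Draws a cohort ground-truth table and runs the full protocol for every
#' subject.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [protocol_config()].
#' @param seed Optional integer seed covering both the cohort draw and all
#'   trial-level randomness.
#' @param consts A [gc_constants()] object.
#' @return List with `truth` (the [generate_cohort()] tibble) and `trials`
#'   (one tibble of all subjects' trials in the shared schema).
#' @export
simulate_cohort <- function(spec, protocol = protocol_config(), seed = NULL,
                            consts = gc_constants()) {
  run <- function() {
    truth <- generate_cohort(spec)
    trials <- purrr::map(seq_len(nrow(truth)), function(i) {
      row <- truth[i, ]
      obs <- observer_from_row(row, spreads = spec$spreads,
                               lapse = spec$lapse, consts = consts)
      simulate_full_protocol(obs, protocol,
                             subject_id = row$subject_id,
                             group = row$group)
    })
    list(truth = truth, trials = dplyr::bind_rows(trials))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
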