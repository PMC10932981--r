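#' Ground-truth specification of a simulated observer
#'
#' Holds the generating values for one simulated subject: per-eye monocular
#' detection thresholds (dB contrast), per-eye received masking weights
#' (dB), the binocular balance point (dB ratio, left/right axis), the 4-C
#' stereoacuity threshold (log2 arc seconds), the psychometric spreads for
#' each task, and a lapse rate. Spreads are logistic scale parameters on
#' the task axis (the slope is `1/spread`).
#'
#' @param det_thr_db Length-2 numeric, named or ordered `(R, L)`: detection
#'   thresholds in dB contrast.
#' @param weight_db Length-2 numeric `(WR, WL)`: received suppression
#'   weights in dB.
#' @param bp_db Balance point in dB (ratio axis `20*log10(cL/cR)`).
#' @param stereo_log2_alpha 4-C stereo threshold, log2 arc seconds.
#' @param spreads Named list of psychometric spreads: `detection` and
#'   `masking` in dB, `bp` in dB ratio, `stereo` in log2 units.
#' @param lapse Lapse rate applied to forced-choice tasks.
#' @return An `observer_spec` object.
#' @export
observer_spec <- function(det_thr_db, weight_db, bp_db, stereo_log2_alpha,
                          spreads = default_spreads(), lapse = 0) {
  stopifnot(length(det_thr_db) == 2, length(weight_db) == 2)
  if (any(!is.finite(c(det_thr_db, weight_db, bp_db, stereo_log2_alpha)))) {
    rlang::abort("Observer parameters must be finite.")
  }
  if (any(unlist(spreads) <= 0)) rlang::abort("Spreads must be > 0.")
  check_rates(0, lapse)
  structure(
    list(detR_db = det_thr_db[[1]], detL_db = det_thr_db[[2]],
         WR_db = weight_db[[1]], WL_db = weight_db[[2]],
         bp_db = bp_db, stereo_log2_alpha = stereo_log2_alpha,
         spreads = spreads, lapse = lapse),
    class = "observer_spec"
  )
}

#' Default psychometric spreads for simulated observers
#'
#' Logistic scale parameters chosen so that the adaptive staircases
#' converge comfortably within their trial budgets: 2 dB for detection and
#' masking, 3 dB for the balance-point task, and 0.5 log2 units for stereo.
#'
#' @return Named list of spreads.
#' @export
default_spreads <- function() {
  list(detection = 2, masking = 2, bp = 3, stereo = 0.5)
}

# location parameter such that p(threshold) == criterion for a logistic
# with guess g, lapse l, slope beta
pf_alpha_for <- function(threshold, beta, gamma, lambda, criterion) {
  threshold + log((1 - gamma - lambda) / (criterion - gamma) - 1) / beta
}

#' Instantiate a simulated observer from its specification
#'
#' Derives the observer's internal gain-control parameters by inverting the
#' two-stage model: input gains from the detection thresholds
#' (`g = det_root / threshold`) and linear weights from the dB weights.
#' Response probabilities are logistic on each task's axis, anchored so
#' that the probability correct equals the task criterion (75% for the
#' single-interval tasks, 62.5% for 4AFC stereo) exactly at the
#' model-implied threshold, and so that the probability of a
#' left-eye-dominant report is exactly 1/2 at the generating balance point.
#'
#' @param spec An [observer_spec()].
#' @param consts A [gc_constants()] object.
#' @return An object of class `sim_observer`: the spec plus derived model
#'   parameters and response-probability functions `p_detect(level, eye)`,
#'   `p_mask_correct(level, target_eye, targ_db)`, `p_left_dominant(level)`,
#'   `p_stereo_correct(level)` and Bernoulli samplers `respond_*` drawing
#'   from the session RNG.
#' @export
make_observer <- function(spec, consts = gc_constants()) {
  stopifnot(inherits(spec, "observer_spec"))
  gR <- consts$det_root / db_to_rms(spec$detR_db)
  gL <- consts$det_root / db_to_rms(spec$detL_db)
  wR <- db_to_rms(spec$WR_db)
  wL <- db_to_rms(spec$WL_db)
  lapse <- spec$lapse
  sp <- spec$spreads

  # guard: a +9 dB masking target must be above its own threshold so that a
  # positive mask threshold exists for any weight
  probe <- consts$det_root * 10^(9 / 20)
  if (probe^consts$m / consts$resp_unit_root - consts$S - probe <= 0) {
    rlang::abort("Degenerate constants: masking target not suprathreshold.")
  }

  mask_thr_db <- function(target_eye, targ_db) {
    if (target_eye == "R") {
      rms_to_db(mask_threshold(gR, gL, wR, db_to_rms(targ_db), consts))
    } else {
      rms_to_db(mask_threshold(gL, gR, wL, db_to_rms(targ_db), consts))
    }
  }

  beta_det <- 1 / sp$detection
  a_det <- c(R = pf_alpha_for(spec$detR_db, beta_det, 0.5, lapse, 0.75),
             L = pf_alpha_for(spec$detL_db, beta_det, 0.5, lapse, 0.75))
  beta_mask <- -1 / sp$masking # performance falls as the mask strengthens
  mask_alpha_cache <- new.env(parent = emptyenv())
  # NA alpha marks a target at or below that eye's own detection
  # threshold: the observer cannot see it and performs at chance for any
  # mask contrast (the downstream psychometric fit then flags the
  # condition as non-convergent instead of inventing a threshold)
  mask_alpha <- function(target_eye, targ_db) {
    key <- paste0(target_eye, "@", format(targ_db, digits = 12))
    if (is.null(mask_alpha_cache[[key]])) {
      thr <- tryCatch(mask_thr_db(target_eye, targ_db),
                      error = function(e) NA_real_)
      mask_alpha_cache[[key]] <- if (is.na(thr)) {
        NA_real_
      } else {
        pf_alpha_for(thr, beta_mask, 0.5, lapse, 0.75)
      }
    }
    mask_alpha_cache[[key]]
  }
  beta_st <- 1 / sp$stereo
  a_st <- pf_alpha_for(spec$stereo_log2_alpha, beta_st, 0.25, lapse, 0.625)

  span2 <- 0.5 - lapse
  span4 <- 0.75 - lapse
  p_detect <- function(level, eye) {
    0.5 + span2 / (1 + exp(-beta_det * (level - a_det[[eye]])))
  }
  p_mask_correct <- function(level, target_eye, targ_db) {
    a <- mask_alpha(target_eye, targ_db)
    if (is.na(a)) return(rep(0.5, length(level))) # invisible target
    0.5 + span2 / (1 + exp(-beta_mask * (level - a)))
  }
  beta_bp <- 1 / sp$bp
  p_left_dominant <- function(level) {
    1 / (1 + exp(-beta_bp * (level - spec$bp_db)))
  }
  p_stereo_correct <- function(level) {
    0.25 + span4 / (1 + exp(-beta_st * (level - a_st)))
  }

  structure(
    list(spec = spec, consts = consts,
         gR = gR, gL = gL, wR = wR, wL = wL,
         mask_thr_db = mask_thr_db,
         p_detect = p_detect,
         p_mask_correct = p_mask_correct,
         p_left_dominant = p_left_dominant,
         p_stereo_correct = p_stereo_correct,
         respond_detect = function(level, eye) {
           stats::runif(1) < p_detect(level, eye)
         },
         respond_mask = function(level, target_eye, targ_db) {
           stats::runif(1) < p_mask_correct(level, target_eye, targ_db)
         },
         respond_stereo = function(level) {
           stats::runif(1) < p_stereo_correct(level)
         }),
    class = "sim_observer"
  )
}

#' Specification of a simulated cohort
#'
#' Group-level generative distributions for a cohort of simulated
#' observers. The defaults are the printed group statistics of the study
#' the package's validation suite emulates: 28 subjects per group;
#' detection thresholds -38.3 +/- 3.6 dB (aging) vs -44.0 +/- 3.6 dB
#' (control); masking weights -7.9 +/- 3.6 vs -11.8 +/- 2.3 dB; mean
#' absolute balance point 2.8 +/- 2.4 vs 1.7 +/- 1.3 dB (generated as a
#' zero-mean Gaussian with matching mean absolute value); 4-C stereoacuity
#' 6.3 +/- 1.0 vs 5.5 +/- 0.7 log2 arc sec, with Titmus and TNO drawn from
#' their own printed distributions. The interocular (eye-to-eye) spread of
#' detection thresholds and weights is not printed; it defaults to a 2 dB
#' SD of the right-minus-left difference.
#'
#' @param group `"aging"` or `"control"` (any label is allowed; defaults
#'   are filled for these two).
#' @param n Number of subjects.
#' @param det_mean,det_sd Group mean/SD of the subject-mean detection
#'   threshold (dB).
#' @param weight_mean,weight_sd Group mean/SD of the subject-mean masking
#'   weight (dB).
#' @param interocular_sd SD of the right-minus-left difference for both
#'   detection thresholds and weights (dB).
#' @param abs_bp_mean Printed mean absolute balance point (dB); the signed
#'   balance point is drawn Normal(0, sigma) with
#'   `sigma = abs_bp_mean / sqrt(2/pi)` so the half-normal mean matches.
#' @param stereo_mean,stereo_sd 4-C log2 stereoacuity mean/SD.
#' @param titmus_mean,titmus_sd,tno_mean,tno_sd Clinical-test log2
#'   stereoacuity distributions (drawn directly; plate administration is
#'   not simulated).
#' @param spreads,lapse Passed to every [observer_spec()].
#' @param gain_weight_cor Correlation between a subject's mean input gain
#'   (in dB; equivalently minus the mean detection threshold) and mean
#'   masking weight. The default is solved from each group's printed
#'   masking-strength SD (strength = contralateral gain + received
#'   weight): `rho = (sd_str^2 - sd_det^2 - sd_w^2) / (2 sd_det sd_w)`,
#'   giving -0.413 (aging, strength SD 3.9) and -0.319 (control, strength
#'   SD 3.6). Independent draws would inflate the strength SD to 5.1/4.3.
#' @param imbalance_cor Optional 3x3 correlation matrix injecting
#'   correlations between (threshold difference, weight difference,
#'   balance point); identity (independence) by default.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(group = c("aging", "control"), n = 28,
                        det_mean = NULL, det_sd = 3.6,
                        weight_mean = NULL, weight_sd = NULL,
                        interocular_sd = 2,
                        abs_bp_mean = NULL,
                        stereo_mean = NULL, stereo_sd = NULL,
                        titmus_mean = NULL, titmus_sd = NULL,
                        tno_mean = NULL, tno_sd = NULL,
                        spreads = default_spreads(), lapse = 0,
                        gain_weight_cor = NULL, imbalance_cor = NULL) {
  group <- match.arg(group)
  defaults <- list(
    aging = list(det_mean = -38.3, weight_mean = -7.9, weight_sd = 3.6,
                 abs_bp_mean = 2.8, stereo_mean = 6.3, stereo_sd = 1.0,
                 titmus_mean = 5.4, titmus_sd = 0.8,
                 tno_mean = 7.1, tno_sd = 1.1,
                 gain_weight_cor = (3.9^2 - 3.6^2 - 3.6^2) / (2 * 3.6 * 3.6)),
    control = list(det_mean = -44.0, weight_mean = -11.8, weight_sd = 2.3,
                   abs_bp_mean = 1.7, stereo_mean = 5.5, stereo_sd = 0.7,
                   titmus_mean = 5.0, titmus_sd = 1.0,
                   tno_mean = 6.3, tno_sd = 0.8,
                   gain_weight_cor = (3.6^2 - 3.6^2 - 2.3^2) / (2 * 3.6 * 2.3))
  )[[group]]
  pick <- function(x, d) if (is.null(x)) d else x
  spec <- list(
    group = group, n = as.integer(n),
    det_mean = pick(det_mean, defaults$det_mean), det_sd = det_sd,
    weight_mean = pick(weight_mean, defaults$weight_mean),
    weight_sd = pick(weight_sd, defaults$weight_sd),
    interocular_sd = interocular_sd,
    abs_bp_mean = pick(abs_bp_mean, defaults$abs_bp_mean),
    stereo_mean = pick(stereo_mean, defaults$stereo_mean),
    stereo_sd = pick(stereo_sd, defaults$stereo_sd),
    titmus_mean = pick(titmus_mean, defaults$titmus_mean),
    titmus_sd = pick(titmus_sd, defaults$titmus_sd),
    tno_mean = pick(tno_mean, defaults$tno_mean),
    tno_sd = pick(tno_sd, defaults$tno_sd),
    spreads = spreads, lapse = lapse,
    gain_weight_cor = pick(gain_weight_cor, defaults$gain_weight_cor),
    imbalance_cor = imbalance_cor
  )
  sds <- c(spec$det_sd, spec$weight_sd, spec$interocular_sd,
           spec$stereo_sd, spec$titmus_sd, spec$tno_sd)
  if (spec$n < 1 || any(sds < 0) || spec$abs_bp_mean < 0) {
    rlang::abort("Cohort spec requires n >= 1 and non-negative SDs.")
  }
  if (abs(spec$gain_weight_cor) > 1) {
    rlang::abort("`gain_weight_cor` must lie in [-1, 1].")
  }
  structure(spec, class = "cohort_spec")
}

#' Draw a cohort of simulated observers
#'
#' Draws per-subject generating parameters from the cohort distributions:
#' Gaussian fields, a zero-mean Gaussian signed balance point (so its
#' absolute value is half-normal with the printed mean), and a
#' gain-weight correlation calibrated to the group's derived
#' masking-strength SD (see [cohort_spec()]). Optionally, `imbalance_cor`
#' correlates the threshold difference, weight difference, and balance
#' point.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A tibble (ground-truth table), one row per subject: `subject_id`,
#'   `group`, `detR_db`, `detL_db`, `WR_db`, `WL_db`, `bp_db`,
#'   `stereo_log2`, `titmus_log2`, `tno_log2`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  draw <- function() {
    n <- spec$n
    bp_sigma <- spec$abs_bp_mean / sqrt(2 / pi)
    if (is.null(spec$imbalance_cor)) {
      d_thr <- stats::rnorm(n, 0, spec$interocular_sd)
      d_w <- stats::rnorm(n, 0, spec$interocular_sd)
      bp <- stats::rnorm(n, 0, bp_sigma)
    } else {
      R <- spec$imbalance_cor
      stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
      sds <- c(spec$interocular_sd, spec$interocular_sd, bp_sigma)
      Sigma <- R * (sds %o% sds)
      z <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = Sigma)
      d_thr <- z[, 1]; d_w <- z[, 2]; bp <- z[, 3]
    }
    # gain (in dB) is minus the detection threshold up to a constant, so a
    # gain-weight correlation of rho is a det-weight correlation of -rho
    rho_dw <- -spec$gain_weight_cor
    z1 <- stats::rnorm(n)
    z2 <- rho_dw * z1 + sqrt(1 - rho_dw^2) * stats::rnorm(n)
    det_mid <- spec$det_mean + spec$det_sd * z1
    w_mid <- spec$weight_mean + spec$weight_sd * z2
    tibble::tibble(
      subject_id = sprintf("%s_%02d", spec$group, seq_len(n)),
      group = spec$group,
      detR_db = det_mid + d_thr / 2,
      detL_db = det_mid - d_thr / 2,
      WR_db = w_mid + d_w / 2,
      WL_db = w_mid - d_w / 2,
      bp_db = bp,
      stereo_log2 = stats::rnorm(n, spec$stereo_mean, spec$stereo_sd),
      titmus_log2 = stats::rnorm(n, spec$titmus_mean, spec$titmus_sd),
      tno_log2 = stats::rnorm(n, spec$tno_mean, spec$tno_sd)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Turn a ground-truth row into an observer
#'
#' @param row One row of a [generate_cohort()] tibble.
#' @param spreads,lapse Psychometric spreads and lapse rate.
#' @param consts A [gc_constants()] object.
#' @return A `sim_observer`.
#' @export
observer_from_row <- function(row, spreads = default_spreads(), lapse = 0,
                              consts = gc_constants()) {
  make_observer(
    observer_spec(
      det_thr_db = c(row$detR_db, row$detL_db),
      weight_db = c(row$WR_db, row$WL_db),
      bp_db = row$bp_db,
      stereo_log2_alpha = row$stereo_log2,
      spreads = spreads, lapse = lapse
    ),
    consts = consts
  )
}
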