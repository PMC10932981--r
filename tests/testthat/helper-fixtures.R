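# Shared fixtures: everything is generated in code at test time.

# Forward-generate a noiseless threshold quartet from known parameters.
quartet_from_params <- function(gR, gL, wR, wL, consts = gc_constants(),
                                targ_offset_db = 9) {
  detR <- detection_threshold(gR, consts)
  detL <- detection_threshold(gL, consts)
  targR <- detR * 10^(targ_offset_db / 20)
  targL <- detL * 10^(targ_offset_db / 20)
  maskR <- mask_threshold(gR, gL, wR, targR, consts)
  maskL <- mask_threshold(gL, gR, wL, targL, consts)
  threshold_quartet(detR, detL, maskR, maskL,
                    targ_offset_db = targ_offset_db)
}

# Random plausible generating parameters (dB gains around typical
# observers, weights well below 0 dB).
random_params_db <- function() {
  list(GR = stats::runif(1, 44, 58), GL = stats::runif(1, 44, 58),
       WR = stats::runif(1, -16, -5), WL = stats::runif(1, -16, -5))
}

# Bernoulli trials from a known logistic observer.
simulate_pf_trials <- function(n_per_level, levels, alpha, beta,
                               gamma = 0.5, lambda = 0) {
  lv <- rep(levels, each = n_per_level)
  p <- gamma + (1 - gamma - lambda) / (1 + exp(-beta * (lv - alpha)))
  tibble::tibble(level = lv, outcome = as.integer(stats::runif(length(lv)) < p))
}

# A small standard observer for pipeline tests.
standard_observer_spec <- function() {
  observer_spec(det_thr_db = c(-40, -42), weight_db = c(-9, -11),
                bp_db = 1.5, stereo_log2_alpha = 6.0)
}

# Stationary logistic respondent for staircase simulations.
logistic_respondent <- function(alpha, spread, gamma = 0.5,
                                decreasing = FALSE) {
  beta <- if (decreasing) -1 / spread else 1 / spread
  function(lv) {
    stats::runif(1) < gamma + (1 - gamma) / (1 + exp(-beta * (lv - alpha)))
  }
}

# Mean percent correct over the final half of each run, averaged over
# `nrun` staircase runs against a stationary observer.
mean_final_half_pc <- function(config, respond_factory, nrun) {
  pcs <- numeric(nrun)
  for (r in seq_len(nrun)) {
    run <- run_staircase(config, respond_factory())
    oc <- run$trials$outcome
    pcs[r] <- mean(oc[(length(oc) %/% 2 + 1):length(oc)])
  }
  mean(pcs)
}
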