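consts <- gc_constants()

test_that("observer response probabilities are anchored at task criteria", {
  spec <- standard_observer_spec()
  obs <- make_observer(spec, consts)
  expect_equal(obs$p_detect(-40, "R"), 0.75)
  expect_equal(obs$p_detect(-42, "L"), 0.75)
  expect_equal(obs$p_left_dominant(1.5), 0.5)
  expect_equal(obs$p_stereo_correct(6.0), 0.625)
  # at the model-implied mask threshold given the protocol target,
  # percent correct equals the 75% criterion
  targR <- -40 + 9
  thrR <- obs$mask_thr_db("R", targR)
  expect_equal(obs$p_mask_correct(thrR, "R", targR), 0.75)
  # anchoring survives a non-zero lapse rate
  spec_l <- observer_spec(c(-40, -42), c(-9, -11), 1.5, 6.0, lapse = 0.02)
  obs_l <- make_observer(spec_l, consts)
  expect_equal(obs_l$p_detect(-40, "R"), 0.75)
  expect_equal(obs_l$p_stereo_correct(6.0), 0.625)
})

test_that("observer internals invert the gain-control model", {
  spec <- standard_observer_spec()
  obs <- make_observer(spec, consts)
  expect_equal(20 * log10(detection_threshold(obs$gR, consts)), -40,
               tolerance = 1e-9)
  expect_equal(20 * log10(obs$wR), -9, tolerance = 1e-12)
  expect_error(observer_spec(c(-40, -42), c(-9, -11), 1.5, 6.0,
                             spreads = list(detection = -1, masking = 2,
                                            bp = 3, stereo = 0.5)),
               "Spreads")
})

test_that("cohort draws are seeded and match the generating distributions", {
  spec <- cohort_spec("aging", n = 2000)
  c1 <- generate_cohort(spec, seed = 99)
  c2 <- generate_cohort(spec, seed = 99)
  expect_identical(c1, c2)
  det_mean <- mean((c1$detR_db + c1$detL_db) / 2)
  expect_lt(abs(det_mean - (-38.3)), 0.2)
  w_mean <- mean((c1$WR_db + c1$WL_db) / 2)
  expect_lt(abs(w_mean - (-7.9)), 0.25)
  # |BP| is half-normal with the printed mean
  expect_lt(abs(mean(abs(c1$bp_db)) - 2.8), 0.15)
  expect_lt(abs(mean(c1$stereo_log2) - 6.3), 0.1)
})

test_that("gain-weight correlation reproduces the printed strength spread", {
  c1 <- generate_cohort(cohort_spec("aging", n = 5000), seed = 100)
  G <- 20 * log10(consts$det_root) - (c1$detR_db + c1$detL_db) / 2
  W <- (c1$WR_db + c1$WL_db) / 2
  expect_lt(abs(stats::sd(G + W) - 3.9), 0.3)
  c2 <- generate_cohort(cohort_spec("control", n = 5000), seed = 100)
  G2 <- 20 * log10(consts$det_root) - (c2$detR_db + c2$detL_db) / 2
  W2 <- (c2$WR_db + c2$WL_db) / 2
  expect_lt(abs(stats::sd(G2 + W2) - 3.6), 0.3)
  # independence variant inflates the strength SD
  c3 <- generate_cohort(cohort_spec("aging", n = 5000,
                                    gain_weight_cor = 0), seed = 100)
  G3 <- 20 * log10(consts$det_root) - (c3$detR_db + c3$detL_db) / 2
  W3 <- (c3$WR_db + c3$WL_db) / 2
  expect_gt(stats::sd(G3 + W3), 4.6)
})

test_that("default cohorts separate by about the printed group difference", {
  a <- generate_cohort(cohort_spec("aging", n = 28), seed = 12)
  c <- generate_cohort(cohort_spec("control", n = 28), seed = 13)
  diff <- mean((a$detR_db + a$detL_db) / 2) - mean((c$detR_db + c$detL_db) / 2)
  expect_lt(abs(diff - 5.7), 3) # stochastic at n = 28
})

test_that("an injected imbalance correlation is realised in the draws", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.7
  spec <- cohort_spec("control", n = 4000, imbalance_cor = R)
  co <- generate_cohort(spec, seed = 15)
  r_obs <- stats::cor(co$detR_db - co$detL_db, co$WR_db - co$WL_db)
  expect_lt(abs(r_obs - 0.7), 0.06)
})

test_that("the full protocol emits the prescribed trial structure", {
  set.seed(20)
  obs <- make_observer(standard_observer_spec(), consts)
  tr <- simulate_full_protocol(obs, subject_id = "s1", group = "control")
  expect_true(validate_trials(tr))
  expect_setequal(unique(tr$task),
                  c("detection", "masking", "combination", "stereo"))
  # combination: 7 ratios x 20 trials x 2 reps
  comb <- tr[tr$task == "combination", ]
  expect_equal(nrow(comb), 280)
  expect_equal(sort(unique(round(comb$level, 2))),
               round(ratio_to_db(c(1 / 4, 1 / 2, 1 / sqrt(2), 1,
                                   sqrt(2), 2, 4)), 2))
  expect_true(all(table(comb$level) == 40))
  # contrast levels never exceed 0 dB; disparity never below 1 arc sec
  expect_true(all(tr$level[tr$level_unit == "dB"] <= 0))
  expect_true(all(tr$level[tr$level_unit == "log2_arcsec"] >= 0))
  # stereo: crossed and uncrossed staircases, two reps, <= 30 trials each
  ste <- tr[tr$task == "stereo", ]
  expect_setequal(unique(ste$condition), c("crossed", "uncrossed"))
  expect_equal(length(unique(ste$staircase_id)), 4)
  expect_true(all(table(ste$staircase_id) <= 30))
  # detection starts at -12 dB, masking at -36 dB
  det1 <- tr[tr$task == "detection" & tr$trial_index == 1, ]
  expect_true(all(det1$level == -12))
  msk1 <- tr[tr$task == "masking" & tr$trial_index == 1, ]
  expect_true(all(msk1$level == -36))
})

test_that("the 4:1 ratio shows 90% and 22.5% contrast at a 45% base", {
  cc <- combination_contrasts(ratio_to_db(4), base = 0.45)
  expect_equal(cc$c_left, 0.9, tolerance = 1e-12)
  expect_equal(cc$c_right, 0.225, tolerance = 1e-12)
  cc_inv <- combination_contrasts(ratio_to_db(1 / 4), base = 0.45)
  expect_equal(cc_inv$c_left, 0.225, tolerance = 1e-12)
  expect_equal(cc_inv$c_right, 0.9, tolerance = 1e-12)
  expect_equal(combination_contrasts(0)$c_left, 0.45)
})

test_that("cohort simulation is deterministic under a seed", {
  spec <- cohort_spec("control", n = 2)
  s1 <- simulate_cohort(spec, seed = 30)
  s2 <- simulate_cohort(spec, seed = 30)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$trials, s2$trials)
  expect_false(identical(s1$trials, simulate_cohort(spec, seed = 31)$trials))
})

test_that("protocol configurations round-trip through YAML", {
  pc <- protocol_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol_config(pc, path)
  back <- read_protocol_config(path)
  expect_equal(back$detection$step, 3)
  expect_equal(back$masking$correct_direction, +1)
  expect_equal(back$stereo$initial_level, log2(512))
  expect_equal(back$ratios_db, pc$ratios_db, tolerance = 1e-12)
  expect_equal(back$targ_offset_db, 9)
  # edited configs are honoured
  pc2 <- protocol_config(n_reps = 1, targ_offset_db = 6)
  write_protocol_config(pc2, path)
  expect_equal(read_protocol_config(path)$n_reps, 1L)
  # malformed configs are named
  yaml::write_yaml(list(n_reps = 2), path)
  expect_error(read_protocol_config(path), "missing field")
})
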