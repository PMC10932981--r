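consts <- gc_constants()

test_that("constants validate and cache the two model roots", {
  expect_error(gc_constants(p = 5, q = 6), "p > q")
  expect_error(gc_constants(m = -1), "> 0")
  # stage-2 unit root solves r^p = Z + r^q and lies in (1.20, 1.21)
  r <- consts$resp_unit_root
  expect_gt(r, 1.20)
  expect_lt(r, 1.21)
  expect_equal(r^8, 1 + r^6.6, tolerance = 1e-10)
  # detection root solves x^m/(S+x) = r*
  x <- consts$det_root
  expect_equal(x^1.3 / (1 + x), r, tolerance = 1e-10)
  expect_equal(x, 3.93721453277, tolerance = 1e-8)
})

test_that("stage-1 response matches hand-evaluated cases", {
  expect_equal(stage1_response(1, 0, 1, 1, 1, consts), 1 / 2)
  expect_equal(stage1_response(1, 1, 1, 1, 1, consts), 1 / 3)
  expect_equal(stage1_response(2, 0, 1, 1, 1, consts), 2^1.3 / 3)
  expect_error(stage1_response(-0.1, 0, 1, 1, 1, consts), "non-negative")
  expect_error(stage1_response(0.1, 0, -1, 1, 1, consts), "positive")
})

test_that("stage-2 response matches hand-evaluated cases", {
  expect_equal(stage2_response(1, consts), 0.5)
  expect_equal(stage2_response(0, consts), 0)
  expect_error(stage2_response(-1, consts), "non-negative")
})

test_that("full transducer is monotone in target and mask contrast", {
  set.seed(11)
  for (i in 1:25) {
    g_t <- 10^stats::runif(1, 2, 3)
    g_m <- 10^stats::runif(1, 2, 3)
    w <- 10^stats::runif(1, -1, 0)
    cm <- stats::runif(1, 0, 0.5)
    ct <- sort(stats::runif(20, 1e-4, 1))
    resp <- stage2_response(stage1_response(ct, cm, g_t, g_m, w, consts),
                            consts)
    expect_true(all(diff(resp) > 0))
    ct0 <- stats::runif(1, 0.01, 1)
    cms <- sort(stats::runif(20, 0, 1))
    resp_m <- stage2_response(stage1_response(ct0, cms, g_t, g_m, w, consts),
                              consts)
    expect_true(all(diff(resp_m) < 0))
  }
})

test_that("detection threshold is the unit-response contrast, scaling as 1/g", {
  g <- 330
  thr <- detection_threshold(g, consts)
  resp <- stage2_response(stage1_response(thr, 0, g, g, 1, consts), consts)
  expect_equal(resp, 1, tolerance = 1e-9)
  expect_equal(detection_threshold(10 * g, consts), thr / 10,
               tolerance = 1e-12)
  expect_equal(g * thr, consts$det_root, tolerance = 1e-12)
})

test_that("mask threshold closed form equals numeric root finding to 1e-9", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_params_db()
    gR <- 10^(p$GR / 20); gL <- 10^(p$GL / 20); wR <- 10^(p$WR / 20)
    targ <- detection_threshold(gR, consts) * 10^(9 / 20)
    cm <- mask_threshold(gR, gL, wR, targ, consts)
    f <- function(c_mask) {
      stage2_response(stage1_response(targ, c_mask, gR, gL, wR, consts),
                      consts) - 1
    }
    cm_num <- stats::uniroot(f, c(cm / 100, cm * 100), tol = 1e-13)$root
    expect_equal(cm, cm_num, tolerance = 1e-9)
    # doubling the received weight halves the mask threshold
    expect_equal(mask_threshold(gR, gL, 2 * wR, targ, consts), cm / 2,
                 tolerance = 1e-12)
  }
})

test_that("a target at its own detection threshold is degenerate for masking", {
  g <- 200
  thr <- detection_threshold(g, consts)
  expect_error(mask_threshold(g, g, 0.5, thr, consts), "[Dd]egenerate")
})

test_that("fit recovers generating parameters from noiseless quartets", {
  set.seed(31)
  for (i in 1:10) {
    p <- random_params_db()
    q <- quartet_from_params(10^(p$GR / 20), 10^(p$GL / 20),
                             10^(p$WR / 20), 10^(p$WL / 20), consts)
    fit <- fit_gain_control(q, consts)
    expect_true(fit$converged)
    expect_lt(max(abs(c(fit$params$GR - p$GR, fit$params$GL - p$GL,
                        fit$params$WR - p$WR, fit$params$WL - p$WL))),
              0.01)
  }
})

test_that("mirror-symmetric quartets give symmetric parameters", {
  q <- quartet_from_params(300, 300, 0.35, 0.35, consts)
  fit <- fit_gain_control(q, consts)
  expect_equal(fit$params$gR, fit$params$gL, tolerance = 1e-8)
  expect_equal(fit$params$wR, fit$params$wL, tolerance = 1e-8)
})

test_that("parameter recovery under 0.5 dB threshold noise stays within 1.5 dB MAE", {
  set.seed(41)
  n_sub <- 200
  errs <- matrix(NA_real_, n_sub, 4)
  for (i in seq_len(n_sub)) {
    p <- random_params_db()
    q <- quartet_from_params(10^(p$GR / 20), 10^(p$GL / 20),
                             10^(p$WR / 20), 10^(p$WL / 20), consts)
    noisy_db <- 20 * log10(c(q$detR, q$detL, q$maskR, q$maskL)) +
      stats::rnorm(4, 0, 0.5)
    qn <- threshold_quartet(db_to_rms(noisy_db[1]), db_to_rms(noisy_db[2]),
                            db_to_rms(noisy_db[3]), db_to_rms(noisy_db[4]))
    fit <- fit_gain_control(qn, consts)
    errs[i, ] <- c(fit$params$GR - p$GR, fit$params$GL - p$GL,
                   fit$params$WR - p$WR, fit$params$WL - p$WL)
  }
  mae <- apply(abs(errs), 2, stats::median)
  expect_true(all(mae <= 1.5))
})

test_that("suppression strength is the exact dB sum", {
  p <- gc_solve_quartet(quartet_from_params(316.23, 251.19, 0.398, 0.316,
                                            consts), consts)
  s <- suppression_strength(p)
  expect_equal(s$supstrR, p$GL + p$WR)
  expect_equal(s$supstrL, p$GR + p$WL)
  # plain-number cases
  fake <- tibble::tibble(GR = 5, GL = 10, WR = -8, WL = -3)
  s2 <- suppression_strength(fake)
  expect_equal(s2$supstrR, 2)
  expect_equal(s2$supstrL, 2)
})

test_that("imbalances are signed right-minus-left and flip under eye swap", {
  p <- gc_solve_quartet(quartet_from_params(300, 250, 0.4, 0.3, consts),
                        consts)
  imb <- sensory_imbalances(-38, -41, p, 1.2)
  expect_equal(imb$threshold_imbalance, 3)
  expect_equal(imb$weight_imbalance, p$WR - p$WL)
  expect_equal(imb$strength_imbalance, (p$GL + p$WR) - (p$GR + p$WL))
  expect_equal(imb$abs_threshold_imbalance, 3)
  # swap eyes: R<->L parameters, negated balance point
  p_sw <- tibble::tibble(gR = p$gL, gL = p$gR, wR = p$wL, wL = p$wR,
                         GR = p$GL, GL = p$GR, WR = p$WL, WL = p$WR)
  imb_sw <- sensory_imbalances(-41, -38, p_sw, -1.2)
  for (v in c("threshold_imbalance", "fusion_imbalance",
              "weight_imbalance", "strength_imbalance")) {
    expect_equal(imb_sw[[v]], -imb[[v]])
  }
  # identical eyes: all zero
  p_id <- tibble::tibble(gR = 300, gL = 300, wR = 0.4, wL = 0.4,
                         GR = 20 * log10(300), GL = 20 * log10(300),
                         WR = 20 * log10(0.4), WL = 20 * log10(0.4))
  imb0 <- sensory_imbalances(-40, -40, p_id, 0)
  expect_true(all(abs(unlist(imb0)) < 1e-12))
})

test_that("gain-control parameters serialise to a flat JSON document", {
  q <- quartet_from_params(300, 250, 0.4, 0.3, consts)
  fit <- fit_gain_control(q, consts)
  path <- withr::local_tempfile(fileext = ".json")
  write_gc_params(fit, path)
  doc <- read_gc_params(path)
  expect_setequal(names(doc),
                  c("m", "p", "q", "S", "Z", "gR", "gL", "wR", "wL",
                    "GR", "GL", "WR", "WL", "supstrR", "supstrL"))
  expect_equal(doc$GR, fit$params$GR, tolerance = 1e-9)
  expect_equal(doc$supstrR, fit$params$GL + fit$params$WR, tolerance = 1e-9)
})
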