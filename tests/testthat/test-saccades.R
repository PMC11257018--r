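test_that("the participant threshold is six times the median initial-window SD", {
  cfg <- sim_trace_config(seed = 13)
  s <- simulate_session(list(target_spec(speed_deg_s = 20)), cfg,
                        trials_per_speed = 4)
  cal <- fit_calibration(s$calibrations[[1]]$segment)
  trials <- lapply(s$trials, function(tr) {
    eye_kinematics(apply_calibration(tr, cal))
  })
  thr <- compute_saccade_threshold(trials)
  # brute-force recomputation with an explicit loop (the first 21 ms of
  # each trial are the derivative filter's startup transient)
  sds <- numeric(0)
  for (tr in trials) {
    sds <- c(sds, sd(tr$accel_deg_s2[22:80]))
  }
  expect_equal(thr, 6 * median(sds), tolerance = 1e-12)
  expect_error(compute_saccade_threshold(list()),
               class = "pg_threshold_error")
})

test_that("the threshold is stable across simulated sessions", {
  thr <- vapply(1:20, function(sd) {
    cfg <- sim_trace_config(noise_sd_deg = 0.1, seed = 300 + sd)
    s <- simulate_session(list(target_spec(speed_deg_s = 20)), cfg,
                          trials_per_speed = 3)
    cal <- fit_calibration(s$calibrations[[1]]$segment)
    compute_saccade_threshold(lapply(s$trials, function(tr) {
      apply_calibration(tr, cal)
    }))
  }, numeric(1))
  expect_lt(sd(thr) / mean(thr), 0.2)    # coefficient of variation
})

test_that("saccade classes follow the error-based definitions", {
  n <- 3000
  tgt <- const_target(n, speed = 20, start = -10)

  # catch-up: 3 deg behind the target, jump onto it
  pos <- tgt$position_deg - 3
  pos <- add_step(pos, 1500, 3, d = 40)
  ev <- detect_and_classify_saccades(make_trace(pos), tgt, threshold = 2000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$klass, "catchup")
  expect_equal(ev$amplitude_deg, 3, tolerance = 0.05)
  expect_lt(abs(ev$onset_ms - 1500), 25)

  # anticipatory: on target, jump 2 deg ahead (error increases, > 1.5 deg)
  pos <- add_step(tgt$position_deg, 1500, 2, d = 35)
  ev <- detect_and_classify_saccades(make_trace(pos), tgt, threshold = 2000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$klass, "anticipatory")

  # small forward jump increasing error but below 1.5 deg -> other
  pos <- add_step(tgt$position_deg, 1500, 1.2, d = 30)
  ev <- detect_and_classify_saccades(make_trace(pos), tgt, threshold = 2000)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$klass, "other")

  # against the pursuit direction -> other
  pos <- add_step(tgt$position_deg, 1500, -2.5, d = 35)
  ev <- detect_and_classify_saccades(make_trace(pos), tgt, threshold = 2000)
  expect_equal(ev$klass, "other")

  # every detected saccade receives exactly one class
  expect_true(all(ev$klass %in% c("catchup", "anticipatory", "other")))
})

test_that("events touching invalid samples are discarded", {
  n <- 3000
  tgt <- const_target(n, speed = 20, start = -10)
  pos <- add_step(tgt$position_deg - 3, 1500, 3, d = 40)
  valid <- rep(TRUE, n)
  valid[1510:1520] <- FALSE
  ev <- detect_and_classify_saccades(make_trace(pos, valid), tgt,
                                     threshold = 2000)
  expect_equal(nrow(ev), 0)
})

test_that("detector scores well against the simulator truth log", {
  for (sd in 1:2) {
    cfg <- sim_trace_config(pursuit_gain_true = 0.9,
                            catchup_rate_per_s = 0.8,
                            anticipatory_rate_per_s = 0.3, seed = 40 + sd)
    s <- simulate_session(config = cfg)
    sc <- score_detection(s, summarize_session(s))
    expect_gte(sc$recall_big, 0.9)
    expect_gte(sc$precision, 0.9)
    expect_gte(sc$class_acc, 0.9)
  }
})
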