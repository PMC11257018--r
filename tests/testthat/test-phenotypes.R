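test_that("RMSE obeys its closed-form cases", {
  tw <- generate_target_waveform(target_spec(speed_deg_s = 20,
                                             initial_fixation_ms = 500),
                                 seed = 1)
  # perfect tracking
  expect_equal(compute_rmse(make_trace(tw$position_deg), tw), 0)
  # constant 1 degree offset
  expect_equal(compute_rmse(make_trace(tw$position_deg + 1), tw), 1)
  # i.i.d. noise: RMSE converges to the noise SD (law of large numbers)
  set.seed(5)
  noisy <- tw$position_deg + rnorm(length(tw$position_deg), 0, 0.5)
  expect_equal(compute_rmse(make_trace(noisy), tw), 0.5, tolerance = 0.02)
  # no valid samples is an error
  expect_error(
    compute_rmse(make_trace(tw$position_deg,
                            valid = rep(FALSE, length(tw$position_deg))),
                 tw),
    class = "pg_trial_error"
  )
})

test_that("pursuit gain recovers proportional tracking and zero motion", {
  tw <- generate_target_waveform(target_spec(speed_deg_s = 20,
                                             initial_fixation_ms = 500),
                                 seed = 2)
  g <- compute_gain(make_trace(0.9 * tw$position_deg), tw, saccades = NULL)
  expect_equal(g, 0.9, tolerance = 0.01)
  frozen <- compute_gain(make_trace(rep(0, length(tw$position_deg))), tw)
  expect_equal(frozen, 0, tolerance = 0.01)
})

test_that("a position offset moves RMSE but not velocity-based gain", {
  tw <- generate_target_waveform(target_spec(speed_deg_s = 20,
                                             initial_fixation_ms = 500),
                                 seed = 3)
  base <- make_trace(0.9 * tw$position_deg)
  shifted <- make_trace(0.9 * tw$position_deg + 2)
  expect_equal(compute_gain(base, tw), compute_gain(shifted, tw),
               tolerance = 1e-9)
  expect_gt(compute_rmse(shifted, tw), compute_rmse(base, tw))
})

test_that("session summary assembles the four phenotypes consistently", {
  cfg <- sim_trace_config(pursuit_gain_true = 0.9, catchup_rate_per_s = 0.6,
                          anticipatory_rate_per_s = 0.3, seed = 17)
  s <- simulate_session(config = cfg, trials_per_speed = 2)
  ph <- summarize_session(s)
  expect_s3_class(ph, "session_phenotypes")
  expect_equal(ph$n_trials_used, 6)
  expect_equal(ph$gain, 0.9, tolerance = 0.05)
  # rate arithmetic: total class counts over total valid tracking time
  total_valid_s <- sum(vapply(seq_along(s$trials), function(i) {
    tr <- s$trials[[i]]
    sum(tr$target$velocity_deg_s != 0 & tr$valid) / 1000
  }, numeric(1)))
  expect_equal(ph$catchup_per_s,
               sum(ph$trials$n_catchup) / total_valid_s,
               tolerance = 1e-9)
  # trial order does not matter for the session RMSE
  s_rev <- s
  s_rev$trials <- rev(s$trials)
  ph_rev <- summarize_session(s_rev)
  expect_equal(ph_rev$rmse_deg, ph$rmse_deg, tolerance = 1e-9)
})

test_that("a clean unit-gain session sits at the noise floor with zero rates", {
  cfg <- sim_trace_config(pursuit_gain_true = 1, pursuit_latency_ms = 0,
                          noise_sd_deg = 0.1, seed = 19)
  s <- simulate_session(list(target_spec(speed_deg_s = 20)), cfg,
                        trials_per_speed = 2)
  ph <- summarize_session(s)
  expect_lt(ph$rmse_deg, 0.25)
  expect_equal(ph$gain, 1, tolerance = 0.03)
  expect_equal(ph$catchup_per_s, 0)
  expect_equal(ph$anticipatory_per_s, 0)
})

test_that("lower pursuit gain strictly raises session RMSE", {
  rmse_at <- function(gain, seeds) {
    vapply(seeds, function(sd) {
      cfg <- sim_trace_config(pursuit_gain_true = gain,
                              catchup_rate_per_s = 0.6, seed = sd)
      s <- simulate_session(list(target_spec(speed_deg_s = 20)), cfg,
                            trials_per_speed = 2)
      summarize_session(s)$rmse_deg
    }, numeric(1))
  }
  expect_gt(mean(rmse_at(0.8, 61:65)), mean(rmse_at(1.0, 61:65)))
})

test_that("phenotype correlations behave as rank statistics", {
  set.seed(31)
  x <- rnorm(50)
  tab <- data.frame(participant_id = sprintf("p%02d", 1:50),
                    rmse_deg = x, gain = -x,
                    catchup_per_s = exp(x),          # monotone in x
                    anticipatory_per_s = rnorm(50))
  out <- correlate_phenotypes(tab)
  expect_equal(out$correlations["rmse_deg", "rmse_deg"], 1)
  expect_equal(out$correlations["rmse_deg", "gain"], -1)
  expect_equal(out$correlations["rmse_deg", "catchup_per_s"], 1)
  # retest reliability of an exactly repeated measure is 1
  out2 <- correlate_phenotypes(tab, tab)
  expect_true(all(out2$reliability == 1))
  expect_error(correlate_phenotypes(tab[1:2, ]),
               class = "pg_correlation_error")
})

test_that("a shared latent factor induces the expected correlation signs", {
  set.seed(77)
  n <- 300
  f <- rnorm(n)                                  # latent tracking quality
  tab <- data.frame(
    participant_id = sprintf("p%03d", 1:n),
    rmse_deg = 0.8 * f + 0.6 * rnorm(n),
    gain = -0.8 * f + 0.6 * rnorm(n),
    catchup_per_s = -0.4 * f + 0.9 * rnorm(n),
    anticipatory_per_s = 0.7 * f + 0.7 * rnorm(n)
  )
  rho <- correlate_phenotypes(tab)$correlations
  expect_lt(rho["rmse_deg", "gain"], 0)
  expect_gt(rho["rmse_deg", "anticipatory_per_s"], 0)
  expect_lt(rho["gain", "anticipatory_per_s"], 0)
})
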