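#' Configure the eye-movement trace simulator
#'
#' Parameters controlling how a simulated participant tracks the pursuit
#' target, the oculomotor events injected into the trace, and the affine
#' distortion of the recorded signal that the calibration step must undo.
#'
#' @param pursuit_gain_true steady-state pursuit gain in (0, 1.2]: the
#'   simulated eye moves at this fraction of target velocity.
#' @param pursuit_latency_ms pursuit latency (ms); the smooth eye trace is the
#'   target trajectory delayed by this amount.
#' @param catchup_rate_per_s Poisson rate of injected catch-up saccades
#'   (saccades toward the target that cancel the accumulated position error).
#' @param anticipatory_rate_per_s Poisson rate of injected anticipatory
#'   saccades (saccades in the pursuit direction that land ahead of the
#'   target).
#' @param anticipatory_amp_deg how far ahead of the target an anticipatory
#'   saccade lands (deg); must exceed 1.5 so that the event is classifiable
#'   as anticipatory by the amplitude rule.
#' @param blink_rate_per_s Poisson rate of blinks.
#' @param blink_duration_ms blink core duration (ms).
#' @param noise_sd_deg sensor noise SD in signal units (default 0.1 deg,
#'   about six minutes of visual angle).
#' @param cal_gain,cal_offset_deg affine distortion of the recorded signal:
#'   `signal = cal_gain * eye + cal_offset + noise`.
#' @param reversal_smooth_ms width (ms) of the moving-average window used to
#'   round the eye trajectory at target direction reversals; 0 gives a
#'   perfectly triangular (corner-preserving) eye trace.
#' @param cal_every number of trials between repeated calibrations.
#' @param seed integer seed; identical seeds reproduce identical sessions.
#'
#' @return An object of class `sim_trace_config`.
#' @export
sim_trace_config <- function(pursuit_gain_true = 0.95,
                             pursuit_latency_ms = 100,
                             catchup_rate_per_s = 0,
                             anticipatory_rate_per_s = 0,
                             anticipatory_amp_deg = 2.5,
                             blink_rate_per_s = 0,
                             blink_duration_ms = 150,
                             noise_sd_deg = 0.1,
                             cal_gain = 1,
                             cal_offset_deg = 0,
                             reversal_smooth_ms = 120,
                             cal_every = 6L,
                             seed = 1L) {
  assert_scalar_num(pursuit_gain_true, "pursuit_gain_true", 0, 1.2,
                    strict_lower = TRUE)
  assert_scalar_num(pursuit_latency_ms, "pursuit_latency_ms", 0)
  assert_scalar_num(catchup_rate_per_s, "catchup_rate_per_s", 0)
  assert_scalar_num(anticipatory_rate_per_s, "anticipatory_rate_per_s", 0)
  assert_scalar_num(anticipatory_amp_deg, "anticipatory_amp_deg", 1.5,
                    strict_lower = TRUE)
  assert_scalar_num(blink_rate_per_s, "blink_rate_per_s", 0)
  assert_scalar_num(blink_duration_ms, "blink_duration_ms", 0,
                    strict_lower = TRUE)
  assert_scalar_num(noise_sd_deg, "noise_sd_deg", 0)
  assert_scalar_num(cal_gain, "cal_gain")
  assert_scalar_num(cal_offset_deg, "cal_offset_deg")
  assert_scalar_num(reversal_smooth_ms, "reversal_smooth_ms", 0)
  assert_scalar_num(cal_every, "cal_every", 1)
  if (abs(cal_gain) < 1e-8) {
    stop_pg("`cal_gain` must be nonzero", "pg_parameter_error")
  }
  structure(
    list(
      pursuit_gain_true = pursuit_gain_true,
      pursuit_latency_ms = pursuit_latency_ms,
      catchup_rate_per_s = catchup_rate_per_s,
      anticipatory_rate_per_s = anticipatory_rate_per_s,
      anticipatory_amp_deg = anticipatory_amp_deg,
      blink_rate_per_s = blink_rate_per_s,
      blink_duration_ms = blink_duration_ms,
      noise_sd_deg = noise_sd_deg,
      cal_gain = cal_gain,
      cal_offset_deg = cal_offset_deg,
      reversal_smooth_ms = reversal_smooth_ms,
      cal_every = as.integer(cal_every),
      seed = as.integer(seed)
    ),
    class = "sim_trace_config"
  )
}

# Minimum-jerk position step of amplitude `amp` over `d` samples.
min_jerk_profile <- function(amp, d) {
  tau <- seq_len(d) / d
  amp * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# Centered moving average with edge padding (rounds trajectory corners).
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(h + 1L):(h + length(x))]
}

# Simulate a single pursuit trial.  RNG state is managed by the caller.
sim_trial <- function(target, config) {
  n <- length(target$time_ms)
  fs <- target$spec$sample_rate_hz
  dt_ms <- 1000 / fs
  lat <- as.integer(round(config$pursuit_latency_ms / dt_ms))
  tpos <- target$position_deg
  tvel <- target$velocity_deg_s

  smooth_w <- as.integer(round(config$reversal_smooth_ms / dt_ms))
  s <- moving_average(tpos, smooth_w)
  s_shift <- if (lat > 0L) c(rep(s[1L], lat), s[seq_len(n - lat)]) else s
  eye0 <- config$pursuit_gain_true * s_shift

  fix <- target$fixation_ms / dt_ms

  # --- blinks -------------------------------------------------------------
  blink <- matrix(numeric(0), ncol = 2L)
  dur <- round(config$blink_duration_ms / dt_ms)
  n_blink <- stats::rpois(1L, config$blink_rate_per_s * n / fs)
  if (n_blink > 0L && n > dur + 500) {
    cand <- sort(round(stats::runif(n_blink, 300, n - dur - 150)))
    for (b in cand) {
      if (nrow(blink) == 0L || b > blink[nrow(blink), 2L] + 300) {
        blink <- rbind(blink, c(b, b + dur))
      }
    }
  }

  # --- saccades -----------------------------------------------------------
  motion_s <- (n - fix) / fs
  draw_times <- function(rate) {
    k <- stats::rpois(1L, rate * motion_s)
    lo <- fix + lat + 150
    hi <- n - 200
    if (k == 0L || hi <= lo) numeric(0) else {
      round(stats::runif(k, lo, hi))
    }
  }
  t_cu <- if (config$catchup_rate_per_s > 0) {
    draw_times(config$catchup_rate_per_s)
  } else numeric(0)
  t_an <- if (config$anticipatory_rate_per_s > 0) {
    draw_times(config$anticipatory_rate_per_s)
  } else numeric(0)
  cand_t <- c(t_cu, t_an)
  cand_k <- c(rep(1L, length(t_cu)), rep(2L, length(t_an)))
  offset <- numeric(n)
  sacc <- NULL
  if (length(cand_t) > 0L) {
    t_lo <- fix + lat + 150
    t_hi <- n - 200
    near_reversal <- function(t) {
      any(t > target$reversal_ms - 80 & t < target$reversal_ms + lat + 120)
    }
    in_blink <- function(t, d) {
      nrow(blink) > 0L && any(t + d > blink[, 1L] - 150 & t < blink[, 2L] + 150)
    }
    tries <- integer(length(cand_t))
    done <- logical(length(cand_t))
    last_end <- -Inf
    # process events chronologically; an event whose placement fails
    # (refractory overlap, reversal zone, blink, or its class condition not
    # met at that moment) is redrawn at a later time rather than dropped,
    # so that the injected count stays Poisson at the configured rate
    repeat {
      open <- which(!done)
      if (length(open) == 0L) break
      i <- open[which.min(cand_t[open])]
      t <- round(cand_t[i])
      retry <- function() {
        tries[i] <<- tries[i] + 1L
        if (tries[i] > 30L || max(last_end + 150, t_lo) >= t_hi) {
          done[i] <<- TRUE              # give up on this event
        } else {
          cand_t[i] <<- stats::runif(1L, max(last_end + 150, t_lo), t_hi)
        }
      }
      if (t < last_end + 150 || t < t_lo || t > t_hi || near_reversal(t)) {
        retry()
        next
      }
      klass <- if (cand_k[i] == 1L) "catchup" else "anticipatory"
      cur_err <- tpos[t + 1L] - (eye0[t + 1L] + offset[t + 1L])
      dir <- sign(tvel[t + 1L])
      # each injected event must satisfy its class definition at injection
      # time: catch-up = with the pursuit direction and error-reducing
      # (requires the eye to lag behind the target); anticipatory = with
      # the pursuit direction, landing far enough ahead of the target that
      # the absolute position error strictly increases (injected only while
      # tracking is tight, which keeps the eye's lead bounded)
      bad_class <- dir == 0 ||
        (klass == "catchup" && (abs(cur_err) < 0.5 || sign(cur_err) != dir)) ||
        (klass == "anticipatory" && abs(cur_err) > 2)
      if (bad_class) {
        retry()
        next
      }
      amp <- if (klass == "catchup") {
        cur_err
      } else {
        cur_err + dir * (abs(cur_err) + config$anticipatory_amp_deg)
      }
      d <- max(30L, min(80L, as.integer(round(21 + 2.2 * abs(amp)))))
      if (in_blink(t, d)) {
        retry()
        next
      }
      idx <- t + seq_len(d)
      offset[idx] <- offset[idx] + min_jerk_profile(amp, d)
      if (t + d < n) offset[(t + d + 1L):n] <- offset[(t + d + 1L):n] + amp
      sacc <- rbind(sacc, data.frame(
        onset_ms = t * dt_ms, offset_ms = (t + d) * dt_ms,
        amplitude_deg = amp, class = klass, stringsAsFactors = FALSE
      ))
      last_end <- t + d
      done[i] <- TRUE
    }
    if (!is.null(sacc)) sacc <- sacc[order(sacc$onset_ms), ]
  }

  eye <- eye0 + offset
  signal <- config$cal_gain * eye + config$cal_offset_deg
  if (config$noise_sd_deg > 0) {
    signal <- signal + stats::rnorm(n, 0, config$noise_sd_deg)
  }
  valid <- rep(TRUE, n)

  # --- blink artifact: off-scale clamp with 50 ms tapered edges -----------
  clamp <- -40
  taper <- round(50 / dt_ms)
  if (nrow(blink) > 0L) {
    for (i in seq_len(nrow(blink))) {
      b1 <- blink[i, 1L]; b2 <- blink[i, 2L]
      core <- max(1L, b1):min(n, b2)
      signal[core] <- clamp
      up <- max(1L, b1 - taper):(b1 - 1L)
      if (length(up) > 0L && up[1L] >= 1L) {
        w <- seq_along(up) / (length(up) + 1L)
        signal[up] <- (1 - w) * signal[up] + w * clamp
      }
      dn <- (b2 + 1L):min(n, b2 + taper)
      if (length(dn) > 0L && dn[length(dn)] <= n) {
        w <- rev(seq_along(dn)) / (length(dn) + 1L)
        signal[dn] <- (1 - w) * signal[dn] + w * clamp
      }
      valid[max(1L, b1 - taper):min(n, b2 + taper)] <- FALSE
    }
  }

  trial <- structure(
    list(time_ms = target$time_ms, signal = signal, valid = valid,
         target = target),
    class = "pursuit_trial"
  )
  list(
    trial = trial,
    saccades = sacc,
    blinks = if (nrow(blink) > 0L) {
      # truth records the full invalid extent (core plus tapered edges)
      data.frame(start_ms = pmax(0, blink[, 1L] - taper) * dt_ms,
                 end_ms = pmin(n, blink[, 2L] + taper) * dt_ms)
    }
  )
}

# Simulate one calibration segment: 1000 ms fixations at the seven grid
# positions, distorted by the same affine signal transform.
sim_calibration <- function(config, fix_ms = 1000L,
                            grid = c(15, 10, 5, 0, -5, -10, -15)) {
  n <- length(grid) * fix_ms
  target_deg <- rep(grid, each = fix_ms)
  signal <- config$cal_gain * target_deg + config$cal_offset_deg
  if (config$noise_sd_deg > 0) {
    signal <- signal + stats::rnorm(n, 0, config$noise_sd_deg)
  }
  structure(
    list(time_ms = seq_len(n) - 1L, signal = signal,
         target_deg = target_deg, valid = rep(TRUE, n)),
    class = "calibration_segment"
  )
}

#' Simulate a full smooth-pursuit recording session
#'
#' Generates a session of pursuit trials (by default eight per target speed,
#' left/right start directions balanced four/four), with calibration segments
#' interleaved at regular intervals, and returns both the raw traces and a
#' ground-truth log (`truth`) of every injected saccade and blink.
#'
#' The simulated smooth eye trace is the target trajectory delayed by the
#' pursuit latency and attenuated by the pursuit gain, with direction
#' reversals rounded over `reversal_smooth_ms`.  Catch-up saccades cancel the
#' accumulated eye-target error; anticipatory saccades land
#' `anticipatory_amp_deg` ahead of the target.  Both use minimum-jerk
#' position profiles of 30-80 ms.  Blinks clamp the signal off-scale with
#' 50 ms tapered edges and are marked invalid.  The recorded signal is
#' `cal_gain * eye + cal_offset + noise`.
#'
#' @param spec_set list of [target_spec()] objects, one per target speed
#'   (default speeds 10, 20, 30 deg/s).
#' @param config a [sim_trace_config()].
#' @param trials_per_speed number of trials per target speed (default 8).
#'
#' @return An object of class `pursuit_session`: a list with `trials` (each
#'   a `pursuit_trial` with raw `signal`, `valid` mask and its
#'   `target_trajectory`), `calibrations` (each with `segment` and the
#'   `after_trial` slot it follows), `truth` (data frames `saccades` and
#'   `blinks` keyed by trial, plus `pursuit_gain_true`) and `config`.
#' @export
simulate_session <- function(spec_set = NULL, config = sim_trace_config(),
                             trials_per_speed = 8L) {
  if (!inherits(config, "sim_trace_config")) {
    stop_pg("`config` must be a sim_trace_config", "pg_parameter_error")
  }
  if (is.null(spec_set)) {
    spec_set <- lapply(c(10, 20, 30), function(v) target_spec(speed_deg_s = v))
  }
  if (inherits(spec_set, "target_spec")) spec_set <- list(spec_set)
  trials_per_speed <- as.integer(trials_per_speed)
  stopifnot(trials_per_speed >= 1L)

  with_seed(config$seed, {
    trials <- list()
    sacc_truth <- NULL
    blink_truth <- NULL
    idx <- 0L
    for (spec in spec_set) {
      for (k in seq_len(trials_per_speed)) {
        idx <- idx + 1L
        dir <- if (k %% 2L == 1L) "right" else "left"
        spec_k <- spec
        spec_k$start_direction <- dir
        target <- generate_target_waveform(
          spec_k, seed = floor(stats::runif(1L, 0, 2^30))
        )
        out <- sim_trial(target, config)
        trials[[idx]] <- out$trial
        trials[[idx]]$trial_no <- idx
        if (!is.null(out$saccades)) {
          sacc_truth <- rbind(sacc_truth,
                              cbind(trial = idx, out$saccades))
        }
        if (!is.null(out$blinks)) {
          blink_truth <- rbind(blink_truth,
                               cbind(trial = idx, out$blinks))
        }
      }
    }
    n_trials <- idx
    cal_after <- seq(0L, n_trials - 1L, by = config$cal_every)
    calibrations <- lapply(cal_after, function(a) {
      list(segment = sim_calibration(config), after_trial = a)
    })

    structure(
      list(
        trials = trials,
        calibrations = calibrations,
        truth = list(
          saccades = if (is.null(sacc_truth)) {
            data.frame(trial = integer(0), onset_ms = numeric(0),
                       offset_ms = numeric(0), amplitude_deg = numeric(0),
                       class = character(0))
          } else sacc_truth,
          blinks = if (is.null(blink_truth)) {
            data.frame(trial = integer(0), start_ms = numeric(0),
                       end_ms = numeric(0))
          } else blink_truth,
          pursuit_gain_true = config$pursuit_gain_true,
          cal_gain = config$cal_gain,
          cal_offset_deg = config$cal_offset_deg
        ),
        config = config
      ),
      class = "pursuit_session"
    )
  })
}
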