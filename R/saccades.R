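#' Smoothed eye velocity and acceleration
#'
#' Differentiates the calibrated position signal with cascaded second-order
#' Savitzky-Golay derivative filters (21 ms windows at the default 1 kHz
#' rate).  Double-differencing raw infrared-oculography data at a noise
#' floor of about six arcmin is unusable; the polynomial filters keep the
#' acceleration noise well below the amplitude of small saccades.
#'
#' @param trace trace with `position_deg` and `time_ms`.
#' @param window_ms filter window (ms), forced odd.
#' @return The trace with `velocity_deg_s` and `accel_deg_s2` added.
#' @export
eye_kinematics <- function(trace, window_ms = 21) {
  if (is.null(trace$position_deg)) {
    stop_pg("trace must be calibrated (no `position_deg`)",
            "pg_parameter_error")
  }
  dt_s <- diff(trace$time_ms[1:2]) * 1e-3
  w <- max(5L, as.integer(round(window_ms / (dt_s * 1000))))
  if (w %% 2L == 0L) w <- w + 1L
  if (length(trace$position_deg) <= w) {
    stop_pg("trace shorter than the differentiation window", "pg_data_error")
  }
  vel <- signal::sgolayfilt(trace$position_deg, p = 2, n = w, m = 1, ts = dt_s)
  acc <- signal::sgolayfilt(vel, p = 2, n = w, m = 1, ts = dt_s)
  trace$velocity_deg_s <- vel
  trace$accel_deg_s2 <- acc
  trace
}

# SD of the acceleration signal over the first `window_ms` of a trial.
# The derivative filter's startup transient (the first `skip_ms`) is
# excluded: those samples come from one-sided polynomial fits with much
# larger, erratic noise amplification and would dominate the SD.
# Returns NA when the initial window is contaminated by invalid samples.
initial_accel_sd <- function(trace, window_ms = 80, skip_ms = 21) {
  dt_ms <- diff(trace$time_ms[1:2])
  k <- as.integer(round(window_ms / dt_ms))
  k0 <- as.integer(round(skip_ms / dt_ms)) + 1L
  if (is.null(trace$accel_deg_s2)) trace <- eye_kinematics(trace)
  if (length(trace$accel_deg_s2) < k || k0 >= k) return(NA_real_)
  ok <- if (is.null(trace$valid)) rep(TRUE, k) else trace$valid[seq_len(k)]
  if (!all(ok)) return(NA_real_)
  stats::sd(trace$accel_deg_s2[k0:k])
}

#' Participant-level saccade detection threshold
#'
#' The relative acceleration threshold: six times the median, across all of
#' a participant's trials, of the standard deviation of the acceleration
#' signal during the first 80 ms of each trial (a period of steady central
#' fixation, so the SD reflects the participant/instrument noise floor).
#'
#' @param trials list of calibrated traces.
#' @param window_ms initial window over which the SD is taken (ms).
#' @param multiplier threshold multiplier (6 by protocol).
#' @return Acceleration threshold in deg/s^2.
#' @export
compute_saccade_threshold <- function(trials, window_ms = 80, multiplier = 6) {
  sds <- vapply(trials, initial_accel_sd, numeric(1), window_ms = window_ms)
  sds <- sds[is.finite(sds)]
  if (length(sds) == 0L) {
    stop_pg("no trial with a valid initial window", "pg_threshold_error")
  }
  multiplier * stats::median(sds)
}

#' Detect and classify saccades in a calibrated trace
#'
#' Candidate events are runs where |acceleration| exceeds the participant
#' threshold; runs closer than a refractory gap are merged, then extended to
#' where |acceleration| falls back below 20% of threshold, and events
#' shorter than a minimum duration or touching invalid (blink) samples are
#' discarded.  Each event is classified against the target trajectory:
#'
#' * `catchup` - saccade direction matches the current target-motion
#'   direction and the absolute eye-target position error decreases from
#'   onset to offset;
#' * `anticipatory` - direction matches the target motion, the error
#'   increases, and the amplitude exceeds 1.5 deg;
#' * `other` - everything else.
#'
#' Positional error is evaluated 5 ms before onset and 5 ms after offset to
#' avoid transient overshoot.
#'
#' @param trace calibrated trace (with `position_deg`; kinematics are
#'   computed if absent).
#' @param target the trial's `target_trajectory`.
#' @param threshold acceleration threshold in deg/s^2 (> 0), from
#'   [compute_saccade_threshold()].
#' @param refractory_ms merge gap between candidate runs.
#' @param min_duration_ms minimum event duration.
#' @param anticipatory_min_amp_deg amplitude rule for the anticipatory
#'   class (1.5 deg by protocol).
#'
#' @return Data frame with one row per saccade: `onset_ms`, `offset_ms`,
#'   `amplitude_deg`, `direction`, `klass`, `err_onset_deg`,
#'   `err_offset_deg`.
#' @export
detect_and_classify_saccades <- function(trace, target, threshold,
                                         refractory_ms = 20,
                                         min_duration_ms = 10,
                                         anticipatory_min_amp_deg = 1.5) {
  assert_scalar_num(threshold, "threshold", 0, strict_lower = TRUE)
  if (is.null(trace$accel_deg_s2)) trace <- eye_kinematics(trace)
  acc <- trace$accel_deg_s2
  pos <- trace$position_deg
  n <- length(pos)
  valid <- if (is.null(trace$valid)) rep(TRUE, n) else trace$valid
  dt_ms <- diff(trace$time_ms[1:2])

  cand <- abs(acc) > threshold & valid
  runs <- true_runs(cand)
  empty <- data.frame(
    onset_ms = numeric(0), offset_ms = numeric(0),
    amplitude_deg = numeric(0), direction = numeric(0),
    klass = character(0), err_onset_deg = numeric(0),
    err_offset_deg = numeric(0)
  )
  if (nrow(runs) == 0L) return(empty)

  gap <- round(refractory_ms / dt_ms)
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      j <- nrow(merged)
      if (runs[i, 1L] - merged[j, 2L] <= gap) {
        merged[j, 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }

  # extend to the 20%-of-threshold re-crossing
  low <- abs(acc) > 0.2 * threshold
  for (i in seq_len(nrow(merged))) {
    a <- merged[i, 1L]
    while (a > 1L && low[a - 1L]) a <- a - 1L
    b <- merged[i, 2L]
    while (b < n && low[b + 1L]) b <- b + 1L
    merged[i, ] <- c(a, b)
  }
  merged <- merge_intervals(merged)

  min_len <- round(min_duration_ms / dt_ms)
  out <- empty
  tpos <- target$position_deg
  tvel <- target$velocity_deg_s
  probe <- round(5 / dt_ms)
  vel <- trace$velocity_deg_s
  edge <- as.integer(round(45 / dt_ms))  # filter startup/teardown transient
  for (i in seq_len(nrow(merged))) {
    a <- merged[i, 1L]
    b <- merged[i, 2L]
    if (b - a < min_len) next
    if (a <= edge || b >= n - edge) next # edge transients are not events
    if (!all(valid[a:b])) next          # events inside blinks are discarded
    # amplitude = position change minus the smooth-pursuit drift expected
    # over the event, estimated from the surrounding baseline velocity
    base_idx <- c(max(1L, a - 60L):max(1L, a - 25L),
                  min(n, b + 25L):min(n, b + 60L))
    base_idx <- base_idx[valid[base_idx]]
    v_base <- if (length(base_idx) > 0L) {
      stats::median(vel[base_idx])
    } else 0
    amp <- pos[b] - pos[a] - v_base * (b - a) * dt_ms * 1e-3
    dir <- sign(amp)
    ia <- max(1L, a - probe)
    ib <- min(n, b + probe)
    err_on <- abs(pos[ia] - tpos[ia])
    err_off <- abs(pos[ib] - tpos[ib])
    pursuit_dir <- sign(tvel[a])
    klass <- "other"
    if (pursuit_dir != 0 && dir == pursuit_dir) {
      if (err_off < err_on) {
        klass <- "catchup"
      } else if (err_off > err_on && abs(amp) > anticipatory_min_amp_deg) {
        klass <- "anticipatory"
      }
    }
    out <- rbind(out, data.frame(
      onset_ms = trace$time_ms[a], offset_ms = trace$time_ms[b],
      amplitude_deg = amp, direction = dir, klass = klass,
      err_onset_deg = err_on, err_offset_deg = err_off,
      stringsAsFactors = FALSE
    ))
  }
  out
}
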