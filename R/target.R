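#' Specify a smooth-pursuit target waveform
#'
#' The pursuit target starts at the central fixation point, remains there for
#' a random initial fixation period, and then moves horizontally at a constant
#' speed, reversing direction at a fixed eccentricity so that its position
#' follows a triangular temporal waveform.
#'
#' @param speed_deg_s constant target speed in degrees of visual angle per
#'   second (the protocol uses 10, 20 and 30 deg/s).
#' @param amplitude_deg eccentricity at which the target reverses (deg).
#' @param n_cycles number of triangular cycles of motion; one cycle is
#'   `4 * amplitude_deg / speed_deg_s` seconds.
#' @param initial_fixation_ms length-2 integer range (ms) from which the
#'   initial central-fixation duration is drawn uniformly; a length-1 value
#'   fixes the duration.
#' @param sample_rate_hz sampling rate of the generated series (Hz).
#' @param start_direction `"right"` (positive) or `"left"` (negative) initial
#'   motion direction.
#'
#' @return An object of class `target_spec`.
#' @seealso [generate_target_waveform()]
#' @export
target_spec <- function(speed_deg_s = 20, amplitude_deg = 15, n_cycles = 5.5,
                        initial_fixation_ms = c(500L, 1500L),
                        sample_rate_hz = 1000L,
                        start_direction = c("right", "left")) {
  assert_scalar_num(speed_deg_s, "speed_deg_s", 0, strict_lower = TRUE)
  assert_scalar_num(amplitude_deg, "amplitude_deg", 0, strict_lower = TRUE)
  assert_scalar_num(n_cycles, "n_cycles", 0, strict_lower = TRUE)
  assert_scalar_num(sample_rate_hz, "sample_rate_hz", 0, strict_lower = TRUE)
  if (!is.numeric(initial_fixation_ms) ||
      !length(initial_fixation_ms) %in% 1:2 ||
      any(initial_fixation_ms < 0)) {
    stop_pg("invalid parameter `initial_fixation_ms`", "pg_parameter_error")
  }
  if (length(initial_fixation_ms) == 1L) {
    initial_fixation_ms <- rep(initial_fixation_ms, 2L)
  }
  if (initial_fixation_ms[2L] < initial_fixation_ms[1L]) {
    stop_pg("invalid parameter `initial_fixation_ms`", "pg_parameter_error")
  }
  start_direction <- match.arg(start_direction)
  structure(
    list(
      speed_deg_s = speed_deg_s,
      amplitude_deg = amplitude_deg,
      n_cycles = n_cycles,
      initial_fixation_ms = as.integer(round(initial_fixation_ms)),
      sample_rate_hz = as.integer(round(sample_rate_hz)),
      start_direction = start_direction
    ),
    class = "target_spec"
  )
}

#' Generate a triangular-waveform target position series
#'
#' Produces the deterministic target trajectory for one pursuit trial: an
#' initial central fixation (duration drawn uniformly from the spec's range),
#' followed by piecewise-linear motion at the constant speed between
#' `-amplitude` and `+amplitude` for `n_cycles` cycles.
#'
#' @param spec a [target_spec()].
#' @param seed integer seed controlling the fixation-duration draw.
#'
#' @return An object of class `target_trajectory`: a list with `time_ms`,
#'   `position_deg`, `velocity_deg_s` (signed, zero during fixation),
#'   `fixation_ms`, `reversal_ms` (times at which the target reverses) and
#'   the generating `spec`.
#' @export
generate_target_waveform <- function(spec, seed = 1L) {
  if (!inherits(spec, "target_spec")) {
    stop_pg("`spec` must be a target_spec", "pg_parameter_error")
  }
  fix_ms <- with_seed(seed, {
    r <- spec$initial_fixation_ms
    if (r[1L] == r[2L]) r[1L] else {
      as.integer(floor(stats::runif(1L, r[1L], r[2L] + 1L)))
    }
  })
  fs <- spec$sample_rate_hz
  v <- spec$speed_deg_s
  a <- spec$amplitude_deg
  cycle_s <- 4 * a / v
  motion_ms <- round(spec$n_cycles * cycle_s * 1000)
  n <- as.integer(fix_ms + motion_ms)
  time_ms <- seq_len(n) - 1L
  dt_ms <- 1000 / fs

  # distance travelled since motion onset, folded onto the triangular wave
  t_motion_s <- pmax(0, (time_ms - fix_ms)) * 1e-3
  dist <- v * t_motion_s
  phase <- dist %% (4 * a)
  pos <- ifelse(phase < a, phase,
                ifelse(phase < 3 * a, 2 * a - phase, phase - 4 * a))
  vel <- ifelse(phase < a | phase >= 3 * a, v, -v)
  moving <- time_ms >= fix_ms
  pos[!moving] <- 0
  vel[!moving] <- 0
  dir <- if (spec$start_direction == "right") 1 else -1
  pos <- dir * pos
  vel <- dir * vel

  # reversal times: target hits +/- amplitude every half cycle after the
  # first quarter cycle
  quarter_ms <- cycle_s / 4 * 1000
  half_ms <- cycle_s / 2 * 1000
  rev_ms <- fix_ms + seq(quarter_ms, motion_ms - dt_ms, by = half_ms)

  structure(
    list(
      time_ms = time_ms,
      position_deg = pos,
      velocity_deg_s = vel,
      fixation_ms = fix_ms,
      reversal_ms = rev_ms,
      spec = spec
    ),
    class = "target_trajectory"
  )
}
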