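#' Fit a spatial calibration by linear regression
#'
#' A calibration segment holds fixations of the seven grid targets (15, 10,
#' 5, 0, -5, -10, -15 deg).  The mean recorded signal at each distinct
#' target is regressed on the target value by ordinary least squares; the
#' slope is the instrument gain and the intercept its offset.  Calibrated
#' position is recovered as `(signal - offset) / gain`.
#'
#' @param segment a calibration segment: a list with numeric `signal`,
#'   `target_deg` (per-sample target position) and optionally a logical
#'   `valid` mask.
#' @param min_gain smallest |gain| accepted before the calibration is
#'   declared degenerate.
#'
#' @return An object of class `pursuit_calibration`: list with `gain`,
#'   `offset`, `r_squared`, and the per-target mean signals.
#' @export
fit_calibration <- function(segment, min_gain = 1e-6) {
  sig <- segment$signal
  tgt <- segment$target_deg
  valid <- if (!is.null(segment$valid)) segment$valid else rep(TRUE, length(sig))
  keep <- valid & !is.na(sig) & !is.na(tgt)
  sig <- sig[keep]
  tgt <- tgt[keep]
  targets <- sort(unique(tgt))
  if (length(targets) < 2L) {
    stop_pg("calibration needs >= 2 distinct fixation targets",
            "pg_calibration_error")
  }
  mean_sig <- vapply(targets, function(v) mean(sig[tgt == v]), numeric(1))
  fit <- stats::lm.fit(cbind(1, targets), mean_sig)
  offset <- fit$coefficients[1L]
  gain <- fit$coefficients[2L]
  if (!is.finite(gain) || abs(gain) < min_gain) {
    stop_pg("degenerate calibration: |gain| below tolerance",
            "pg_calibration_error")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((mean_sig - mean(mean_sig))^2)
  structure(
    list(gain = unname(gain), offset = unname(offset),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         target_positions_deg = targets, mean_signal_per_target = mean_sig),
    class = "pursuit_calibration"
  )
}

#' Apply a calibration to a raw trace
#'
#' @param trace a trial trace (list with `time_ms`, `signal`, `valid`).
#' @param cal a [fit_calibration()] result.
#' @return The trace with a `position_deg` element added:
#'   `(signal - offset) / gain`.
#' @export
apply_calibration <- function(trace, cal) {
  if (!inherits(cal, "pursuit_calibration")) {
    stop_pg("`cal` must be a pursuit_calibration", "pg_parameter_error")
  }
  trace$position_deg <- (trace$signal - cal$offset) / cal$gain
  trace
}

#' Detect blinks and signal dropout in a trace
#'
#' Marks intervals where the recorded signal is off the plausible position
#' scale or where the sample-to-sample velocity exceeds a physiologically
#' impossible bound, pads each interval on both sides, and updates the
#' trace's validity mask.
#'
#' @param trace a trace with `position_deg` (calibrated) or `signal`.
#' @param off_scale_deg positions beyond this magnitude are treated as
#'   dropout (default 25 deg; the target never exceeds 15 deg).
#' @param max_velocity velocity bound in deg/s (default 1000).
#' @param pad_ms padding added to each side of a detected interval.
#'
#' @return A list with `intervals` (data frame `start_ms`, `end_ms`),
#'   the updated `trace` (validity mask ANDed with the blink mask) and
#'   `usable` (FALSE when the whole trial is invalid).
#' @export
detect_blinks <- function(trace, off_scale_deg = 25, max_velocity = 1000,
                          pad_ms = 50) {
  pos <- if (!is.null(trace$position_deg)) trace$position_deg else trace$signal
  n <- length(pos)
  dt_s <- diff(trace$time_ms[1:2]) * 1e-3
  vel <- c(0, diff(pos)) / dt_s
  bad <- !is.finite(pos) | abs(pos) > off_scale_deg | abs(vel) > max_velocity
  if (!is.null(trace$valid)) bad <- bad | !trace$valid
  pad <- round(pad_ms / (dt_s * 1000))
  runs <- true_runs(bad)
  if (nrow(runs) > 0L) {
    runs[, 1L] <- pmax(1L, runs[, 1L] - pad)
    runs[, 2L] <- pmin(n, runs[, 2L] + pad)
    runs <- merge_intervals(runs)
  }
  mask <- rep(TRUE, n)
  if (nrow(runs) > 0L) {
    for (i in seq_len(nrow(runs))) mask[runs[i, 1L]:runs[i, 2L]] <- FALSE
  }
  trace$valid <- mask
  intervals <- data.frame(
    start_ms = trace$time_ms[runs[, 1L]],
    end_ms = trace$time_ms[runs[, 2L]]
  )
  list(intervals = intervals, trace = trace, usable = any(mask))
}
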