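#' Root-mean-square eye-position error for one trial
#'
#' RMS of (eye - target) position over all valid samples, i.e. the complete
#' pursuit signal including saccades but excluding blink-masked samples.
#'
#' @param trace calibrated trace with `position_deg` and `valid`.
#' @param target the trial's `target_trajectory`.
#' @return RMSE in degrees of visual angle.
#' @export
compute_rmse <- function(trace, target) {
  valid <- if (is.null(trace$valid)) rep(TRUE, length(trace$position_deg)) else trace$valid
  err <- trace$position_deg[valid] - target$position_deg[valid]
  if (length(err) == 0L) {
    stop_pg("no valid samples in trial", "pg_trial_error")
  }
  sqrt(mean(err^2))
}

#' Pursuit gain for one trial
#'
#' Mean over retained samples of signed eye velocity divided by signed
#' target velocity.  Retained samples are valid (non-blink), outside
#' detected saccades (padded), within 10 deg of target eccentricity (this
#' excludes the direction-reversal regions) and during target motion.
#'
#' @param trace calibrated trace (kinematics computed if absent).
#' @param target the trial's `target_trajectory`.
#' @param saccades data frame from [detect_and_classify_saccades()]
#'   (may have zero rows).
#' @param max_eccentricity_deg eccentricity cut-off (deg).
#' @param saccade_pad_ms padding around saccade intervals (covers filter
#'   bleed from the saccade into neighbouring samples).
#' @return Pursuit gain (dimensionless).
#' @export
compute_gain <- function(trace, target, saccades = NULL,
                         max_eccentricity_deg = 10, saccade_pad_ms = 25) {
  if (is.null(trace$velocity_deg_s)) trace <- eye_kinematics(trace)
  n <- length(trace$position_deg)
  valid <- if (is.null(trace$valid)) rep(TRUE, n) else trace$valid
  keep <- valid &
    abs(target$position_deg) <= max_eccentricity_deg &
    target$velocity_deg_s != 0
  if (!is.null(saccades) && nrow(saccades) > 0L) {
    dt_ms <- diff(trace$time_ms[1:2])
    for (i in seq_len(nrow(saccades))) {
      a <- max(1L, round((saccades$onset_ms[i] - saccade_pad_ms) / dt_ms) + 1L)
      b <- min(n, round((saccades$offset_ms[i] + saccade_pad_ms) / dt_ms) + 1L)
      keep[a:b] <- FALSE
    }
  }
  if (!any(keep)) {
    stop_pg("no retained samples for gain", "pg_trial_error")
  }
  mean(trace$velocity_deg_s[keep] / target$velocity_deg_s[keep])
}

#' Compute the four session-level pursuit phenotypes
#'
#' Applies the most recent preceding calibration to each trial, rejects
#' blinks, derives the participant's acceleration threshold, detects and
#' classifies saccades, and aggregates RMSE, pursuit gain, and catch-up /
#' anticipatory saccade rates over the session.
#'
#' Trials with fewer than `min_valid_frac` valid samples are dropped.
#' Session RMSE and gain are the unweighted mean of per-trial values across
#' all speeds (`aggregate = "mean"`) or, for RMSE, the pooled-sample RMS
#' (`aggregate = "pooled"`).  Saccade rates are total class counts divided
#' by total valid tracking (target-motion) time in seconds.
#'
#' @param session a `pursuit_session` from [simulate_session()] or
#'   [read_traces()].
#' @param aggregate `"mean"` or `"pooled"` per-trial aggregation for RMSE.
#' @param min_valid_frac minimum fraction of valid samples for a trial to
#'   be used.
#'
#' @return An object of class `session_phenotypes`: list with `rmse_deg`,
#'   `gain`, `catchup_per_s`, `anticipatory_per_s`, `n_trials_used`,
#'   `threshold_deg_s2`, per-trial table `trials` and the per-saccade event
#'   table `events`.
#' @export
summarize_session <- function(session, aggregate = c("mean", "pooled"),
                              min_valid_frac = 0.5) {
  aggregate <- match.arg(aggregate)
  if (length(session$trials) == 0L) {
    stop_pg("session has no trials", "pg_session_error")
  }
  if (length(session$calibrations) == 0L) {
    stop_pg("session has no calibration segments", "pg_session_error")
  }
  cal_after <- vapply(session$calibrations, function(cc) cc$after_trial,
                      numeric(1))
  cals <- lapply(session$calibrations, function(cc) fit_calibration(cc$segment))

  prepped <- list()
  for (i in seq_along(session$trials)) {
    trial <- session$trials[[i]]
    trial_no <- if (!is.null(trial$trial_no)) trial$trial_no else i
    ci <- which(cal_after < trial_no)
    if (length(ci) == 0L) next                    # no preceding calibration
    cal <- cals[[ci[which.max(cal_after[ci])]]]
    tr <- apply_calibration(trial, cal)
    bl <- detect_blinks(tr)
    tr <- bl$trace
    if (!bl$usable || mean(tr$valid) < min_valid_frac) next
    tr <- eye_kinematics(tr)
    prepped[[length(prepped) + 1L]] <- tr
  }
  if (length(prepped) == 0L) {
    stop_pg("no usable trials in session", "pg_session_error")
  }

  threshold <- compute_saccade_threshold(prepped)

  per_trial <- NULL
  events <- NULL
  total_valid_s <- 0
  for (tr in prepped) {
    target <- tr$target
    sacc <- detect_and_classify_saccades(tr, target, threshold)
    rmse <- compute_rmse(tr, target)
    gain <- tryCatch(compute_gain(tr, target, sacc),
                     pursuitgwas_error = function(e) NA_real_)
    moving_valid <- tr$valid & target$velocity_deg_s != 0
    dt_s <- diff(tr$time_ms[1:2]) * 1e-3
    total_valid_s <- total_valid_s + sum(moving_valid) * dt_s
    per_trial <- rbind(per_trial, data.frame(
      trial = if (!is.null(tr$trial_no)) tr$trial_no else NA_integer_,
      rmse_deg = rmse, gain = gain,
      n_catchup = sum(sacc$klass == "catchup"),
      n_anticipatory = sum(sacc$klass == "anticipatory"),
      n_valid = sum(tr$valid)
    ))
    if (nrow(sacc) > 0L) {
      events <- rbind(events, cbind(
        trial = if (!is.null(tr$trial_no)) tr$trial_no else NA_integer_,
        sacc
      ))
    }
  }

  rmse_session <- if (aggregate == "mean") {
    mean(per_trial$rmse_deg)
  } else {
    sqrt(sum(per_trial$rmse_deg^2 * per_trial$n_valid) /
           sum(per_trial$n_valid))
  }
  structure(
    list(
      rmse_deg = rmse_session,
      gain = mean(per_trial$gain, na.rm = TRUE),
      catchup_per_s = sum(per_trial$n_catchup) / total_valid_s,
      anticipatory_per_s = sum(per_trial$n_anticipatory) / total_valid_s,
      n_trials_used = nrow(per_trial),
      threshold_deg_s2 = threshold,
      trials = per_trial,
      events = if (is.null(events)) data.frame() else events
    ),
    class = "session_phenotypes"
  )
}

#' @export
print.session_phenotypes <- function(x, ...) {
  cat(sprintf(
    paste0("session phenotypes (%d trials): RMSE %.3f deg, gain %.3f, ",
           "catch-up %.3f /s, anticipatory %.3f /s\n"),
    x$n_trials_used, x$rmse_deg, x$gain, x$catchup_per_s,
    x$anticipatory_per_s
  ))
  invisible(x)
}

#' Spearman correlations between pursuit phenotypes
#'
#' Rank-order correlations (average ranks for ties) between the four
#' session measures across participants, and, when a retest table is
#' supplied, the per-measure test-retest reliability (rank correlation of
#' session 1 against session 2 on the participants present in both).
#'
#' @param table1 data frame with `participant_id` and the measure columns
#'   `rmse_deg`, `gain`, `catchup_per_s`, `anticipatory_per_s`.
#' @param table2 optional retest table in the same format.
#' @param measures which columns to correlate.
#'
#' @return List with `correlations` (Spearman matrix across measures) and,
#'   if `table2` is given, `reliability` (named vector of test-retest rank
#'   correlations).
#' @export
correlate_phenotypes <- function(table1, table2 = NULL,
                                 measures = c("rmse_deg", "gain",
                                              "catchup_per_s",
                                              "anticipatory_per_s")) {
  if (!all(measures %in% names(table1))) {
    stop_pg("missing measure columns in `table1`", "pg_parameter_error")
  }
  x <- table1[, measures, drop = FALSE]
  if (sum(stats::complete.cases(x)) < 3L) {
    stop_pg("fewer than 3 complete observations", "pg_correlation_error")
  }
  rho <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  out <- list(correlations = rho)
  if (!is.null(table2)) {
    if (!all(c("participant_id", measures) %in% names(table2))) {
      stop_pg("missing columns in `table2`", "pg_parameter_error")
    }
    common <- intersect(table1$participant_id, table2$participant_id)
    if (length(common) < 3L) {
      stop_pg("fewer than 3 matched participants", "pg_correlation_error")
    }
    i1 <- match(common, table1$participant_id)
    i2 <- match(common, table2$participant_id)
    out$reliability <- vapply(measures, function(mm) {
      stats::cor(table1[[mm]][i1], table2[[mm]][i2], method = "spearman",
                 use = "pairwise.complete.obs")
    }, numeric(1))
  }
  out
}
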