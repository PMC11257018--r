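# Shared fixtures: constructed traces/targets and scoring against the
# simulator's truth log.  Everything is generated in code at test time.

# Constant-velocity target trajectory (no fixation, no reversals).
const_target <- function(n_ms, speed = 20, start = -10) {
  t <- seq_len(n_ms) - 1L
  structure(
    list(time_ms = t, position_deg = start + speed * t * 1e-3,
         velocity_deg_s = rep(speed, n_ms), fixation_ms = 0L,
         reversal_ms = numeric(0),
         spec = target_spec(speed_deg_s = max(abs(speed), 1))),
    class = "target_trajectory"
  )
}

# Calibrated trace from a position series.
make_trace <- function(position, valid = rep(TRUE, length(position))) {
  list(time_ms = seq_along(position) - 1L, position_deg = position,
       valid = valid)
}

# Add a minimum-jerk position step of amplitude `amp` starting at sample
# `t0` (1-based) with duration `d` samples.
add_step <- function(pos, t0, amp, d = 40L) {
  tau <- seq_len(d) / d
  prof <- amp * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  pos[t0 + seq_len(d)] <- pos[t0 + seq_len(d)] + prof
  if (t0 + d < length(pos)) {
    pos[(t0 + d + 1L):length(pos)] <- pos[(t0 + d + 1L):length(pos)] + amp
  }
  pos
}

# Score detected events against a session's truth log.  Events match when
# onsets agree within `tol_ms` in the same trial.
score_detection <- function(session, phen, tol_ms = 60) {
  ev <- phen$events
  tr <- session$truth$saccades
  tr$detected <- FALSE
  tr$klass_det <- NA_character_
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(tr))) {
      cand <- which(ev$trial == tr$trial[i] &
                      abs(ev$onset_ms - tr$onset_ms[i]) <= tol_ms)
      if (length(cand) > 0L) {
        k <- cand[which.min(abs(ev$onset_ms[cand] - tr$onset_ms[i]))]
        tr$detected[i] <- TRUE
        tr$klass_det[i] <- ev$klass[k]
      }
    }
  }
  matched <- if (nrow(ev) > 0L) {
    vapply(seq_len(nrow(ev)), function(i) {
      any(tr$trial == ev$trial[i] &
            abs(tr$onset_ms - ev$onset_ms[i]) <= tol_ms)
    }, logical(1))
  } else logical(0)
  big <- abs(tr$amplitude_deg) >= 2
  list(
    recall_big = if (any(big)) mean(tr$detected[big]) else NA_real_,
    precision = if (length(matched)) mean(matched) else NA_real_,
    class_acc = {
      ok <- big & tr$detected
      if (any(ok)) mean(tr$klass_det[ok] == tr$class[ok]) else NA_real_
    },
    truth = tr
  )
}

# Independent HWE oracle: full enumeration via the probability recurrence
# on heterozygote counts (distinct from the package's closed-form route).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  r <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (r == 0) return(1)
  het <- seq(r %% 2, r, by = 2)
  pr <- numeric(length(het))
  pr[length(het)] <- 1
  if (length(het) > 1) {
    for (k in (length(het) - 1):1) {
      h <- het[k + 1]
      hom_r <- (r - h) / 2
      hom_c <- n - h - hom_r
      pr[k] <- pr[k + 1] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- match(min(n_Aa, r), het)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}
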