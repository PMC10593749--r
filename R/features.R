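#' Stride-level statistics of one IMU channel
#'
#' Computes the five per-channel stride features: the maximum and minimum of
#' the signal over the gait cycle, the absolute impulse (time integral of
#' |x| over the whole cycle), and the signed stance-phase and swing-phase
#' impulses. Integrals use the trapezoidal rule with dt = 1/fs; the gait
#' cycle spans heel strike to the next heel strike.
#'
#' @param signal Channel series.
#' @param fs Sampling rate, Hz.
#' @param hs,to,next_hs 1-based sample indices of heel strike, toe-off, and
#'   the next heel strike (`hs < to < next_hs <= length(signal)`).
#' @return Named numeric vector: `max`, `min`, `abs_impulse`,
#'   `stance_impulse`, `swing_impulse`.
#' @export
stride_channel_stats <- function(signal, fs, hs, to, next_hs) {
  if (!(hs < to && to < next_hs)) {
    stopf("stride_channel_stats: need hs < to < next_hs (got %d, %d, %d)",
          hs, to, next_hs)
  }
  if (hs < 1L || next_hs > length(signal)) {
    stopf("stride_channel_stats: stride indices [%d, %d] out of range (n = %d)",
          hs, next_hs, length(signal))
  }
  dt <- 1 / fs
  seg <- signal[hs:(next_hs - 1L)]  # half-open: next_hs starts the next cycle
  c(max = max(seg), min = min(seg),
    abs_impulse = trapz_idx(abs(signal), hs, next_hs, dt),
    stance_impulse = trapz_idx(signal, hs, to, dt),
    swing_impulse = trapz_idx(signal, to, next_hs, dt))
}

stat_names <- c("max", "min", "abs_impulse", "stance_impulse", "swing_impulse")

#' Extract the stride-level feature table for a trial
#'
#' One row per stride. For each requested IMU location and channel the five
#' [stride_channel_stats()] are emitted as columns named
#' `<location>_<channel>_<stat>`; insole-derived stance and swing times
#' appear once (they do not depend on the IMU). Stride indices live on the
#' insole clock and are mapped to the IMU clock by time-proportional index
#' mapping (round half up) when the IMU has been decimated.
#'
#' @param trial A [trial_recording()].
#' @param strides Data.frame from [segment_strides()].
#' @param locations IMU locations to use (default: all present in the trial).
#' @param use_gyro Include gyroscope channels? (default `TRUE`; with `FALSE`
#'   only accelerometer statistics are emitted).
#' @return A data.frame with one row per stride: `stance_time_s`,
#'   `swing_time_s`, then the per-location channel statistics.
#' @export
extract_features <- function(trial, strides, locations = names(trial$imus),
                             use_gyro = TRUE) {
  missing_loc <- setdiff(locations, names(trial$imus))
  if (length(missing_loc)) {
    stopf("extract_features: location(s) not present in trial: %s",
          paste(missing_loc, collapse = ", "))
  }
  n <- nrow(strides)
  out <- data.frame(stance_time_s = strides$stance_time_s,
                    swing_time_s = strides$swing_time_s)
  if (n == 0L) out <- out[0L, , drop = FALSE]
  channels <- imu_channel_names(use_gyro)
  for (loc in locations) {
    imu <- trial$imus[[loc]]
    hs <- map_index(strides$hs_idx, trial$fs_insole, imu$fs)
    to <- map_index(strides$to_idx, trial$fs_insole, imu$fs)
    next_hs <- map_index(strides$next_hs_idx, trial$fs_insole, imu$fs)
    for (ch in channels) {
      sig <- imu[[ch]]
      stats_mat <- vapply(seq_len(n), function(s) {
        stride_channel_stats(sig, imu$fs, hs[s], to[s], next_hs[s])
      }, numeric(5L))
      cols <- paste(loc, ch, stat_names, sep = "_")
      if (n == 0L) {
        for (cn in cols) out[[cn]] <- numeric(0)
      } else {
        stats_mat <- t(stats_mat)
        for (q in seq_along(cols)) out[[cols[q]]] <- stats_mat[, q]
      }
    }
  }
  out
}
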