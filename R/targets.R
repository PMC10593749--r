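#' Estimate Achilles tendon load from total insole force
#'
#' A configurable moment-balance stand-in for a physics-based insole-to-tendon
#' model: per-sample tendon load in body weights (BW) is
#' `lever_ratio * force / body_weight_N`. It is monotone in plantar force,
#' zero where force is zero, and documented as replaceable by a full
#' physics-based estimator; with the synthetic generator the default
#' `lever_ratio = 1` recovers the generator's ground-truth loads exactly at
#' the stance peak.
#'
#' @param insole_force Total plantar force series, Newtons.
#' @param body_weight_N Subject body weight, Newtons (> 0).
#' @param lever_ratio Unitless multiplier mapping plantar force to tendon
#'   force (default 1).
#' @return Per-sample tendon load series in BW.
#' @export
estimate_achilles_load <- function(insole_force, body_weight_N,
                                   lever_ratio = 1) {
  if (!is.numeric(body_weight_N) || body_weight_N <= 0) {
    stopf("estimate_achilles_load: body_weight_N must be > 0")
  }
  if (lever_ratio <= 0) {
    stopf("estimate_achilles_load: lever_ratio must be > 0")
  }
  lever_ratio * insole_force / body_weight_N
}

#' Peak tendon load per stride with the 0.5 BW inclusion filter
#'
#' The peak is taken over each gait cycle (heel strike to next heel strike).
#' Strides whose peak load falls below `min_bw` body weights are flagged for
#' exclusion from model training and testing; the boundary is inclusive
#' (a peak exactly at `min_bw` is kept).
#'
#' @param load Per-sample tendon load series, BW.
#' @param strides Data.frame from [segment_strides()].
#' @param min_bw Minimum peak load (BW) for a stride to be kept (default 0.5).
#' @return Data.frame with columns `at_peak_bw` and `kept`.
#' @export
peak_load_per_stride <- function(load, strides, min_bw = 0.5) {
  n <- nrow(strides)
  if (n == 0L) return(data.frame(at_peak_bw = numeric(0), kept = logical(0)))
  if (max(strides$next_hs_idx) > length(load)) {
    stopf("peak_load_per_stride: stride indices exceed load series length")
  }
  peaks <- vapply(seq_len(n), function(s) {
    max(load[strides$hs_idx[s]:(strides$next_hs_idx[s] - 1L)])
  }, numeric(1L))
  data.frame(at_peak_bw = peaks, kept = peaks >= min_bw)
}

#' Trial walking speed from the forward COM trace
#'
#' Walking speed is the net forward progression of the center of mass divided
#' by the elapsed time, computed once per trial. A least-squares line of
#' position on time provides the coefficient of determination used as a
#' constant-speed quality check; trials with r-squared below `r2_flag` are
#' flagged (not rejected).
#'
#' @param com_x Forward COM position series, metres.
#' @param fs_com Sampling rate, Hz.
#' @param r2_flag QC threshold on r-squared (default 0.98).
#' @return List with `speed_mps`, `r_squared`, and `qc_flag` (`TRUE` when
#'   r-squared falls below the threshold).
#' @export
trial_walking_speed <- function(com_x, fs_com, r2_flag = 0.98) {
  n <- length(com_x)
  if (n < 2L) stopf("trial_walking_speed: need at least 2 samples")
  t <- (seq_len(n) - 1) / fs_com
  elapsed <- t[n] - t[1L]
  if (elapsed <= 0) stopf("trial_walking_speed: zero elapsed time")
  speed <- (com_x[n] - com_x[1L]) / elapsed
  fit <- stats::lm.fit(cbind(1, t), com_x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((com_x - mean(com_x))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(speed_mps = speed, r_squared = r2, qc_flag = r2 < r2_flag)
}
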