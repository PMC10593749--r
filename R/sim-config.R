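#' Configuration for the synthetic boot-gait cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort size,
#' heel-wedge conditions, self-selected speed categories, trial/stride counts,
#' sampling rate, and the stochastic structure of the targets. Defaults
#' describe a cohort of ten subjects walking at four self-selected speeds
#' under three wedge conditions (30, 5, 0 degrees), roughly 5,000 strides in
#' total, with a strong subject-specific offset on tendon load and a clean
#' kinematic link for walking speed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Heel-wedge angles in degrees, highest (most plantarflexed,
#'   least loaded) first. Default `c(30, 5, 0)`.
#' @param speed_labels Ordered self-selected speed categories, slowest first.
#' @param trials_per_cell Walking trials per subject x condition x speed cell.
#' @param strides_per_trial Complete gait cycles per trial.
#' @param fs Sampling rate in Hz for all generated streams.
#' @param body_weight_mean_N,body_weight_sd_N Body-weight sampling
#'   distribution (normal, truncated to `[500, 1000]` N).
#' @param subject_effect_sd Named numeric, SDs of the subject-specific target
#'   offsets: `load` in body weights (BW), `speed` in m/s.
#' @param noise_sd Named numeric: `load` is the within-stride SD of the
#'   ground-truth peak load (BW); `speed` is the trial-to-trial SD of walking
#'   speed around the subject's category speed (m/s).
#' @param imu_noise_sd Relative per-stride amplitude jitter of the IMU
#'   waveforms; also scales the additive sample-level sensor noise.
#' @param speed_means_mps Mean walking speed (m/s) for each speed label.
#' @param base_load_bw Named numeric, condition base peak tendon load in BW at
#'   the reference speed; names are the wedge angles. Must decrease with
#'   increasing wedge angle (progressive loading as wedges are removed).
#' @param load_speed_slope Increase in peak load (BW) per m/s of walking speed.
#' @param locations IMU locations to synthesize; subset of
#'   `c("boot", "contra_wrist", "contra_shank", "contra_foot")`.
#' @param seed Integer seed; each subject draws from the substream
#'   `seed + subject index`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_subjects = 10,
                       conditions = c(30, 5, 0),
                       speed_labels = c("pathological", "slow", "medium", "fast"),
                       trials_per_cell = 3,
                       strides_per_trial = 14,
                       fs = 100,
                       body_weight_mean_N = 700,
                       body_weight_sd_N = 80,
                       subject_effect_sd = c(load = 0.45, speed = 0.05),
                       noise_sd = c(load = 0.06, speed = 0.03),
                       imu_noise_sd = 0.04,
                       speed_means_mps = c(0.60, 0.90, 1.25, 1.60),
                       base_load_bw = c("30" = 1.3, "5" = 2.1, "0" = 2.9),
                       load_speed_slope = 0.8,
                       locations = c("boot", "contra_foot"),
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, conditions = conditions,
    speed_labels = speed_labels, trials_per_cell = trials_per_cell,
    strides_per_trial = strides_per_trial, fs = fs,
    body_weight_mean_N = body_weight_mean_N,
    body_weight_sd_N = body_weight_sd_N,
    subject_effect_sd = subject_effect_sd, noise_sd = noise_sd,
    imu_noise_sd = imu_noise_sd, speed_means_mps = speed_means_mps,
    base_load_bw = base_load_bw, load_speed_slope = load_speed_slope,
    locations = locations, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stopf("invalid sim_config field '%s': %s", field, why)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 2) {
    fail("n_subjects", "must be >= 2")
  }
  if (length(cfg$conditions) < 1) fail("conditions", "must be non-empty")
  if (!is.numeric(cfg$fs) || cfg$fs <= 0) fail("fs", "must be > 0")
  if (length(cfg$speed_labels) < 1) fail("speed_labels", "must be non-empty")
  if (length(cfg$speed_means_mps) != length(cfg$speed_labels)) {
    fail("speed_means_mps", "must have one entry per speed label")
  }
  if (is.unsorted(cfg$speed_means_mps, strictly = TRUE)) {
    fail("speed_means_mps", "must increase with speed label order")
  }
  if (cfg$trials_per_cell < 1) fail("trials_per_cell", "must be >= 1")
  if (cfg$strides_per_trial < 1) fail("strides_per_trial", "must be >= 1")
  for (f in c("subject_effect_sd", "noise_sd")) {
    v <- cfg[[f]]
    if (!all(c("load", "speed") %in% names(v))) {
      fail(f, "must be named with entries 'load' and 'speed'")
    }
    if (any(v < 0)) fail(f, "SDs must be >= 0")
  }
  if (cfg$imu_noise_sd < 0) fail("imu_noise_sd", "must be >= 0")
  missing_bl <- setdiff(as.character(cfg$conditions), names(cfg$base_load_bw))
  if (length(missing_bl)) {
    fail("base_load_bw", paste("missing condition(s):",
                               paste(missing_bl, collapse = ", ")))
  }
  bl <- cfg$base_load_bw[as.character(sort(unique(cfg$conditions)))]
  if (length(bl) > 1 && is.unsorted(rev(bl), strictly = TRUE)) {
    fail("base_load_bw", "must decrease as wedge angle increases")
  }
  bad_loc <- setdiff(cfg$locations, names(location_gains()))
  if (length(bad_loc)) {
    fail("locations", paste("unknown location(s):",
                            paste(bad_loc, collapse = ", ")))
  }
  if (!is.finite(cfg$seed)) fail("seed", "must be a finite integer")
  invisible(cfg)
}

# Relative waveform amplitude at each supported IMU location; the boot sensor
# sits on the instrumented limb and carries the strongest gait signal.
location_gains <- function() {
  c(boot = 1.0, contra_foot = 0.8, contra_shank = 0.6, contra_wrist = 0.3)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects x %d conditions x %d speeds x %d trials x %d strides (fs %g Hz)\n",
              x$n_subjects, length(x$conditions), length(x$speed_labels),
              x$trials_per_cell, x$strides_per_trial, x$fs))
  cat(sprintf("  subject effect SD: %.3g BW / %.3g m/s; stride noise SD: %.3g BW\n",
              x$subject_effect_sd[["load"]], x$subject_effect_sd[["speed"]],
              x$noise_sd[["load"]]))
  invisible(x)
}
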