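#' Generate a synthetic immobilizing-boot walking cohort
#'
#' Simulates walking trials with known ground truth, emulating the statistical
#' structure the monitoring models assume: stride-periodic signals whose
#' amplitude and timing features carry a linear-plus-subject-offset
#' relationship to walking speed and peak Achilles tendon load, with
#' condition-dependent loading (higher load as heel wedges are removed,
#' 0 deg > 5 deg > 30 deg) and within-subject noise.
#'
#' Each trial contains: (a) an insole force trace built from a smooth
#' double-peak stance bump per step, scaled so the sampled peak equals the
#' stride's ground-truth load times body weight, and essentially zero
#' (< 50 N) during swing; (b) a superior-inferior accelerometer channel whose
#' stride oscillation amplitude grows linearly with walking speed plus a
#' heel-strike transient; (c) a lateral-medial gyroscope channel whose
#' extrema scale with cadence; remaining channels are lower-amplitude
#' gait-locked oscillations plus sensor noise; (d) a forward COM trace
#' `x(t) = v t` plus bounded noise. Generation is deterministic given the
#' seed; each subject draws from the substream `seed + subject index`.
#'
#' @param config A [sim_config()].
#' @return A list of class `gait_cohort` with elements `trials` (list of
#'   [trial_recording()]), `ground_truth` (data.frame with one row per stride:
#'   `subject_id`, `condition_deg`, `speed_label`, `trial`, `stride`,
#'   `at_load_bw`, `speed_mps`, and the true heel-strike/toe-off sample
#'   indices `hs_idx`, `to_idx`, `next_hs_idx` on the insole clock), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  trials <- list()
  gt <- list()
  for (i in seq_len(config$n_subjects)) {
    subj <- sprintf("S%02d", i)
    # per-subject substream: subject-level reproducibility when subsetting;
    # the wide spacing keeps nearby global seeds from sharing substreams
    set.seed(substream_seed(config$seed, i * 100003L))
    bw <- 0
    while (bw < 500 || bw > 1000) {
      bw <- stats::rnorm(1, config$body_weight_mean_N, config$body_weight_sd_N)
    }
    load_offset <- stats::rnorm(1, 0, config$subject_effect_sd[["load"]])
    speed_offset <- stats::rnorm(1, 0, config$subject_effect_sd[["speed"]])
    for (cond in config$conditions) {
      for (k in seq_along(config$speed_labels)) {
        v_cell <- max(0.3, config$speed_means_mps[k] + speed_offset)
        for (j in seq_len(config$trials_per_cell)) {
          v_trial <- max(0.3, v_cell + stats::rnorm(1, 0, config$noise_sd[["speed"]]))
          sim <- simulate_trial(config, cond, v_trial, bw, load_offset)
          trial <- trial_recording(
            subject_id = subj, condition_deg = cond,
            speed_label = config$speed_labels[k],
            imus = sim$imus,
            insole_force = sim$force, fs_insole = config$fs,
            com_x = sim$com_x, fs_com = config$fs,
            body_weight_N = bw)
          trials[[length(trials) + 1L]] <- trial
          gt[[length(gt) + 1L]] <- data.frame(
            subject_id = subj, condition_deg = cond,
            speed_label = config$speed_labels[k], trial = j,
            stride = seq_len(config$strides_per_trial),
            at_load_bw = sim$at_load_bw, speed_mps = v_trial,
            hs_idx = sim$hs_idx, to_idx = sim$to_idx,
            next_hs_idx = sim$next_hs_idx)
        }
      }
    }
  }
  structure(list(trials = trials,
                 ground_truth = do.call(rbind, gt),
                 config = config),
            class = "gait_cohort")
}

# Stance vertical-force shape on phase u in [0, 1): weight-acceptance and
# push-off Gaussian bumps over a 0.45 floor. The floor keeps the whole
# stance — including the first stance sample and the mid-stance valley —
# above the 50 N detection threshold for every permitted load, so each step
# registers as exactly one contact.
stance_shape <- function(u) {
  b <- exp(-((u - 0.27) / 0.15)^2) + 0.95 * exp(-((u - 0.73) / 0.15)^2)
  pmax(b, 0.45)
}

# One trial's signals. Strides are laid back-to-back after a 0.3 s lead-in;
# a final terminating contact provides the last stride's closing heel strike.
simulate_trial <- function(config, cond, v_trial, bw, load_offset) {
  fs <- config$fs
  n_strides <- config$strides_per_trial
  lead_n <- round(0.3 * fs)
  tail_n <- round(0.3 * fs)
  base_load <- config$base_load_bw[[as.character(cond)]]
  noise_load <- config$noise_sd[["load"]]
  imu_sd <- config$imu_noise_sd

  # per-stride parameters (final entry is the terminating contact)
  n_blocks <- n_strides + 1L
  dur_s <- pmin(1.6, pmax(0.7, 1.25 - 0.3 * v_trial +
                            stats::rnorm(n_blocks, 0, 0.02)))
  stance_frac <- pmin(0.72, pmax(0.50, 0.62 + stats::rnorm(n_blocks, 0, 0.015)))
  # floor at 0.3 BW: low enough to exercise the 0.5 BW inclusion filter,
  # high enough that the stance valley clears the 50 N contact threshold
  at_load <- pmax(0.3, base_load + config$load_speed_slope * (v_trial - 1.1) +
                    load_offset + stats::rnorm(n_blocks, 0, noise_load))
  amp_jit <- 1 + stats::rnorm(n_blocks, 0, imu_sd)

  n_samp <- pmax(40L, as.integer(round(dur_s * fs)))
  stance_n <- pmax(10L, as.integer(round(stance_frac * n_samp)))
  block_len <- n_samp
  block_len[n_blocks] <- stance_n[n_blocks] + tail_n  # terminating contact

  total_n <- lead_n + sum(block_len)
  force <- stats::runif(total_n, 0, 3)
  gains <- location_gains()[config$locations]
  imu_sig <- lapply(config$locations, function(loc) {
    lapply(imu_channel_names(TRUE), function(ch) numeric(total_n))
  })
  names(imu_sig) <- config$locations
  for (loc in config$locations) names(imu_sig[[loc]]) <- imu_channel_names(TRUE)

  block_start <- lead_n + cumsum(c(0L, block_len[-n_blocks])) + 1L
  for (s in seq_len(n_blocks)) {
    i0 <- block_start[s]
    sn <- stance_n[s]
    u_st <- (seq_len(sn) - 1) / sn
    shape <- stance_shape(u_st)
    peak_force <- at_load[s] * bw
    force[i0:(i0 + sn - 1L)] <- peak_force * shape / max(shape)

    len <- block_len[s]
    u <- (seq_len(len) - 1) / n_samp[s]
    A <- (2 + 4 * v_trial) * amp_jit[s]
    B <- (40 + 150 / dur_s[s]) * amp_jit[s]
    wav <- list(
      acc_si = A * sin(2 * pi * u) + 0.35 * A * exp(-u / 0.04),
      acc_ap = 0.5 * A * sin(4 * pi * u + 0.7),
      acc_ml = 0.3 * A * sin(2 * pi * u + 2.1),
      gyr_si = 0.4 * B * sin(4 * pi * u + 1.3),
      gyr_ap = 0.3 * B * sin(2 * pi * u + 0.5),
      gyr_ml = B * sin(2 * pi * u + pi))
    idx <- i0:(i0 + len - 1L)
    for (loc in config$locations) {
      g <- gains[[loc]]
      for (ch in imu_channel_names(TRUE)) {
        imu_sig[[loc]][[ch]][idx] <- g * wav[[ch]]
      }
    }
  }
  # additive sensor noise, scaled by the configured jitter level
  for (loc in config$locations) {
    for (ch in imu_channel_names(TRUE)) {
      sd0 <- if (startsWith(ch, "acc")) 1.5 * imu_sd else 25 * imu_sd
      if (sd0 > 0) {
        imu_sig[[loc]][[ch]] <- imu_sig[[loc]][[ch]] +
          stats::rnorm(total_n, 0, sd0)
      }
    }
  }
  imus <- lapply(config$locations, function(loc) {
    do.call(imu_channel_set, c(list(location = loc), imu_sig[[loc]],
                               list(fs = fs)))
  })
  names(imus) <- config$locations

  t <- (seq_len(total_n) - 1) / fs
  com_x <- v_trial * t + 0.002 * sin(2 * pi * 0.5 * t + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(total_n, 0, 5e-4)

  hs <- block_start[seq_len(n_strides)]
  list(force = force, imus = imus, com_x = com_x,
       at_load_bw = at_load[seq_len(n_strides)],
       hs_idx = hs,
       to_idx = hs + stance_n[seq_len(n_strides)],
       next_hs_idx = block_start[seq_len(n_strides) + 1L])
}

#' Truncate a trial's insole trace to create a length-mismatch fixture
#'
#' Returns a copy of the trial whose insole recording is shortened by
#' `delta_s` seconds, producing a known-bad input for [check_integrity()].
#'
#' @param trial A [trial_recording()].
#' @param delta_s Seconds to remove from the end of the insole trace (>= 0).
#' @return A [trial_recording()].
#' @export
perturb_recording_length <- function(trial, delta_s) {
  if (delta_s < 0) stopf("perturb_recording_length: delta_s must be >= 0")
  n_cut <- round(delta_s * trial$fs_insole)
  n <- length(trial$insole_force)
  if (n_cut >= n) {
    stopf("perturb_recording_length: cannot truncate %g s from a %g s trace",
          delta_s, n / trial$fs_insole)
  }
  if (n_cut > 0) trial$insole_force <- trial$insole_force[seq_len(n - n_cut)]
  trial
}

#' Write a cohort to disk
#'
#' One directory per trial (`signals.csv` + `meta.json`, see [write_trial()])
#' plus a cohort-level `ground_truth.csv`.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  counter <- new.env()
  for (trial in cohort$trials) {
    key <- paste(trial$subject_id, trial$condition_deg, trial$speed_label,
                 sep = "_")
    n <- (counter[[key]] %||% 0L) + 1L
    counter[[key]] <- n
    write_trial(trial, file.path(path, sprintf("%s_t%02d", key, n)))
  }
  utils::write.csv(cohort$ground_truth, file.path(path, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param path Cohort directory.
#' @return A list with `trials` (list of [trial_recording()]) and
#'   `ground_truth` (data.frame, or `NULL` if absent).
#' @export
load_cohort <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  trials <- lapply(dirs, load_trial)
  gt_path <- file.path(path, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) utils::read.csv(gt_path) else NULL
  structure(list(trials = trials, ground_truth = gt), class = "gait_cohort")
}
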