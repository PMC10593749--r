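# Dataset assembly: trials -> stride-level feature table with targets.

META_COLUMNS <- c("subject_id", "condition_deg", "speed_label", "trial",
                  "stride", "at_peak_bw", "speed_mps", "kept", "com_r_squared")

#' Feature column names of a stride dataset
#'
#' Every column that is not a key, target, or QC column is a feature.
#'
#' @param dataset Data.frame from [build_dataset()] (or its CSV round-trip).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(dataset) {
  setdiff(names(dataset), META_COLUMNS)
}

#' Process one trial into stride-level rows
#'
#' Runs the full per-trial chain: optional IMU decimation, gait event
#' detection on the insole force, stride segmentation, IMU feature
#' extraction, per-stride peak tendon load with the `min_bw` inclusion
#' filter, and the trial walking speed broadcast to all its strides.
#'
#' @param trial A [trial_recording()].
#' @param locations IMU locations to use.
#' @param use_gyro Include gyroscope channels?
#' @param target_fs IMU sampling rate to simulate (100, 50, or 25 Hz).
#' @param lever_ratio Passed to [estimate_achilles_load()].
#' @param min_bw Passed to [peak_load_per_stride()].
#' @param threshold_N Contact threshold for [detect_gait_events()].
#' @return Data.frame of stride rows (possibly zero rows).
#' @export
process_trial <- function(trial, locations = names(trial$imus),
                          use_gyro = TRUE, target_fs = NULL,
                          lever_ratio = 1, min_bw = 0.5, threshold_N = 50) {
  if (!is.null(target_fs)) trial <- decimate_trial(trial, target_fs)
  events <- detect_gait_events(trial$insole_force, trial$fs_insole,
                               threshold_N = threshold_N)
  strides <- segment_strides(events, trial$fs_insole)
  feats <- extract_features(trial, strides, locations = locations,
                            use_gyro = use_gyro)
  load <- estimate_achilles_load(trial$insole_force, trial$body_weight_N,
                                 lever_ratio = lever_ratio)
  peaks <- peak_load_per_stride(load, strides, min_bw = min_bw)
  speed <- trial_walking_speed(trial$com_x, trial$fs_com)
  n <- nrow(strides)
  key <- data.frame(subject_id = rep(trial$subject_id, n),
                    condition_deg = rep(trial$condition_deg, n),
                    speed_label = rep(trial$speed_label, n),
                    stride = seq_len(n))
  cbind(key, feats, peaks,
        data.frame(speed_mps = rep(speed$speed_mps, n),
                   com_r_squared = rep(speed$r_squared, n)))
}

#' Assemble the stride-level dataset for a set of trials
#'
#' Applies the recording-integrity screen, then [process_trial()] per
#' accepted trial, numbering trials within each subject x condition x speed
#' cell. Attrition counts (trials rejected, strides segmented, strides
#' dropped by the minimum-load filter) are attached as the `"attrition"`
#' attribute and reported via `message()`.
#'
#' @param trials List of [trial_recording()] (e.g. `cohort$trials`).
#' @param locations,use_gyro,target_fs,lever_ratio,min_bw,threshold_N As in
#'   [process_trial()].
#' @param integrity_tol_s Recording-length tolerance in seconds (default 0.1).
#' @param quiet Suppress attrition messages?
#' @return Data.frame of stride rows; rows with `kept == FALSE` are retained
#'   (flagged) so downstream callers can audit the filter, but evaluation
#'   functions use only kept rows.
#' @export
build_dataset <- function(trials, locations = NULL, use_gyro = TRUE,
                          target_fs = NULL, lever_ratio = 1, min_bw = 0.5,
                          threshold_N = 50, integrity_tol_s = 0.1,
                          quiet = FALSE) {
  rows <- list()
  n_rejected <- 0L
  counter <- new.env()
  for (trial in trials) {
    rep_ <- check_integrity(trial, tolerance_s = integrity_tol_s)
    if (!rep_$accepted) {
      n_rejected <- n_rejected + 1L
      next
    }
    loc <- locations %||% names(trial$imus)
    df <- process_trial(trial, locations = loc, use_gyro = use_gyro,
                        target_fs = target_fs, lever_ratio = lever_ratio,
                        min_bw = min_bw, threshold_N = threshold_N)
    key <- paste(trial$subject_id, trial$condition_deg, trial$speed_label,
                 sep = "_")
    tn <- (counter[[key]] %||% 0L) + 1L
    counter[[key]] <- tn
    df$trial <- tn
    rows[[length(rows) + 1L]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  n_seg <- nrow(out)
  n_dropped <- if (n_seg) sum(!out$kept) else 0L
  attrition <- c(trials_in = length(trials), trials_rejected = n_rejected,
                 strides_segmented = n_seg, strides_dropped_min_bw = n_dropped,
                 strides_kept = n_seg - n_dropped)
  if (!quiet) {
    message(sprintf(
      "build_dataset: %d/%d trials accepted; %d strides segmented, %d dropped by the %.2g BW filter, %d kept",
      length(trials) - n_rejected, length(trials), n_seg, n_dropped, min_bw,
      n_seg - n_dropped))
  }
  attr(out, "attrition") <- attrition
  out
}

#' Write / read a stride dataset as CSV
#'
#' @param dataset Data.frame from [build_dataset()].
#' @param path CSV file path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_features_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
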