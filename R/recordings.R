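#' Construct a six-channel IMU recording for one body location
#'
#' Channels follow the anatomical axis convention: superior-inferior (SI),
#' anterior-posterior (AP), and lateral-medial (ML), for the accelerometer
#' (m/s^2) and gyroscope (deg/s).
#'
#' @param location One of `"boot"`, `"contra_wrist"`, `"contra_shank"`,
#'   `"contra_foot"`.
#' @param acc_si,acc_ap,acc_ml Accelerometer series, m/s^2.
#' @param gyr_si,gyr_ap,gyr_ml Gyroscope series, deg/s.
#' @param fs Sampling rate in Hz.
#' @return An object of class `imu_channel_set`.
#' @export
imu_channel_set <- function(location, acc_si, acc_ap, acc_ml,
                            gyr_si, gyr_ap, gyr_ml, fs) {
  lens <- lengths(list(acc_si, acc_ap, acc_ml, gyr_si, gyr_ap, gyr_ml))
  if (length(unique(lens)) != 1L) {
    stopf("imu_channel_set: all six channels must have equal length")
  }
  if (lens[1L] == 0L) stopf("imu_channel_set: channels must be non-empty")
  if (!fs > 0) stopf("imu_channel_set: fs must be > 0")
  structure(list(location = location,
                 acc_si = acc_si, acc_ap = acc_ap, acc_ml = acc_ml,
                 gyr_si = gyr_si, gyr_ap = gyr_ap, gyr_ml = gyr_ml,
                 fs = fs),
            class = "imu_channel_set")
}

imu_channel_names <- function(use_gyro = TRUE) {
  acc <- c("acc_si", "acc_ap", "acc_ml")
  if (use_gyro) c(acc, c("gyr_si", "gyr_ap", "gyr_ml")) else acc
}

#' Construct a trial recording
#'
#' One walking pass: per-location IMU channel sets, total plantar force from
#' the instrumented insole, a forward center-of-mass (COM) position trace,
#' and trial metadata.
#'
#' @param subject_id Subject label.
#' @param condition_deg Heel-wedge angle, one of 30, 5, 0 (degrees).
#' @param speed_label Self-selected speed category label.
#' @param imus Named list of [imu_channel_set()] objects, keyed by location.
#' @param insole_force Total plantar force series, Newtons.
#' @param fs_insole Insole sampling rate, Hz.
#' @param com_x Forward COM position series, metres.
#' @param fs_com COM sampling rate, Hz.
#' @param body_weight_N Subject body weight, Newtons (> 0).
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, condition_deg, speed_label, imus,
                            insole_force, fs_insole, com_x, fs_com,
                            body_weight_N) {
  if (!is.numeric(body_weight_N) || body_weight_N <= 0) {
    stopf("trial_recording: body_weight_N must be > 0")
  }
  if (!condition_deg %in% c(30, 5, 0)) {
    stopf("trial_recording: condition_deg must be one of 30, 5, 0")
  }
  if (length(insole_force) == 0L) {
    stopf("trial_recording: insole_force must be non-empty")
  }
  if (length(imus) == 0L || is.null(names(imus))) {
    stopf("trial_recording: imus must be a named list of imu_channel_set")
  }
  structure(list(subject_id = as.character(subject_id),
                 condition_deg = condition_deg,
                 speed_label = as.character(speed_label),
                 imus = imus,
                 insole_force = insole_force, fs_insole = fs_insole,
                 com_x = com_x, fs_com = fs_com,
                 body_weight_N = body_weight_N),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  imu <- x$imus[[1L]]
  cat(sprintf("<trial_recording> subject %s, wedge %g deg, speed '%s'\n",
              x$subject_id, x$condition_deg, x$speed_label))
  cat(sprintf("  IMU: %s @ %g Hz (%.1f s); insole @ %g Hz (%.1f s); BW %.0f N\n",
              paste(names(x$imus), collapse = "+"), imu$fs,
              length(imu$acc_si) / imu$fs, x$fs_insole,
              length(x$insole_force) / x$fs_insole, x$body_weight_N))
  invisible(x)
}

#' Screen a trial for stream-length agreement
#'
#' Trials whose insole and IMU recordings differ in duration by more than the
#' tolerance indicate a synchronization fault and are rejected from analysis.
#'
#' @param trial A [trial_recording()].
#' @param tolerance_s Maximum permitted duration mismatch in seconds
#'   (default 0.1 s).
#' @return A list of class `integrity_report` with elements `accepted`,
#'   `duration_imu_s`, `duration_insole_s`, and `reason`.
#' @export
check_integrity <- function(trial, tolerance_s = 0.1) {
  if (tolerance_s < 0) stopf("check_integrity: tolerance_s must be >= 0")
  imu <- trial$imus[[1L]]
  dur_imu <- length(imu$acc_si) / imu$fs
  dur_ins <- length(trial$insole_force) / trial$fs_insole
  gap <- abs(dur_imu - dur_ins)
  accepted <- gap <= tolerance_s
  reason <- if (accepted) {
    "recording lengths agree"
  } else {
    sprintf("recording length mismatch of %.3f s exceeds tolerance %.3f s",
            gap, tolerance_s)
  }
  structure(list(accepted = accepted, duration_imu_s = dur_imu,
                 duration_insole_s = dur_ins, reason = reason),
            class = "integrity_report")
}

#' Decimate a trial's IMU streams to simulate a slower sensor
#'
#' Keeps every k-th IMU sample (k = fs / `target_fs`) starting at the first
#' sample, with no anti-alias filtering: the aim is to emulate a sensor that
#' natively samples at the lower rate, and such a sensor applies no digital
#' pre-filter. Insole and COM streams come from lab-grade equipment and are
#' left untouched.
#'
#' @param trial A [trial_recording()].
#' @param target_fs Target IMU sampling rate in Hz; must divide the current
#'   rate evenly (e.g. 100 -> 50 or 100 -> 25).
#' @return A [trial_recording()] with decimated IMU channel sets.
#' @export
decimate_trial <- function(trial, target_fs) {
  fs <- trial$imus[[1L]]$fs
  if (target_fs == fs) return(trial)
  k <- fs / target_fs
  if (k < 1 || abs(k - round(k)) > 1e-9) {
    stopf("decimate_trial: target_fs %g does not divide fs %g evenly",
          target_fs, fs)
  }
  k <- as.integer(round(k))
  trial$imus <- lapply(trial$imus, function(imu) {
    idx <- seq.int(1L, length(imu$acc_si), by = k)
    for (ch in imu_channel_names(TRUE)) imu[[ch]] <- imu[[ch]][idx]
    imu$fs <- target_fs
    imu
  })
  trial
}

#' Write a trial recording to a directory
#'
#' Writes `signals.csv` (columns `time_s`, `<location>_<channel>` for every
#' IMU channel, `insole_force_n`, `com_x_m`) and `meta.json` (keys `subject`,
#' `condition_deg`, `speed_label`, `fs_hz`, `body_weight_n`). All streams must
#' share one sampling rate (as produced by the generator).
#'
#' @param trial A [trial_recording()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  imu_fs <- trial$imus[[1L]]$fs
  if (imu_fs != trial$fs_insole || imu_fs != trial$fs_com) {
    stopf("write_trial: all streams must share one sampling rate")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(trial$insole_force)
  df <- data.frame(time_s = (seq_len(n) - 1) / imu_fs)
  for (loc in names(trial$imus)) {
    imu <- trial$imus[[loc]]
    for (ch in imu_channel_names(TRUE)) {
      df[[paste(loc, ch, sep = "_")]] <- imu[[ch]]
    }
  }
  df$insole_force_n <- trial$insole_force
  df$com_x_m <- trial$com_x
  utils::write.csv(df, file.path(path, "signals.csv"), row.names = FALSE)
  meta <- list(subject = trial$subject_id,
               condition_deg = trial$condition_deg,
               speed_label = trial$speed_label,
               fs_hz = imu_fs,
               body_weight_n = trial$body_weight_N)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trial recording from a directory
#'
#' Reads the `signals.csv` + `meta.json` dialect written by [write_trial()].
#' IMU locations are discovered from the column prefixes; missing optional
#' locations are tolerated.
#'
#' @param path Directory containing `signals.csv` and `meta.json`.
#' @return A [trial_recording()].
#' @export
load_trial <- function(path) {
  sig_path <- file.path(path, "signals.csv")
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(sig_path)) stopf("load_trial: missing %s", sig_path)
  if (!file.exists(meta_path)) stopf("load_trial: missing %s", meta_path)
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) {
                     stopf("load_trial: malformed JSON in %s: %s",
                           meta_path, conditionMessage(e))
                   })
  for (key in c("subject", "condition_deg", "speed_label", "fs_hz",
                "body_weight_n")) {
    if (is.null(meta[[key]])) {
      stopf("load_trial: meta.json is missing required key '%s'", key)
    }
  }
  df <- tryCatch(utils::read.csv(sig_path),
                 error = function(e) {
                   stopf("load_trial: malformed CSV in %s: %s",
                         sig_path, conditionMessage(e))
                 })
  for (col in c("time_s", "insole_force_n", "com_x_m")) {
    if (!col %in% names(df)) {
      stopf("load_trial: signals.csv is missing required column '%s'", col)
    }
  }
  if (anyNA(df$time_s) || is.unsorted(df$time_s, strictly = TRUE)) {
    stopf("load_trial: non-monotone time_s in %s", sig_path)
  }
  fs <- meta$fs_hz
  imus <- list()
  for (loc in names(location_gains())) {
    cols <- paste(loc, imu_channel_names(TRUE), sep = "_")
    if (all(cols %in% names(df))) {
      imus[[loc]] <- imu_channel_set(
        loc,
        acc_si = df[[cols[1L]]], acc_ap = df[[cols[2L]]],
        acc_ml = df[[cols[3L]]],
        gyr_si = df[[cols[4L]]], gyr_ap = df[[cols[5L]]],
        gyr_ml = df[[cols[6L]]], fs = fs)
    }
  }
  if (length(imus) == 0L) {
    stopf("load_trial: no complete IMU location found in %s", sig_path)
  }
  trial_recording(subject_id = meta$subject,
                  condition_deg = meta$condition_deg,
                  speed_label = meta$speed_label,
                  imus = imus,
                  insole_force = df$insole_force_n, fs_insole = fs,
                  com_x = df$com_x_m, fs_com = fs,
                  body_weight_N = meta$body_weight_n)
}
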