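# Sensor-configuration ablations, learning curves, sensor agreement.

#' Default sensor-configuration ablation grid
#'
#' Five configurations: the full baseline (boot IMU, accelerometer +
#' gyroscope, 100 Hz), gyroscope removed, 50 Hz and 25 Hz decimation, and a
#' two-sensor configuration adding the contralateral foot.
#'
#' @return List of sensor configs, each with `locations`, `use_gyro`, `fs`.
#' @export
default_sensor_grid <- function() {
  list(
    list(locations = "boot", use_gyro = TRUE, fs = 100),
    list(locations = "boot", use_gyro = FALSE, fs = 100),
    list(locations = "boot", use_gyro = TRUE, fs = 50),
    list(locations = "boot", use_gyro = TRUE, fs = 25),
    list(locations = c("boot", "contra_foot"), use_gyro = TRUE, fs = 100)
  )
}

#' Run the sensor-configuration ablation grid
#'
#' For every grid row the pipeline is re-run from the raw 100 Hz recordings
#' (decimation changes the extracted features, so features are re-extracted
#' per configuration): decimate, segment, extract, evaluate.
#'
#' @param trials List of raw 100 Hz [trial_recording()]s.
#' @param grid List of sensor configs (see [default_sensor_grid()]).
#' @param paradigms Paradigms to evaluate per configuration.
#' @param config A [model_config()].
#' @param conditions,targets Passed to [evaluate_all()].
#' @param split_seed Seed for the shared split plan.
#' @param ... Further arguments to [build_dataset()] (e.g. `min_bw`,
#'   `lever_ratio`, `quiet`).
#' @return List of `eval_result` objects across all grid rows; use
#'   [results_table()] to flatten.
#' @export
run_ablation_grid <- function(trials, grid = default_sensor_grid(),
                              paradigms = "generalized",
                              config = model_config(),
                              conditions = NULL, targets = c("at_peak_bw",
                                                             "speed_mps"),
                              split_seed = 1L, ...) {
  known <- names(location_gains())
  results <- list()
  for (sc in grid) {
    bad <- setdiff(sc$locations, known)
    if (length(bad)) {
      stopf("run_ablation_grid: unknown location(s): %s",
            paste(bad, collapse = ", "))
    }
    dataset <- build_dataset(trials, locations = sc$locations,
                             use_gyro = sc$use_gyro, target_fs = sc$fs, ...)
    conds <- conditions %||% sort(unique(dataset$condition_deg),
                                  decreasing = TRUE)
    res <- evaluate_all(dataset, config = config, conditions = conds,
                        targets = targets, paradigms = paradigms,
                        split_seed = split_seed, sensor_config = sc)
    results <- c(results, res)
  }
  results
}

#' Learning curve under leave-one-subject-out testing
#'
#' For each training-set fraction, the generalized evaluation is repeated
#' with every training set subsampled (at stride level, seeded) to that
#' fraction of its rows, and the across-subject mean MAPE is averaged over
#' `n_reps` resampling repetitions. A fraction of 1 reproduces
#' [evaluate_generalized()].
#'
#' @param dataset Stride dataset.
#' @param condition Heel-wedge condition to evaluate.
#' @param target Target column.
#' @param fractions Training fractions in (0, 1].
#' @param config A [model_config()].
#' @param n_reps Resampling repetitions per fraction (default 5).
#' @param seed Seed for the subsampling substreams.
#' @return Data.frame with columns `fraction`, `mape`, and `delta` (change
#'   from the previous fraction; `NA` for the first).
#' @export
learning_curve <- function(dataset, condition, target,
                           fractions = seq(0.1, 1, by = 0.1),
                           config = model_config(), n_reps = 5, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) {
    stopf("learning_curve: fractions must lie in (0, 1]")
  }
  idx <- condition_rows(dataset, condition)
  subjects <- eval_subjects(dataset, idx)
  curve <- vapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    reps <- vapply(seq_len(n_reps), function(rep_i) {
      mapes <- vapply(subjects, function(s) {
        test_idx <- idx[dataset$subject_id[idx] == s]
        train_idx <- setdiff(idx, test_idx)
        n_take <- max(1L, round(f * length(train_idx)))
        if (n_take < config$inner_cv_folds) {
          stopf("learning_curve: fraction %.3g yields %d rows, fewer than %d inner folds",
                f, n_take, config$inner_cv_folds)
        }
        if (n_take < length(train_idx)) {
          set.seed(substream_seed(seed, fi * 1000L + rep_i * 37L +
                                    match(s, subjects)))
          train_idx <- sample(train_idx, n_take)
        }
        fit <- fit_l1(dataset[train_idx, , drop = FALSE], target, config)
        mape(dataset[[target]][test_idx],
             predict(fit, dataset[test_idx, , drop = FALSE]))
      }, numeric(1L))
      mean(mapes)
    }, numeric(1L))
    mean(reps)
  }, numeric(1L))
  data.frame(fraction = fractions, mape = curve,
             delta = c(NA, diff(curve)))
}

#' Cross-correlation agreement between two sensors
#'
#' Maximum over integer lags of the normalized (zero-mean, unit-energy)
#' cross-correlation between two equally sampled series, expressed in
#' percent. The normalization is computed on the overlapping segment at each
#' lag, so a pure delay of one signal still scores 100%. The signed maximum
#' is reported: anti-phase signals score poorly. The caller averages across
#' channels when comparing full IMUs.
#'
#' @param sig_a,sig_b Series at the same sampling rate.
#' @param fs Sampling rate, Hz.
#' @param max_lag_s Lag search bound in seconds (default 1; synchronization
#'   error is assumed small, and an unbounded search invites spurious
#'   maxima).
#' @return List with `agreement_pct` and `lag_s`.
#' @export
sensor_agreement <- function(sig_a, sig_b, fs, max_lag_s = 1) {
  if (stats::sd(sig_a) == 0 || stats::sd(sig_b) == 0) {
    stopf("sensor_agreement: constant series have undefined correlation")
  }
  max_lag <- min(as.integer(round(max_lag_s * fs)),
                 length(sig_a) - 2L, length(sig_b) - 2L)
  best <- -Inf
  best_lag <- 0L
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      a <- sig_a[1:(length(sig_a) - lag)]
      b <- sig_b[(1 + lag):length(sig_b)]
    } else {
      a <- sig_a[(1 - lag):length(sig_a)]
      b <- sig_b[1:(length(sig_b) + lag)]
    }
    n <- min(length(a), length(b))
    a <- a[seq_len(n)]
    b <- b[seq_len(n)]
    if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best) {
      best <- r
      best_lag <- lag
    }
  }
  list(agreement_pct = 100 * best, lag_s = best_lag / fs)
}
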