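# Training paradigms and aggregation of subject-level MAPE.

#' Per-subject 50/50 stride split plan
#'
#' Randomly partitions each subject's kept strides into two halves (sizes
#' differing by at most one), at stride level with a fixed seed. The same
#' plan is meant to be shared between the hybridized and personalized
#' paradigms so their test sets coincide and paradigm comparisons are paired.
#'
#' @param dataset Stride dataset (kept rows are split; rows are addressed by
#'   position within `dataset`).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: a list with `train` and `test`,
#'   each a named list of integer row indices per subject, plus `seed`.
#' @export
split_plan <- function(dataset, seed = 1L) {
  kept_idx <- which(dataset$kept)
  subjects <- sort(unique(dataset$subject_id[kept_idx]))
  set.seed(substream_seed(seed, 0))
  train <- list()
  test <- list()
  for (s in subjects) {
    idx <- kept_idx[dataset$subject_id[kept_idx] == s]
    n_tr <- floor(length(idx) / 2)
    tr <- sort(sample(idx, n_tr))
    train[[s]] <- tr
    test[[s]] <- setdiff(idx, tr)
  }
  structure(list(train = train, test = test, seed = seed),
            class = "split_plan")
}

aggregate_eval <- function(paradigm, condition, target, per_subject_mape,
                           sensor_config = NULL) {
  m <- unlist(per_subject_mape)
  structure(list(paradigm = paradigm, condition_deg = condition,
                 target = target,
                 sensor_config = sensor_config,
                 per_subject_mape = m,
                 mape_mean = mean(m),
                 mape_sd = if (length(m) > 1L) stats::sd(m) else 0,
                 grade = mape_grade(mean(m))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s, %g deg, %s: MAPE %.2f +/- %.2f %% (%s, %d subjects)\n",
              x$paradigm, x$condition_deg, x$target, x$mape_mean, x$mape_sd,
              x$grade, length(x$per_subject_mape)))
  invisible(x)
}

condition_rows <- function(dataset, condition) {
  which(dataset$kept & dataset$condition_deg == condition)
}

eval_subjects <- function(dataset, idx) {
  subjects <- sort(unique(dataset$subject_id[idx]))
  if (length(subjects) < 2L) {
    stopf("evaluation: need >= 2 subjects with kept strides in condition")
  }
  subjects
}

#' Generalized paradigm: leave-one-subject-out cross-validation
#'
#' The dataset is partitioned by subject; each subject in turn is held out
#' entirely, a model is fit on every other subject's kept strides, and the
#' held-out subject's MAPE is computed on all of their kept strides. The
#' per-subject MAPEs are aggregated as mean and SD, each subject weighting
#' equally.
#'
#' @param dataset Stride dataset from [build_dataset()].
#' @param condition Heel-wedge condition (deg) to evaluate.
#' @param target Target column, `"at_peak_bw"` or `"speed_mps"`.
#' @param config A [model_config()].
#' @param sensor_config Optional descriptive list attached to the result.
#' @return An `eval_result`.
#' @export
evaluate_generalized <- function(dataset, condition, target,
                                 config = model_config(),
                                 sensor_config = NULL) {
  idx <- condition_rows(dataset, condition)
  subjects <- eval_subjects(dataset, idx)
  mapes <- list()
  for (s in subjects) {
    test_idx <- idx[dataset$subject_id[idx] == s]
    train_idx <- setdiff(idx, test_idx)
    if (length(test_idx) == 0L) {
      warning(sprintf("subject %s has no kept strides; excluded", s))
      next
    }
    fit <- fit_l1(dataset[train_idx, , drop = FALSE], target, config)
    pred <- predict(fit, dataset[test_idx, , drop = FALSE])
    mapes[[s]] <- mape(dataset[[target]][test_idx], pred)
  }
  aggregate_eval("generalized", condition, target, mapes, sensor_config)
}

#' Hybridized paradigm: other subjects' data plus half of the test subject's
#'
#' For each subject, the training set is every other subject's kept strides
#' plus the subject's own training half from the shared [split_plan()]; the
#' model is tested on the remaining half.
#'
#' @inheritParams evaluate_generalized
#' @param split A [split_plan()] built on the same dataset.
#' @return An `eval_result`.
#' @export
evaluate_hybridized <- function(dataset, condition, target, split,
                                config = model_config(),
                                sensor_config = NULL) {
  evaluate_with_split(dataset, condition, target, split, config,
                      paradigm = "hybridized", sensor_config)
}

#' Personalized paradigm: the subject's own data only
#'
#' For each subject, a model is trained solely on that subject's training
#' half and tested on their remaining half; other subjects' data never enter
#' the fit.
#'
#' @inheritParams evaluate_hybridized
#' @return An `eval_result`.
#' @export
evaluate_personalized <- function(dataset, condition, target, split,
                                  config = model_config(),
                                  sensor_config = NULL) {
  evaluate_with_split(dataset, condition, target, split, config,
                      paradigm = "personalized", sensor_config)
}

evaluate_with_split <- function(dataset, condition, target, split, config,
                                paradigm, sensor_config = NULL) {
  if (!inherits(split, "split_plan")) {
    stopf("evaluate_%s: 'split' must be a split_plan", paradigm)
  }
  idx <- condition_rows(dataset, condition)
  subjects <- eval_subjects(dataset, idx)
  mapes <- list()
  for (s in subjects) {
    own_train <- intersect(split$train[[s]] %||% integer(0), idx)
    own_test <- intersect(split$test[[s]] %||% integer(0), idx)
    if (length(own_test) == 0L || length(own_train) == 0L) {
      warning(sprintf("subject %s has no split strides in condition; excluded",
                      s))
      next
    }
    train_idx <- if (paradigm == "hybridized") {
      c(setdiff(idx, c(own_train, own_test)), own_train)
    } else {
      own_train
    }
    fit <- fit_l1(dataset[train_idx, , drop = FALSE], target, config)
    pred <- predict(fit, dataset[own_test, , drop = FALSE])
    mapes[[s]] <- mape(dataset[[target]][own_test], pred)
  }
  aggregate_eval(paradigm, condition, target, mapes, sensor_config)
}

#' Run all paradigms over all conditions and targets
#'
#' The baseline experiment grid: 3 conditions x 3 paradigms x 2 targets
#' (18 cells with the default cohort). The split plan is shared between the
#' hybridized and personalized paradigms.
#'
#' @param dataset Stride dataset.
#' @param config A [model_config()].
#' @param conditions Conditions to evaluate (default: those present).
#' @param targets Target columns (default both).
#' @param paradigms Paradigms to run.
#' @param split_seed Seed for the shared [split_plan()].
#' @param sensor_config Optional descriptive list attached to every result.
#' @return List of `eval_result` objects.
#' @export
evaluate_all <- function(dataset, config = model_config(),
                         conditions = sort(unique(dataset$condition_deg),
                                           decreasing = TRUE),
                         targets = c("at_peak_bw", "speed_mps"),
                         paradigms = c("generalized", "hybridized",
                                       "personalized"),
                         split_seed = 1L, sensor_config = NULL) {
  split <- split_plan(dataset, seed = split_seed)
  results <- list()
  for (cond in conditions) {
    for (target in targets) {
      for (p in paradigms) {
        res <- switch(p,
          generalized = evaluate_generalized(dataset, cond, target, config,
                                             sensor_config),
          hybridized = evaluate_hybridized(dataset, cond, target, split,
                                           config, sensor_config),
          personalized = evaluate_personalized(dataset, cond, target, split,
                                               config, sensor_config),
          stopf("evaluate_all: unknown paradigm '%s'", p))
        results[[length(results) + 1L]] <- res
      }
    }
  }
  results
}

#' Flatten evaluation results to a table
#'
#' @param results List of `eval_result` objects.
#' @return Data.frame with one row per cell: `paradigm`, `condition_deg`,
#'   `target`, `locations`, `use_gyro`, `fs_hz`, `mape_mean`, `mape_sd`,
#'   `grade`.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    sc <- r$sensor_config %||% list()
    data.frame(paradigm = r$paradigm, condition_deg = r$condition_deg,
               target = r$target,
               locations = paste(sc$locations %||% NA, collapse = "+"),
               use_gyro = sc$use_gyro %||% NA,
               fs_hz = sc$fs %||% NA,
               mape_mean = r$mape_mean, mape_sd = r$mape_sd,
               grade = r$grade)
  }))
}
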