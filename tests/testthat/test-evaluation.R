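# Training paradigms, split plans, aggregation, sensor agreement.

# a hand-built dataset with an exact linear target shared by two subjects
exact_linear_dataset <- function(n_per = 30, seed = 21) {
  set.seed(seed)
  df <- data.frame(subject_id = rep(c("A", "B"), each = n_per),
                   condition_deg = 0,
                   speed_label = "medium",
                   trial = 1L,
                   stride = rep(seq_len(n_per), 2),
                   f1 = rnorm(2 * n_per, 2), f2 = rnorm(2 * n_per, 1))
  df$at_peak_bw <- 2 + 0.8 * df$f1 + 0.3 * df$f2
  df$speed_mps <- 1.2
  df$kept <- TRUE
  df$com_r_squared <- 1
  df
}

test_that("exchangeable subjects with an exact linear target give near-zero MAPE", {
  ds <- exact_linear_dataset()
  res <- evaluate_generalized(ds, 0, "at_peak_bw",
                              model_config(penalty_grid = 1e-8))
  expect_length(res$per_subject_mape, 2L)
  expect_lt(res$mape_mean, 0.1)
  expect_lt(res$mape_sd, 0.1)
  expect_equal(res$grade, "excellent")
})

test_that("n subjects yield n per-subject MAPE entries and exact aggregation", {
  ds <- small_dataset()
  res <- evaluate_generalized(ds, 30, "speed_mps", cheap_config())
  expect_length(res$per_subject_mape, 4L)
  expect_equal(res$mape_mean, mean(res$per_subject_mape), tolerance = 1e-12)
  expect_equal(res$mape_sd, sd(res$per_subject_mape), tolerance = 1e-12)
})

test_that("split plans partition each subject's kept strides into near-equal disjoint halves", {
  ds <- small_dataset()
  sp <- split_plan(ds, seed = 3)
  for (s in names(sp$train)) {
    tr <- sp$train[[s]]
    te <- sp$test[[s]]
    expect_length(intersect(tr, te), 0L)
    all_s <- which(ds$kept & ds$subject_id == s)
    expect_setequal(c(tr, te), all_s)
    expect_lte(abs(length(tr) - length(te)), 1L)
  }
  # same seed, same plan; hybridized and personalized share test sets
  sp2 <- split_plan(ds, seed = 3)
  expect_identical(sp, sp2)
})

test_that("personalized models are independent of other subjects' data", {
  ds <- exact_linear_dataset(n_per = 40)
  sp <- split_plan(ds, seed = 1)
  cfgm <- model_config(penalty_grid = 1e-8)
  base <- evaluate_personalized(ds, 0, "at_peak_bw", sp, cfgm)

  tampered <- ds
  rows_b <- tampered$subject_id == "B"
  tampered$at_peak_bw[rows_b] <- sample(tampered$at_peak_bw[rows_b])
  tampered$f1[rows_b] <- rev(tampered$f1[rows_b])
  after <- evaluate_personalized(tampered, 0, "at_peak_bw", sp, cfgm)
  expect_equal(after$per_subject_mape[["A"]], base$per_subject_mape[["A"]],
               tolerance = 1e-12)

  # with an exact linear per-subject relation the personalized error vanishes
  expect_lt(base$per_subject_mape[["A"]], 1e-4)
})

test_that("a subject-specific offset makes generalized worse than personalized", {
  ds <- exact_linear_dataset(n_per = 40)
  ds$at_peak_bw <- ds$at_peak_bw + ifelse(ds$subject_id == "A", 0.8, -0.8)
  sp <- split_plan(ds, seed = 2)
  cfgm <- model_config(penalty_grid = 1e-6)
  gen <- evaluate_generalized(ds, 0, "at_peak_bw", cfgm)
  per <- evaluate_personalized(ds, 0, "at_peak_bw", sp, cfgm)
  expect_gt(gen$mape_mean, per$mape_mean)
  expect_gt(gen$mape_mean, 10)
  expect_lt(per$mape_mean, 1)
})

test_that("the baseline grid covers 3 conditions x 3 paradigms x 2 targets", {
  ds <- small_dataset()
  results <- evaluate_all(ds, config = cheap_config(), split_seed = 4)
  expect_length(results, 18L)
  tab <- results_table(results)
  expect_equal(nrow(tab), 18L)
  expect_equal(sort(unique(tab$condition_deg)), c(0, 5, 30))
  expect_setequal(unique(tab$paradigm),
                  c("generalized", "hybridized", "personalized"))
  expect_setequal(unique(tab$target), c("at_peak_bw", "speed_mps"))
  expect_true(all(tab$grade %in% c("excellent", "acceptable",
                                   "unacceptable")))
})

test_that("identity ablation row reproduces the baseline evaluation exactly", {
  coh <- small_cohort()
  baseline_ds <- build_dataset(coh$trials, locations = "boot",
                               use_gyro = TRUE, quiet = TRUE)
  base <- evaluate_all(baseline_ds, config = cheap_config(),
                       conditions = 0, targets = "at_peak_bw",
                       paradigms = "generalized", split_seed = 4)
  abl <- run_ablation_grid(coh$trials,
                           grid = list(list(locations = "boot",
                                            use_gyro = TRUE, fs = 100)),
                           paradigms = "generalized",
                           config = cheap_config(), conditions = 0,
                           targets = "at_peak_bw", split_seed = 4,
                           quiet = TRUE)
  expect_equal(abl[[1]]$per_subject_mape, base[[1]]$per_subject_mape,
               tolerance = 1e-12)
  expect_error(run_ablation_grid(coh$trials,
                                 grid = list(list(locations = "hip",
                                                  use_gyro = TRUE,
                                                  fs = 100))),
               "hip")
})

test_that("the default ablation grid matches the five published sensor configurations", {
  grid <- default_sensor_grid()
  expect_length(grid, 5L)
  expect_equal(grid[[1]], list(locations = "boot", use_gyro = TRUE, fs = 100))
  expect_equal(grid[[2]], list(locations = "boot", use_gyro = FALSE, fs = 100))
  expect_equal(grid[[3]]$fs, 50)
  expect_equal(grid[[4]]$fs, 25)
  expect_equal(grid[[5]]$locations, c("boot", "contra_foot"))
})

test_that("learning curve at fraction 1 reproduces the generalized evaluation", {
  ds <- small_dataset()
  cfgm <- cheap_config(seed = 6)
  gen <- evaluate_generalized(ds, 0, "speed_mps", cfgm)
  curve <- learning_curve(ds, 0, "speed_mps", fractions = c(0.5, 1),
                          config = cfgm, n_reps = 2, seed = 8)
  expect_equal(nrow(curve), 2L)
  expect_equal(curve$mape[2], gen$mape_mean, tolerance = 1e-12)
  expect_true(is.na(curve$delta[1]))
  expect_equal(curve$delta[2], diff(curve$mape))
  expect_error(learning_curve(ds, 0, "speed_mps", fractions = c(0, 0.5)),
               "fractions")
})

test_that("sensor agreement: identity, pure delay, anti-phase, and degenerate input", {
  set.seed(33)
  sig <- cumsum(rnorm(400))  # non-periodic, so anti-phase cannot realign
  self <- sensor_agreement(sig, sig, fs = 100)
  expect_equal(self$agreement_pct, 100, tolerance = 1e-9)
  expect_equal(self$lag_s, 0)

  delayed <- c(numeric(10) + sig[1], sig)[1:length(sig)]
  del <- sensor_agreement(sig, delayed, fs = 100)
  expect_equal(del$agreement_pct, 100, tolerance = 1e-6)
  expect_equal(abs(del$lag_s), 0.1)

  anti <- sensor_agreement(sig, -sig, fs = 100)
  expect_lt(anti$agreement_pct, 50)

  expect_error(sensor_agreement(rep(1, 100), sig, fs = 100), "constant")
})
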