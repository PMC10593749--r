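# Synthetic cohort generator: determinism, ground-truth structure, and the
# physical guarantees the downstream pipeline relies on.

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_subjects = 2, trials_per_cell = 1,
                    strides_per_trial = 4, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$trials[[1]]$insole_force, b$trials[[1]]$insole_force)
  expect_identical(a$trials[[5]]$imus$boot$gyr_ml, b$trials[[5]]$imus$boot$gyr_ml)
})

test_that("zero noise and zero subject effect make load an exact function of condition and speed", {
  cfg <- sim_config(n_subjects = 3, trials_per_cell = 2, strides_per_trial = 4,
                    subject_effect_sd = c(load = 0, speed = 0),
                    noise_sd = c(load = 0, speed = 0), seed = 7)
  gt <- generate_cohort(cfg)$ground_truth
  cell_var <- tapply(gt$at_load_bw,
                     interaction(gt$condition_deg, gt$speed_label), var)
  expect_true(all(cell_var < 1e-24))
  # and identical across subjects within a cell
  cell_span <- tapply(gt$at_load_bw,
                      interaction(gt$condition_deg, gt$speed_label),
                      function(x) diff(range(x)))
  expect_true(all(cell_span == 0))
})

test_that("progressive loading: neutral wedge loads exceed 30-degree loads within every subject", {
  gt <- small_cohort()$ground_truth
  for (s in unique(gt$subject_id)) {
    m0 <- mean(gt$at_load_bw[gt$subject_id == s & gt$condition_deg == 0])
    m30 <- mean(gt$at_load_bw[gt$subject_id == s & gt$condition_deg == 30])
    expect_gt(m0, m30)
  }
  # and speed categories are ordered
  sp <- tapply(gt$speed_mps, gt$speed_label, mean)
  expect_true(sp[["pathological"]] < sp[["slow"]] &&
                sp[["slow"]] < sp[["medium"]] && sp[["medium"]] < sp[["fast"]])
})

test_that("every stride is detectable: stance peak above and swing below the 50 N threshold", {
  coh <- small_cohort()
  gt <- coh$ground_truth
  trial_of <- function(row) {
    Filter(function(t) {
      t$subject_id == row$subject_id && t$condition_deg == row$condition_deg &&
        t$speed_label == row$speed_label
    }, coh$trials)[[1]]
  }
  set.seed(1)
  for (i in sample(nrow(gt), 40)) {
    row <- gt[i, ]
    f <- trial_of(row)$insole_force
    expect_gt(max(f[row$hs_idx:(row$to_idx - 1)]), 50)
    expect_lt(max(f[row$to_idx:(row$next_hs_idx - 1)]), 50)
  }
})

test_that("COM traces pass the constant-speed QC and encode the true walking speed", {
  coh <- small_cohort()
  gt <- coh$ground_truth
  for (i in seq_along(coh$trials)) {
    trial <- coh$trials[[i]]
    ws <- trial_walking_speed(trial$com_x, trial$fs_com)
    expect_gt(ws$r_squared, 0.98)
    truth <- unique(gt$speed_mps[gt$subject_id == trial$subject_id &
                                   gt$condition_deg == trial$condition_deg &
                                   gt$speed_label == trial$speed_label])
    expect_equal(ws$speed_mps, truth, tolerance = 0.01)
  }
})

test_that("subject offset dispersion matches the configured SD at large n", {
  cfg <- sim_config(n_subjects = 60, conditions = c(0),
                    speed_labels = c("slow", "fast"),
                    speed_means_mps = c(0.9, 1.6),
                    trials_per_cell = 1, strides_per_trial = 4, seed = 20)
  gt <- generate_cohort(cfg)$ground_truth
  # subject offset = subject mean load after removing the speed-cell mean
  cell_mean <- ave(gt$at_load_bw, gt$speed_label)
  offs <- tapply(gt$at_load_bw - cell_mean, gt$subject_id, mean)
  expect_lt(abs(sd(offs) - 0.45) / 0.45, 0.2)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(fs = 0), "'fs'")
  expect_error(sim_config(conditions = numeric(0)), "conditions")
  expect_error(sim_config(noise_sd = c(load = -1, speed = 0)), "noise_sd")
  expect_error(sim_config(locations = "hip"), "locations")
  expect_error(sim_config(base_load_bw = c("30" = 3, "5" = 2, "0" = 1)),
               "base_load_bw")
})

test_that("perturb_recording_length truncates only the insole stream", {
  trial <- small_cohort()$trials[[1]]
  expect_identical(perturb_recording_length(trial, 0), trial)
  bad <- perturb_recording_length(trial, 0.5)
  expect_equal(length(trial$insole_force) - length(bad$insole_force),
               round(0.5 * trial$fs_insole))
  expect_identical(bad$imus, trial$imus)
  rep_ <- check_integrity(bad, tolerance_s = 0.1)
  expect_false(rep_$accepted)
  expect_error(perturb_recording_length(trial, 1e6), "truncate")
})
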