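# L1 regression: limits, support recovery, prediction contracts, MAPE.

make_design <- function(n, p, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(df) <- paste0("f", seq_len(p))
  df
}

test_that("the near-zero penalty limit matches a normal-equations oracle", {
  df <- make_design(20, 3, seed = 2)
  df$y <- 1.5 + 2 * df$f1 - 1 * df$f2 + 0.5 * df$f3 + rnorm(20, 0, 0.01)
  fit <- fit_l1(df, "y", model_config(penalty_grid = 1e-9),
                features = c("f1", "f2", "f3"))
  beta <- ols_coef(df[, c("f1", "f2", "f3")], df$y)
  # compare on the original feature scale
  raw_coef <- fit$coefficients / fit$scaler_sds
  expect_equal(unname(raw_coef), unname(beta[-1]), tolerance = 1e-4)
  pred <- predict(fit, df)
  ols_pred <- beta[1] + as.matrix(df[, 1:3]) %*% beta[-1]
  expect_equal(pred, drop(ols_pred), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("a very large penalty yields the intercept-only model", {
  df <- make_design(30, 4, seed = 3)
  df$y <- 2 + df$f1 + rnorm(30, 0, 0.1)
  fit <- fit_l1(df, "y", model_config(penalty_grid = 1e6),
                features = paste0("f", 1:4))
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, mean(df$y))
  expect_equal(unique(predict(fit, df)), mean(df$y))
})

test_that("a planted 2-sparse signal is recovered among noise features", {
  df <- make_design(200, 12, seed = 4)
  df$y <- 20 + 3 * df$f1 - 2 * df$f2 + rnorm(200, 0, 1e-6)
  fit <- fit_l1(df, "y", model_config(seed = 9),
                features = paste0("f", 1:12))
  nz <- names(fit$coefficients)[fit$coefficients != 0]
  expect_setequal(nz, c("f1", "f2"))
  raw <- fit$coefficients / fit$scaler_sds
  expect_lt(abs(raw[["f1"]] - 3) / 3, 0.05)
  expect_lt(abs(raw[["f2"]] + 2) / 2, 0.05)
})

test_that("prediction is invariant to column order and names missing features", {
  df <- make_design(40, 3, seed = 5)
  df$y <- 10 + df$f1 + 2 * df$f2 + rnorm(40, 0, 0.05)
  fit <- fit_l1(df, "y", cheap_config(), features = c("f1", "f2", "f3"))
  p1 <- predict(fit, df)
  p2 <- predict(fit, df[, c("f3", "y", "f2", "f1")])
  expect_identical(p1, p2)
  expect_error(predict(fit, df[, c("f1", "f2")]), "f3")
})

test_that("zero-variance features are tolerated and zero-variance targets refused", {
  df <- make_design(30, 2, seed = 6)
  df$flat <- 7
  df$y <- 10 + df$f1 + rnorm(30, 0, 0.05)
  fit <- fit_l1(df, "y", cheap_config(), features = c("f1", "f2", "flat"))
  expect_equal(fit$coefficients[["flat"]], 0)
  expect_true(is.finite(predict(fit, df)[1]))

  df$yc <- 1
  expect_error(fit_l1(df, "yc", cheap_config(),
                      features = c("f1", "f2")), "zero-variance")
  expect_error(fit_l1(df[1:2, ], "y", model_config(inner_cv_folds = 5),
                      features = c("f1", "f2")), "fewer rows")
})

test_that("sparsity is monotone along the penalty path", {
  df <- make_design(60, 8, seed = 7)
  df$y <- 2 * df$f1 - df$f3 + 0.5 * df$f5 + rnorm(60, 0, 0.2)
  grid <- 10^seq(-4, 0.5, length.out = 10)
  nnz <- vapply(grid, function(l) {
    fit <- fit_l1(df, "y", model_config(penalty_grid = l),
                  features = paste0("f", 1:8))
    sum(fit$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("standardization absorbs affine rescaling of a feature", {
  df <- make_design(50, 4, seed = 8)
  df$y <- 10 + df$f1 - df$f2 + rnorm(50, 0, 0.05)
  fit_a <- fit_l1(df, "y", model_config(seed = 2),
                  features = paste0("f", 1:4))
  df2 <- df
  df2$f2 <- 7 * df2$f2 + 3
  fit_b <- fit_l1(df2, "y", model_config(seed = 2),
                  features = paste0("f", 1:4))
  expect_equal(predict(fit_a, df), predict(fit_b, df2), tolerance = 1e-8)
})

test_that("model fitting is deterministic given the seed", {
  ds <- small_dataset()
  kept <- ds[ds$kept & ds$condition_deg == 0, ]
  f1 <- fit_l1(kept, "at_peak_bw", cheap_config(seed = 3))
  f2 <- fit_l1(kept, "at_peak_bw", cheap_config(seed = 3))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$selected_penalty, f2$selected_penalty)
})

test_that("MAPE arithmetic, guards, and agreement grades", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(c(1, 2), c(1.1, 1.8)), 10)
  expect_gte(mape(runif(10, 1, 2), runif(10, 1, 2)), 0)
  expect_error(mape(c(1, 0), c(1, 1)), "> 0")
  expect_error(mape(c(1, 2), c(1)), "equal length")
  expect_equal(mape_grade(c(9.5, 15, 25)),
               c("excellent", "acceptable", "unacceptable"))
})

test_that("fitted models survive a JSON round trip", {
  df <- make_design(40, 3, seed = 10)
  df$y <- 10 + df$f1 + rnorm(40, 0, 0.1)
  fit <- fit_l1(df, "y", cheap_config(), features = paste0("f", 1:3))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, df), predict(fit, df), tolerance = 1e-12)
})
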