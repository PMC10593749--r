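#' Configuration for the L1-regularized regression
#'
#' The regularization weight is chosen by inner K-fold cross-validation
#' minimizing mean absolute percentage error (MAPE) over a log-spaced grid.
#' When `penalty_grid` is `NULL` the grid spans `[1e-4, 10]` times the
#' data-driven maximal penalty (the smallest weight that zeroes every
#' coefficient) with `grid_length` points.
#'
#' @param penalty_grid Optional explicit vector of positive penalty weights.
#' @param grid_length Number of grid points when the grid is data-driven.
#' @param inner_cv_folds Inner cross-validation folds (default 5).
#' @param standardize Z-score features with training statistics? (default
#'   `TRUE`; zero-variance features are excluded and get coefficient 0).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `model_config`.
#' @export
model_config <- function(penalty_grid = NULL, grid_length = 30,
                         inner_cv_folds = 5, standardize = TRUE, seed = 1L) {
  if (!is.null(penalty_grid)) {
    if (length(penalty_grid) == 0L || any(penalty_grid <= 0)) {
      stopf("model_config: penalty_grid must be non-empty and all > 0")
    }
  }
  if (inner_cv_folds < 2) stopf("model_config: inner_cv_folds must be >= 2")
  structure(list(penalty_grid = penalty_grid, grid_length = grid_length,
                 inner_cv_folds = inner_cv_folds,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "model_config")
}

#' Fit an L1-regularized (LASSO) linear model from stride features
#'
#' Standardization statistics are computed from the supplied (training) rows
#' only, so no test-set information leaks into the scaler. The penalty is
#' selected by seeded inner K-fold cross-validation minimizing MAPE, then the
#' model is refit on all rows at the selected penalty. The intercept is never
#' penalized.
#'
#' @param data Data.frame of training rows (kept strides only).
#' @param target Name of the target column (`"at_peak_bw"` or `"speed_mps"`).
#' @param config A [model_config()].
#' @param features Feature column names; defaults to [feature_columns()].
#' @return An object of class `boot_lasso`: `feature_names`, `coefficients`
#'   (on the original feature scale of the standardized design),
#'   `intercept`, `scaler_means`, `scaler_sds`, `selected_penalty`,
#'   `cv_mape`.
#' @export
fit_l1 <- function(data, target, config = model_config(),
                   features = feature_columns(data)) {
  if (!target %in% names(data)) stopf("fit_l1: target '%s' not found", target)
  y <- data[[target]]
  n <- length(y)
  if (n < 2L) stopf("fit_l1: need at least 2 rows")
  if (!all(is.finite(y))) stopf("fit_l1: target contains non-finite values")
  if (stats::sd(y) == 0) stopf("fit_l1: zero-variance target")
  if (n < config$inner_cv_folds) {
    stopf("fit_l1: fewer rows (%d) than inner CV folds (%d)", n,
          config$inner_cv_folds)
  }
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"

  means <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  active <- if (config$standardize) sds > 0 else rep(TRUE, ncol(x))
  if (!any(active)) stopf("fit_l1: all features have zero variance")
  xs <- x[, active, drop = FALSE]
  if (config$standardize) {
    xs <- sweep(sweep(xs, 2L, means[active], "-"), 2L, sds[active], "/")
  }

  grid <- config$penalty_grid
  if (is.null(grid)) {
    lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n
    grid <- lambda_max * exp(seq(log(10), log(1e-4),
                                 length.out = config$grid_length))
  }
  grid <- sort(grid, decreasing = TRUE)

  cv_mape <- rep(NA_real_, length(grid))
  if (length(grid) > 1L) {
    set.seed(config$seed)
    fold <- sample(rep_len(seq_len(config$inner_cv_folds), n))
    err <- matrix(0, config$inner_cv_folds, length(grid))
    for (f in seq_len(config$inner_cv_folds)) {
      tr <- fold != f
      # near-zero penalties on collinear stride features need not converge
      # fully; such grid points lose the MAPE comparison anyway
      fit <- suppressWarnings(
        glmnet::glmnet(xs[tr, , drop = FALSE], y[tr], alpha = 1,
                       lambda = grid, standardize = FALSE, thresh = 1e-8))
      pred <- stats::predict(fit, newx = xs[!tr, , drop = FALSE], s = grid,
                             exact = FALSE)
      err[f, ] <- apply(pred, 2L, function(p) mape(y[!tr], p))
    }
    cv_mape <- colMeans(err)
    best <- which(cv_mape <= min(cv_mape) + 1e-12)[1L]  # tie -> sparser model
  } else {
    best <- 1L
  }
  lambda <- grid[best]

  # refit on the full path down to the selected penalty only (warm starts
  # keep the solution exact at `lambda`; the unused tail is never computed);
  # on nearly collinear designs the last digits of a small-penalty solution
  # may not settle within maxit — predictions are unaffected at this thresh
  final <- suppressWarnings(
    glmnet::glmnet(xs, y, alpha = 1,
                   lambda = grid[grid >= lambda * (1 - 1e-12)],
                   standardize = FALSE, thresh = 1e-9, maxit = 500000))
  beta_active <- as.numeric(stats::coef(final, s = lambda))
  coefs <- stats::setNames(rep(0, length(features)), features)
  coefs[active] <- beta_active[-1L]

  structure(list(feature_names = features,
                 coefficients = coefs,
                 intercept = beta_active[1L],
                 scaler_means = stats::setNames(means, features),
                 scaler_sds = stats::setNames(sds, features),
                 standardize = config$standardize,
                 selected_penalty = lambda,
                 penalty_grid = grid,
                 cv_mape = cv_mape),
            class = "boot_lasso")
}

#' Predict from a fitted L1 model
#'
#' Columns are aligned by name, so their order is irrelevant; features are
#' standardized with the scaler stored at training time.
#'
#' @param object A `boot_lasso` from [fit_l1()].
#' @param newdata Data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.boot_lasso <- function(object, newdata, ...) {
  missing_f <- setdiff(object$feature_names, names(newdata))
  if (length(missing_f)) {
    stopf("predict: missing feature column(s): %s",
          paste(missing_f, collapse = ", "))
  }
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  if (object$standardize) {
    sds <- object$scaler_sds
    safe_sds <- ifelse(sds > 0, sds, 1)
    x <- sweep(sweep(x, 2L, object$scaler_means, "-"), 2L, safe_sds, "/")
  }
  drop(x %*% object$coefficients) + object$intercept
}

#' @export
print.boot_lasso <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<boot_lasso> %d/%d nonzero features, penalty %.4g\n",
              nz, length(x$coefficients), x$selected_penalty))
  invisible(x)
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y_pred - y_true| / y_true)`. All true values must be strictly
#' positive; upstream the 0.5 BW stride filter and walking-speed positivity
#' guarantee this.
#'
#' @param y_true True values, all > 0.
#' @param y_pred Predictions, same length.
#' @return MAPE in percent.
#' @export
mape <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("mape: y_true and y_pred must have equal length")
  }
  if (any(y_true <= 0)) stopf("mape: all y_true must be > 0")
  100 * mean(abs(y_pred - y_true) / y_true)
}

#' Grade a MAPE against the a-priori agreement thresholds
#'
#' Agreement under 10% MAPE is graded `"excellent"`, under 20%
#' `"acceptable"`, otherwise `"unacceptable"`.
#'
#' @param mape_pct MAPE value(s) in percent.
#' @return Character vector of grades.
#' @export
mape_grade <- function(mape_pct) {
  ifelse(mape_pct < 10, "excellent",
         ifelse(mape_pct < 20, "acceptable", "unacceptable"))
}

#' Export / import a fitted model as JSON
#'
#' @param model A `boot_lasso`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `boot_lasso` (read).
#' @export
write_model_json <- function(model, path) {
  payload <- model[c("feature_names", "coefficients", "intercept",
                     "scaler_means", "scaler_sds", "standardize",
                     "selected_penalty")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_names = p$feature_names,
                 coefficients = stats::setNames(p$coefficients,
                                                p$feature_names),
                 intercept = p$intercept,
                 scaler_means = stats::setNames(p$scaler_means,
                                                p$feature_names),
                 scaler_sds = stats::setNames(p$scaler_sds, p$feature_names),
                 standardize = isTRUE(p$standardize),
                 selected_penalty = p$selected_penalty),
            class = "boot_lasso")
}
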