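#' Support vector regression model configuration
#'
#' Defaults are the study's optimum for the normalized IOL-power task: a
#' degree-2 polynomial kernel, an epsilon-insensitive tube of half-width
#' 0.0282 (normalized units) and a box constraint of 0.0049, with 30% of
#' the training table held out for validation MSE reporting. The kernel is
#' (scale * <x, x'> + 1)^order; the kernel scale is configurable and
#' defaults to 1.
#'
#' @param polynomial_order polynomial kernel degree (>= 1).
#' @param epsilon insensitive-tube half-width (normalized units, > 0).
#' @param box_constraint regularization bound C (> 0).
#' @param kernel_scale inner-product scale of the polynomial kernel.
#' @param holdout_fraction fraction held out for validation MSE.
#' @param seed integer seed for the holdout partition.
#' @return list of class `svm_config`.
#' @export
svm_config <- function(polynomial_order = 2, epsilon = 0.0282,
                       box_constraint = 0.0049, kernel_scale = 1,
                       holdout_fraction = 0.3, seed = 1L) {
  stopifnot(polynomial_order >= 1, epsilon > 0, box_constraint > 0,
            kernel_scale > 0, holdout_fraction >= 0, holdout_fraction < 1)
  structure(
    list(polynomial_order = polynomial_order, epsilon = epsilon,
         box_constraint = box_constraint, kernel_scale = kernel_scale,
         holdout_fraction = holdout_fraction, seed = as.integer(seed)),
    class = "svm_config"
  )
}

#' Fit the polynomial-kernel support vector regression model
#'
#' Epsilon-insensitive SVR on the normalized training table. A random
#' holdout (default 30%) is set aside for validation MSE reporting; the
#' returned model is the one fitted on the remaining fraction. Fitting goes
#' through the libsvm solver, which optimizes the same convex objective as
#' sequential minimal optimization.
#'
#' @param table normalized data.frame containing the predictor columns and
#'   the target column.
#' @param config an [svm_config()].
#' @param predictors predictor column names.
#' @param target target column name.
#' @return object of class `svm_rm` with elements `fit` (the e1071 model),
#'   `holdout_mse`, `holdout_idx`, `predictors`, `target`, `config`.
#' @export
fit_svm_rm <- function(table, config = svm_config(),
                       predictors = predictor_vars, target = "iol_ideal_d") {
  x <- as.matrix(table[, predictors, drop = FALSE])
  y <- table[[target]]
  n <- nrow(x)
  set.seed(config$seed)
  n_hold <- round(config$holdout_fraction * n)
  hold <- if (n_hold > 0) sort(sample.int(n, n_hold)) else integer(0)
  train <- if (n_hold > 0) setdiff(seq_len(n), hold) else seq_len(n)

  fit <- tryCatch(
    e1071::svm(
      x = x[train, , drop = FALSE], y = y[train],
      type = "eps-regression", kernel = "polynomial",
      degree = config$polynomial_order,
      gamma = config$kernel_scale, coef0 = 1,
      cost = config$box_constraint, epsilon = config$epsilon,
      scale = FALSE
    ),
    error = function(e) {
      if (!grepl("empty", conditionMessage(e), ignore.case = TRUE)) stop(e)
      # no support vectors: every residual fits inside the insensitive
      # tube, and the flattest function is the constant bias term
      structure(list(constant = mean(y[train])), class = "svr_constant")
    }
  )
  holdout_mse <- if (n_hold > 0) {
    mean((y[hold] - predict_svr(fit, x[hold, , drop = FALSE]))^2)
  } else NA_real_

  structure(
    list(fit = fit, holdout_mse = holdout_mse, holdout_idx = hold,
         predictors = predictors, target = target, config = config),
    class = "svm_rm"
  )
}

predict_svr <- function(fit, x) {
  if (inherits(fit, "svr_constant")) rep(fit$constant, nrow(x))
  else as.numeric(stats::predict(fit, x))
}

#' @export
predict.svm_rm <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  predict_svr(object$fit, x)
}
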