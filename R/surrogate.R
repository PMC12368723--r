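# Gradient-boosted surrogates: training, evaluation metrics, calibration
# fit lines, and learning curves.  One independent model per output.

#' Surrogate hyperparameters
#'
#' The four tuned hyperparameters of the gradient-boosted backend: tree
#' depth, learning rate, L2 leaf regularization, and number of boosting
#' iterations.
#'
#' @param depth Maximum tree depth (integer).
#' @param learning_rate Shrinkage per boosting step.
#' @param l2_leaf_reg L2 regularization on leaf weights.
#' @param iterations Number of boosting rounds (integer).
#' @return A list of class `hyperparameters`.
#' @export
hyperparameters <- function(depth = 6, learning_rate = 0.1,
                            l2_leaf_reg = 3, iterations = 500) {
  stopifnot(depth >= 1, learning_rate > 0, l2_leaf_reg >= 0, iterations >= 1)
  structure(list(depth = as.integer(round(depth)),
                 learning_rate = as.numeric(learning_rate),
                 l2_leaf_reg = as.numeric(l2_leaf_reg),
                 iterations = as.integer(round(iterations))),
            class = "hyperparameters")
}

# warn (but proceed) when tuned ranges are left; perturbation studies need it
check_hp_ranges <- function(hp) {
  sp <- default_hyperparameter_space()
  v <- unlist(hp[sp$name])
  out <- v < sp$lower | v > sp$upper
  if (any(out))
    warning("hyperparameters outside the tuned ranges: ",
            paste(sp$name[out], collapse = ", "))
  invisible(hp)
}

#' Train a gradient-boosted surrogate for one output
#'
#' Backend: xgboost regression trees (`tree_method = "hist"`,
#' `max_bin = 32`, single thread), which makes training deterministic
#' under a fixed seed and data.
#'
#' @param data Flat data frame holding the feature columns and the
#'   outcome.
#' @param outcome Outcome column name (`"y1"`, `"y2"`, or `"y3"`).
#' @param hp A `hyperparameters` object.
#' @param seed Integer seed recorded in the model.
#' @param features Feature column names (default x1..x14).
#' @return A `surrogate_model` wrapping the booster plus its
#'   hyperparameters, seed, backend, and training-data hash.
#' @export
train_surrogate <- function(data, outcome = "y1", hp = hyperparameters(),
                            seed = 0L, features = paste0("x", 1:14)) {
  stopifnot(inherits(hp, "hyperparameters"))
  if (nrow(data) < 50) stop("need at least 50 training rows")
  miss <- setdiff(c(features, outcome), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (any(!is.finite(y))) stop("non-finite labels in outcome ", outcome)
  check_hp_ranges(hp)
  X <- as.matrix(data[, features])
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(max_depth = hp$depth, eta = hp$learning_rate,
                  lambda = hp$l2_leaf_reg, objective = "reg:squarederror",
                  tree_method = "hist", max_bin = 32, nthread = 1,
                  seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = hp$iterations, verbose = 0)
  structure(list(booster = booster, features = features, outcome = outcome,
                 hp = hp, seed = as.integer(seed), n_train = nrow(data),
                 backend = "xgboost", data_hash = dataset_hash(data)),
            class = "surrogate_model")
}

#' Predict from a surrogate model
#'
#' @param object A `surrogate_model`.
#' @param newdata Data frame or matrix containing the model's feature
#'   columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  predict(object$booster, X)
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("<surrogate_model> outcome ", x$outcome, ", backend ", x$backend,
      ", n_train ", x$n_train, "\n  hp: depth=", x$hp$depth,
      " eta=", format(x$hp$learning_rate, digits = 4),
      " l2=", format(x$hp$l2_leaf_reg, digits = 4),
      " iters=", x$hp$iterations, "\n", sep = "")
  invisible(x)
}

#' Evaluate a surrogate on a split
#'
#' Standard regression metrics: MSE, RMSE, MAE, R^2 = 1 - SSres/SStot,
#' and MAPE in percent with exact-zero labels excluded (count reported).
#' Also fits the calibration line of observed on predicted values with a
#' 95% prediction interval (see [fit_line_with_interval()]).
#'
#' @param model A `surrogate_model`.
#' @param data Non-empty split containing features and outcome.
#' @return A list of class `eval_report`.
#' @export
evaluate_surrogate <- function(model, data) {
  stopifnot(nrow(data) >= 1)
  y <- data[[model$outcome]]
  yhat <- predict(model, data)
  resid <- y - yhat
  mse <- mean(resid^2)
  nz <- y != 0
  r2 <- if (length(y) >= 2 && var(y) > 0)
    1 - sum(resid^2) / sum((y - mean(y))^2) else NA_real_
  line <- if (length(y) >= 3 && var(yhat) > 0)
    fit_line_with_interval(y, yhat) else NULL
  structure(list(
    n = length(y),
    MSE = mse, RMSE = sqrt(mse), MAE = mean(abs(resid)), R2 = r2,
    MAPE = if (any(nz)) 100 * mean(abs(resid[nz] / y[nz])) else NA_real_,
    n_zero_excluded = sum(!nz),
    fit_line = line),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  RMSE=%.5g  MAE=%.5g  R2=%.6g  MAPE=%.4g%%\n",
              x$n, x$RMSE, x$MAE, x$R2, x$MAPE))
  if (!is.null(x$fit_line))
    cat(sprintf("  fit line: y = %.4f yhat + %.4g  (t=%.4g, p=%.3g)\n",
                x$fit_line$slope, x$fit_line$intercept,
                x$fit_line$t_value, x$fit_line$p_value))
  invisible(x)
}

#' Calibration line of observed on predicted values
#'
#' Ordinary least squares of `y` on `yhat` with the slope's t statistic
#' and the standard 95% prediction interval.
#'
#' @param y Observed values.
#' @param yhat Predicted values (must have nonzero variance, n >= 3).
#' @return List with `slope`, `intercept`, `t_value`, `p_value`,
#'   `pi_halfwidth` (mean half-width of the 95% prediction band) and
#'   `band`, a data frame (`yhat`, `fit`, `lwr`, `upr`) sorted by `yhat`.
#' @export
fit_line_with_interval <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (length(y) < 3) stop("need at least 3 points")
  if (var(yhat) == 0) stop("zero-variance predictions: fit line undefined")
  fit <- lm(y ~ yhat)
  sm <- summary(fit)
  # in-sample prediction band is the intended use here
  pred <- suppressWarnings(predict(fit, interval = "prediction", level = 0.95))
  ord <- order(yhat)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       t_value = sm$coefficients[2, "t value"],
       p_value = sm$coefficients[2, "Pr(>|t|)"],
       pi_halfwidth = mean((pred[, "upr"] - pred[, "lwr"]) / 2),
       band = data.frame(yhat = yhat[ord], fit = pred[ord, "fit"],
                         lwr = pred[ord, "lwr"], upr = pred[ord, "upr"]))
}

#' Learning curve over training-set sizes
#'
#' For each size, k-fold cross-validation on a fixed subsample: the model
#' is trained on the in-fold rows and scored (R^2) on both the training
#' fold and the held-out fold.  Fold assignment is seed-deterministic.
#'
#' @param data Flat data frame.
#' @param hp A `hyperparameters` object.
#' @param sizes Training sizes to evaluate (each <= `nrow(data)`).
#' @param k Number of folds.
#' @param outcome Outcome column.
#' @param seed Integer seed.
#' @return Data frame with per-size mean and sd of train and validation
#'   R^2.  Sizes smaller than `2 * k` are skipped with a warning.
#' @export
learning_curve <- function(data, hp, sizes, k = 5, outcome = "y1",
                           seed = 1L) {
  stopifnot(all(sizes <= nrow(data)))
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    if (sz < 2 * k) {
      warning("size ", sz, " < 2k, skipped")
      return(NULL)
    }
    sub <- data[sample.int(nrow(data), sz), , drop = FALSE]
    fold <- sample(rep_len(seq_len(k), sz))
    r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    scores <- vapply(seq_len(k), function(f) {
      tr <- sub[fold != f, , drop = FALSE]
      va <- sub[fold == f, , drop = FALSE]
      m <- train_surrogate(tr, outcome = outcome, hp = hp, seed = seed)
      c(train = r2(tr[[outcome]], predict(m, tr)),
        validation = r2(va[[outcome]], predict(m, va)))
    }, c(train = 0, validation = 0))
    data.frame(size = sz,
               train_mean = mean(scores["train", ]),
               train_sd = sd(scores["train", ]),
               validation_mean = mean(scores["validation", ]),
               validation_sd = sd(scores["validation", ]))
  })
  do.call(rbind, rows)
}

#' Save a surrogate with a JSON metadata sidecar
#'
#' @param model A `surrogate_model`.
#' @param path Output path for the booster (xgboost JSON format); the
#'   metadata sidecar goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  xgboost::xgb.save(model$booster, path)
  meta <- list(outcome = model$outcome, features = model$features,
               hp = unclass(model$hp), seed = model$seed,
               n_train = model$n_train, backend = model$backend,
               data_hash = model$data_hash)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
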