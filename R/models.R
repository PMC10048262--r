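#' Regressor specification
#'
#' Uniform description of the three supported regressors.
#'
#' * `plsr`: `components` (integer, or `"auto"` to pick by RMSECV),
#'   `max_components`, `folds`.
#' * `svr`: epsilon-SVR with RBF kernel; `cost` (C), `epsilon`, `gamma`
#'   (`NULL` means `1 / (p * var(X))`). The response is standardized
#'   internally and de-standardized on output, because the epsilon tube is
#'   scale-sensitive.
#' * `gbm`: gradient boosted regression trees in the leaf-wise ("gbdt")
#'   growth mode with `num_leaves = 31`, unlimited depth
#'   (`max_depth = -1`), `learning_rate = 0.1` and `n_estimators = 100` as
#'   defaults; `max_bin` controls the backend's histogram quantization and
#'   `min_child_samples` can be lowered for small calibration sets.
#'
#' @param name one of `"plsr"`, `"svr"`, `"gbm"`.
#' @param ... hyperparameter overrides for the chosen model.
#' @return list of class `regressor_spec`.
#' @export
regressor_spec <- function(name = c("plsr", "svr", "gbm"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    plsr = list(components = "auto", max_components = 15, folds = 5),
    svr = list(kernel = "radial", cost = 10, epsilon = 0.1, gamma = NULL),
    gbm = list(boosting_type = "gbdt", num_leaves = 31, max_depth = -1,
               learning_rate = 0.1, n_estimators = 100,
               max_bin = 32, min_child_samples = 1, subsample = 1)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "))
  }
  hp <- modifyList(defaults, overrides)
  if (name == "gbm") {
    stopifnot(hp$num_leaves >= 2, hp$learning_rate > 0, hp$n_estimators >= 1)
    if (!identical(hp$boosting_type, "gbdt")) {
      stop("only the gbdt boosting type is supported")
    }
  }
  if (name == "svr") stopifnot(hp$cost > 0, hp$epsilon >= 0)
  structure(list(name = name, hyperparameters = hp),
            class = "regressor_spec")
}

#' Fit a regressor
#'
#' Trains the model described by `spec` on the calibration matrix, with an
#' optional variable mask restricting the predictors. The mask is stored
#' and enforced at prediction time. For `plsr` with `components = "auto"`
#' the component count is chosen by [rmsecv()]. Refitting with the same
#' seed reproduces predictions bit-identically (the GBM backend runs
#' single-threaded for that reason).
#'
#' @param spec a [regressor_spec()].
#' @param X_cal calibration matrix, full width.
#' @param y_cal response (mg/kg).
#' @param variables optional integer mask of active columns (default all).
#' @param seed RNG seed for stochastic backends.
#' @return object of class `fitted_model`.
#' @export
fit_model <- function(spec, X_cal, y_cal, variables = NULL, seed = NULL) {
  stopifnot(inherits(spec, "regressor_spec"))
  X_cal <- as.matrix(X_cal)
  variables <- if (is.null(variables)) seq_len(ncol(X_cal)) else
    sort(unique(as.integer(variables)))
  if (min(variables) < 1 || max(variables) > ncol(X_cal)) {
    stop("variable mask out of range")
  }
  Xm <- X_cal[, variables, drop = FALSE]
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    plsr = {
      a <- hp$components
      if (identical(a, "auto")) {
        cv <- rmsecv(Xm, y_cal, ncomp_max = hp$max_components,
                     folds = hp$folds, seed = seed)
        a <- cv$best_ncomp
      }
      list(model = fit_pls(Xm, y_cal, ncomp = a), ncomp = a)
    },
    svr = {
      y_mean <- mean(y_cal)
      y_sd <- sd(y_cal)
      if (y_sd == 0) y_sd <- 1
      gamma <- hp$gamma %||% {
        v <- mean((Xm - mean(Xm))^2)
        if (v > 0) 1 / (ncol(Xm) * v) else 1 / ncol(Xm)
      }
      m <- e1071::svm(x = Xm, y = (y_cal - y_mean) / y_sd,
                      type = "eps-regression", kernel = hp$kernel,
                      cost = hp$cost, epsilon = hp$epsilon, gamma = gamma,
                      scale = FALSE)
      list(model = m, y_mean = y_mean, y_sd = y_sd, gamma = gamma)
    },
    gbm = {
      colnames(Xm) <- paste0("ch", variables)
      params <- list(objective = "reg:squarederror",
                     eta = hp$learning_rate,
                     max_leaves = hp$num_leaves,
                     max_depth = if (hp$max_depth < 0) 0 else hp$max_depth,
                     grow_policy = "lossguide",
                     tree_method = "hist",
                     max_bin = hp$max_bin,
                     min_child_weight = hp$min_child_samples,
                     subsample = hp$subsample,
                     nthread = 1,
                     seed = seed %||% 0)
      dtrain <- xgboost::xgb.DMatrix(Xm, label = y_cal, nthread = 1)
      m <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = hp$n_estimators, verbose = 0)
      list(model = m, feature_names = colnames(Xm))
    }
  )
  structure(list(spec = spec, fit = fit, variables = variables,
                 p_full = ncol(X_cal), seed = seed),
            class = "fitted_model")
}

#' Predict from a fitted regressor
#'
#' @param model a [fit_model()] object.
#' @param X_new matrix with the full training width (the stored variable
#'   mask is applied) or exactly the masked width.
#' @return numeric predictions (mg/kg), one per row of `X_new`.
#' @export
model_predict <- function(model, X_new) {
  stopifnot(inherits(model, "fitted_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) == model$p_full) {
    Xm <- X_new[, model$variables, drop = FALSE]
  } else if (ncol(X_new) == length(model$variables)) {
    Xm <- X_new
  } else {
    stop("X_new has ", ncol(X_new), " columns; expected ", model$p_full,
         " (full) or ", length(model$variables), " (masked)")
  }
  out <- switch(model$spec$name,
    plsr = pls_predict(model$fit$model, Xm),
    svr = {
      ps <- as.numeric(predict(model$fit$model, Xm))
      ps * model$fit$y_sd + model$fit$y_mean
    },
    gbm = {
      colnames(Xm) <- model$fit$feature_names
      as.numeric(predict(model$fit$model,
                         xgboost::xgb.DMatrix(Xm, nthread = 1)))
    }
  )
  if (!all(is.finite(out))) stop("non-finite predictions")
  out
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model [", x$spec$name, "]:", length(x$variables),
      "active variables\n")
  invisible(x)
}

#' Persist / restore a fitted model
#'
#' Saves the fitted-model object (spec, variable mask, backend state) to
#' an RDS file tagged with the package version, and restores it. The GBM
#' backend serializes its booster explicitly so the file survives R
#' sessions.
#'
#' @param model a [fit_model()] object.
#' @param path file path (conventionally
#'   `model_<element>_<model>_<selector>.rds`).
#' @return `save_fitted_model` returns `path` invisibly;
#'   `load_fitted_model` the restored `fitted_model`.
#' @export
save_fitted_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  obj <- model
  if (obj$spec$name == "gbm") {
    obj$fit$model_raw <- xgboost::xgb.save.raw(obj$fit$model)
    obj$fit$model <- NULL
  }
  obj$package_version <- as.character(utils::packageVersion("libsvarsel"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_fitted_model
#' @export
load_fitted_model <- function(path) {
  obj <- readRDS(path)
  if (obj$spec$name == "gbm" && !is.null(obj$fit$model_raw)) {
    obj$fit$model <- xgboost::xgb.load.raw(obj$fit$model_raw)
    obj$fit$model_raw <- NULL
  }
  obj
}

#' GBM per-variable importance
#'
#' Relative importance of each active variable in a fitted GBM: the split
#' criterion (squared-error) improvement of every split is averaged per
#' variable over all trees using that variable, and the averages are
#' normalized to sum to one. Variables never used in a split score zero.
#' For a degenerate model with no splits (e.g. constant response) the
#' importance is undefined and reported as uniform with a `degenerate`
#' flag.
#'
#' @param model a [fit_model()] object with a gbm spec.
#' @return list with `importance` (named non-negative vector over active
#'   variables, summing to 1) and `degenerate` flag.
#' @export
gbm_importance <- function(model) {
  stopifnot(inherits(model, "fitted_model"))
  if (model$spec$name != "gbm") stop("importance requires a gbm model")
  trees <- xgboost::xgb.model.dt.tree(model = model$fit$model)
  splits <- trees[trees$Feature != "Leaf", ]
  imp <- setNames(numeric(length(model$variables)),
                  model$fit$feature_names)
  degenerate <- nrow(splits) == 0
  if (degenerate) {
    imp[] <- 1 / length(imp)
  } else {
    means <- tapply(splits$Gain, splits$Feature, mean)
    imp[names(means)] <- pmax(0, as.numeric(means))
    if (sum(imp) > 0) imp <- imp / sum(imp) else {
      imp[] <- 1 / length(imp)
      degenerate <- TRUE
    }
  }
  names(imp) <- as.character(model$variables)
  list(importance = imp, degenerate = degenerate)
}
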