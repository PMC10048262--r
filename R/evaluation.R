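#' Regression metrics (RMSE and R-squared)
#'
#' `rmse = sqrt(mean((y - yhat)^2))` in the units of the response (mg/kg
#' throughout this pipeline); `r_squared = 1 - SSE/SST` with SST taken
#' about the mean of the reference values. This is the coefficient of
#' determination, not the squared Pearson correlation: the two differ off
#' the 45-degree line, and the definition is switchable via
#' `method = "pearson"`.
#'
#' @param y_true reference values (length >= 2, finite).
#' @param y_pred predictions, same length.
#' @param method `"determination"` (default) or `"pearson"`.
#' @return list of class `metrics`: `r_squared`, `rmse`, `n`, plus a
#'   `zero_sst` flag when the reference values have no variance (R-squared
#'   is then `NA`).
#' @export
compute_metrics <- function(y_true, y_pred,
                            method = c("determination", "pearson")) {
  method <- match.arg(method)
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 observations")
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) {
    stop("non-finite values")
  }
  sse <- sum((y_true - y_pred)^2)
  sst <- sum((y_true - mean(y_true))^2)
  rmse <- sqrt(sse / length(y_true))
  zero_sst <- sst == 0
  r2 <- if (zero_sst) NA_real_ else if (method == "determination") {
    1 - sse / sst
  } else {
    suppressWarnings(stats::cor(y_true, y_pred))^2
  }
  structure(list(r_squared = r2, rmse = rmse, n = length(y_true),
                 zero_sst = zero_sst),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat("metrics: R2 =", format(x$r_squared), ", RMSE =", format(x$rmse),
      "(n =", x$n, ")\n")
  invisible(x)
}

#' Descriptive statistics of a concentration design
#'
#' Per element and group: minimum, maximum, mean, range, variance and
#' standard deviation of the concentrations (mg/kg; variance in mg^2/kg^2).
#' The sample (n-1) convention is used for the variance. Groups with a
#' single sample get `NA` variance and sd.
#'
#' @param concentrations a [generate_design()] table.
#' @return data.frame of class `summary_table` with columns `element`,
#'   `group`, `n`, `min`, `max`, `mean`, `range`, `var`, `std`.
#' @export
descriptive_stats <- function(concentrations) {
  conc <- concentration_matrix(concentrations)
  groups <- unique(as.character(concentrations$group))
  rows <- list()
  for (el in colnames(conc)) {
    for (g in groups) {
      v <- conc[as.character(concentrations$group) == g, el]
      rows[[length(rows) + 1L]] <- data.frame(
        element = el, group = g, n = length(v),
        min = min(v), max = max(v), mean = mean(v),
        range = max(v) - min(v),
        var = if (length(v) > 1) var(v) else NA_real_,
        std = if (length(v) > 1) sd(v) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs beyond the data: the split
#' fractions, per-selector configurations and per-model specifications.
#'
#' @param fractions calibration/validation/prediction fractions.
#' @param stratify stratify the split by group label (default TRUE).
#' @param elements elements to model (default Cd, Cu, Pb).
#' @param models named list of [regressor_spec()]s.
#' @param cars,frog,uve selector configurations.
#' @param r2_method R-squared convention for [compute_metrics()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(fractions = c(0.60, 0.28, 0.12),
                              stratify = TRUE,
                              elements = c("Cd", "Cu", "Pb"),
                              models = list(PLSR = regressor_spec("plsr"),
                                            SVR = regressor_spec("svr"),
                                            GBM = regressor_spec("gbm")),
                              cars = cars_config(),
                              frog = frog_config(),
                              uve = uve_config(),
                              r2_method = "determination") {
  structure(list(fractions = fractions, stratify = stratify,
                 elements = elements, models = models,
                 cars = cars, frog = frog, uve = uve,
                 r2_method = r2_method),
            class = "experiment_config")
}

run_selector <- function(method, X_cal, y_cal, config, seed) {
  switch(method,
    CARS = {
      cfg <- config$cars; cfg$seed <- seed
      cars_select(X_cal, y_cal, cfg)
    },
    RF = {
      cfg <- config$frog; cfg$seed <- seed
      random_frog_select(X_cal, y_cal, cfg)
    },
    UVE = {
      cfg <- config$uve; cfg$seed <- seed
      uve_select(X_cal, y_cal, cfg)
    },
    stop("unknown selector: ", method)
  )
}

#' Run the full element x model x selector experiment grid
#'
#' Normalizes the spectra (area normalization; skipped if the rows already
#' have unit area), computes one calibration/validation/prediction split
#' shared by every grid cell, runs each wavelength selector on the
#' calibration rows of each element, then fits every model on the full
#' spectrum and on each selector's channels and evaluates all three
#' subsets. Cell failures are recorded and skipped, not fatal.
#'
#' @param spectra a [spectrum_set()].
#' @param concentrations matching [generate_design()] table.
#' @param config an [experiment_config()].
#' @param seed master seed; all stage seeds are derived from it.
#' @return object of class `evaluation_report`: `table` (one row per grid
#'   cell with RC2/RMSEC, RV2/RMSEV, RP2/RMSEP and the selected variable
#'   count), `predictions` (per cell, per subset reference and predicted
#'   values), `selections`, `split`, `seed`, `failures`.
#' @export
run_experiment <- function(spectra, concentrations,
                           config = experiment_config(), seed = 1) {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (!identical(spectra$sample_ids, concentrations$sample_id)) {
    stop("spectra and concentrations sample ids differ")
  }
  areas <- spectral_areas(spectra)
  if (max(abs(areas - 1)) > 1e-8) spectra <- area_normalize(spectra)
  X <- spectra$intensities
  n <- nrow(X)
  conc <- concentration_matrix(concentrations)

  split <- split_dataset(
    n, config$fractions, seed = hash_seed(seed, "split"),
    group_labels = if (config$stratify) as.character(concentrations$group)
  )
  sets <- list(calibration = split$calibration,
               validation = split$validation,
               prediction = split$prediction)

  selectors <- c("full", "CARS", "RF", "UVE")
  rows <- list()
  predictions <- list()
  selections <- list()
  failures <- list()
  for (el in config$elements) {
    y <- conc[, el]
    X_cal <- X[sets$calibration, , drop = FALSE]
    y_cal <- y[sets$calibration]
    sel_idx <- list(full = seq_len(ncol(X)))
    selections[[el]] <- list()
    for (m in c("CARS", "RF", "UVE")) {
      res <- tryCatch(
        run_selector(m, X_cal, y_cal, config,
                     seed = hash_seed(seed, "select", m, el)),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[paste(el, m, "selection", sep = "/")]] <-
          conditionMessage(res)
        next
      }
      selections[[el]][[m]] <- res
      sel_idx[[m]] <- res$selected
    }
    for (model_name in names(config$models)) {
      for (sel in selectors) {
        if (is.null(sel_idx[[sel]])) next
        cell <- paste(el, model_name, sel, sep = "/")
        out <- tryCatch({
          fm <- fit_model(config$models[[model_name]], X_cal, y_cal,
                          variables = sel_idx[[sel]],
                          seed = hash_seed(seed, "fit", model_name, sel, el))
          preds <- lapply(sets, function(idx) {
            list(y_true = y[idx],
                 y_pred = model_predict(fm, X[idx, , drop = FALSE]))
          })
          mets <- lapply(preds, function(pr)
            compute_metrics(pr$y_true, pr$y_pred, method = config$r2_method))
          list(preds = preds, mets = mets)
        }, error = function(e) e)
        if (inherits(out, "error")) {
          failures[[cell]] <- conditionMessage(out)
          next
        }
        predictions[[cell]] <- out$preds
        rows[[cell]] <- data.frame(
          element = el, model = model_name, selector = sel,
          n_variables = length(sel_idx[[sel]]),
          rc2 = out$mets$calibration$r_squared,
          rmsec = out$mets$calibration$rmse,
          rv2 = out$mets$validation$r_squared,
          rmsev = out$mets$validation$rmse,
          rp2 = out$mets$prediction$r_squared,
          rmsep = out$mets$prediction$rmse,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 predictions = predictions, selections = selections,
                 split = split, seed = seed, failures = failures,
                 r2_method = config$r2_method),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", nrow(x$table), "grid cells (seed", x$seed, ")\n")
  if (length(x$failures)) {
    cat("failures:", paste(names(x$failures), collapse = ", "), "\n")
  }
  print(x$table, digits = 4)
  invisible(x)
}

#' Write an evaluation report
#'
#' `report.csv` mirrors the element/model/selector table (RC2, RMSEC, RV2,
#' RMSEV, RP2, RMSEP column order); `report.json` adds the per-cell
#' reference/predicted values so every metric can be recomputed.
#'
#' @param report an [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  data.table::fwrite(report$table, csv)
  js <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(seed = report$seed, r2_method = report$r2_method,
         table = report$table, predictions = report$predictions),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Reference-vs-predicted scatter data
#'
#' Long-format table of reference and predicted concentrations for one
#' grid cell, per subset — the data behind calibration/prediction scatter
#' plots.
#'
#' @param report an [run_experiment()] result.
#' @param element,model,selector cell coordinates.
#' @return data.frame with `subset`, `reference`, `predicted`.
#' @export
prediction_scatter <- function(report, element, model, selector) {
  cell <- paste(element, model, selector, sep = "/")
  pr <- report$predictions[[cell]]
  if (is.null(pr)) stop("no predictions for cell ", cell)
  do.call(rbind, lapply(names(pr), function(s) {
    data.frame(subset = s, reference = pr[[s]]$y_true,
               predicted = pr[[s]]$y_pred, stringsAsFactors = FALSE)
  }))
}
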