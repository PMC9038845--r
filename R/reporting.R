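#' Score an elite archive on held-out validation data
#'
#' Each archived model is refit on the full train/test partition with its
#' own feature subset and hyperparameters, then scored on the untouched
#' validation partition (native, unresampled data). The best model is
#' selected by validation accuracy (classification) or r-squared
#' (regression), ties broken by lower training BIC.
#'
#' @param archive Non-empty list of `evaluated_model`.
#' @param X_train,y_train Train/test partition used for refitting.
#' @param X_val,y_val Held-out validation partition.
#' @param handle An [inner_model()] handle.
#' @return A `validation_report`: data frame `results` (one row per
#'   archived model: features used, train BIC, validation metrics),
#'   `selected` (index of the winning model) and `best_model`.
#' @export
validate_final <- function(archive, X_train, y_train, X_val, y_val, handle) {
  if (length(archive) == 0L) stop("archive is empty")
  metric <- if (handle$task == "classification") "accuracy" else "r2"
  rows <- lapply(seq_along(archive), function(i) {
    m <- archive[[i]]
    feats <- m$chromosome$features
    fit <- fit_inner(handle, X_train[, feats, drop = FALSE], y_train,
                     m$chromosome$hyperparameters)
    preds <- predict_inner(fit, X_val[, feats, drop = FALSE])
    mets <- if (handle$task == "classification") {
      classification_metrics(y_val, preds)
    } else {
      regression_metrics(y_val, preds)
    }
    c(model = i, n_features = length(feats), train_bic = m$bic, mets)
  })
  results <- as.data.frame(do.call(rbind, rows))
  ord <- order(-results[[metric]], results$train_bic)
  selected <- results$model[ord[1L]]
  structure(
    list(results = results, selected = selected,
         best_model = archive[[selected]],
         metric = metric,
         best_metrics = results[results$model == selected, , drop = FALSE]),
    class = "validation_report"
  )
}

#' Default-settings baseline (no evolution, no feature selection)
#'
#' Fits the inner model with its library-default hyperparameters
#' ([default_values()]) on the full feature set under the same adaptive
#' cross-validation used inside the evolutionary loop, for direct
#' comparison against evolved models.
#'
#' @param X,y Training data (all features).
#' @param handle An [inner_model()] handle.
#' @param k_cap Optional fold cap.
#' @return An `evaluated_model` for the default chromosome (provenance
#'   `"random"` is replaced by `"default"`).
#' @export
run_default_baseline <- function(X, y, handle, k_cap = NULL) {
  defaults <- default_values(handle$kind)
  ch <- new_chromosome(defaults, colnames(X), "default")
  evaluate_chromosome(ch, X, y, handle, k_cap = k_cap)
}

#' Write the run reports as delimited text tables
#'
#' Emits, under `dir`: `fitness_trace.tsv` (generation, best BIC),
#' `importance.tsv` (feature, importance for the selected model),
#' `metrics_summary.tsv` (evolved vs. default metrics side by side),
#' `hyperparameters.tsv` (tuned vs. default values), and
#' `run_record.json` (config, seed, queue history, archive summary) —
#' enough to reload and reproduce the run.
#'
#' @param run A `run_result`.
#' @param validation Optional `validation_report`.
#' @param baseline Optional baseline `evaluated_model` from
#'   [run_default_baseline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(run, validation = NULL, baseline = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wtab <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wtab(data.frame(generation = seq_along(run$trace), best_bic = run$trace),
       "fitness_trace.tsv")
  best <- run$archive[[1L]]
  wtab(data.frame(feature = names(best$importances),
                  importance = unname(best$importances)),
       "importance.tsv")
  met <- data.frame(
    metric = c("bic", names(best$metrics)),
    evolved = c(best$bic, unname(best$metrics))
  )
  if (!is.null(baseline)) {
    met$default <- c(baseline$bic, unname(baseline$metrics[names(best$metrics)]))
  }
  if (!is.null(validation)) {
    vb <- validation$best_metrics
    met$validation <- vapply(met$metric, function(m) {
      if (m %in% names(vb)) vb[[m]] else NA_real_
    }, numeric(1))
  }
  wtab(met, "metrics_summary.tsv")
  kind <- best$chromosome$hyperparameters
  wtab(data.frame(hyperparameter = names(kind), tuned = unname(kind)),
       "hyperparameters.tsv")
  record <- list(
    seed = run$seed,
    config = unclass(run$config),
    generations = run$generations,
    converged = run$converged,
    trace = run$trace,
    queue = lapply(run$queue, function(entry) lapply(entry, function(e) {
      list(bic = e$bic, features = e$chromosome$features,
           hyperparameters = as.list(e$chromosome$hyperparameters))
    })),
    archive = lapply(run$archive, function(m) {
      list(bic = m$bic, features = m$chromosome$features,
           hyperparameters = as.list(m$chromosome$hyperparameters),
           metrics = as.list(m$metrics))
    })
  )
  p <- file.path(dir, "run_record.json")
  jsonlite::write_json(record, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}

#' Read / write a run configuration file
#'
#' Round-trips the run configuration (task, model kind, population and
#' convergence settings, warm-start toggle, cutoffs, seed) through a YAML
#' file.
#'
#' @param path File path.
#' @param config Named list to write.
#' @return `read_run_config` returns the named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read / write delimited feature tables
#'
#' Tables are comma- or tab-separated with a header row; empty cells or
#' `"NA"` mark missing values. The target column is split off by name.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @param target Name of the target column.
#' @return List with matrix `X` and vector `y`.
#' @export
read_table_xy <- function(path, target) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE)
  if (!target %in% names(df)) stop("target column '", target, "' not found")
  y <- df[[target]]
  X <- as.matrix(df[setdiff(names(df), target)])
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

#' @rdname read_table_xy
#' @param X Feature matrix.
#' @param y Target vector.
#' @export
write_table_xy <- function(X, y, path, target = "target") {
  df <- as.data.frame(X)
  df[[target]] <- y
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
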