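#' Adaptive number of cross-validation folds
#'
#' The fold count adapts to the size of the selected feature subset:
#' `k = ceiling(n_samples / n_features)`, then clamped to
#' `[max(2, k_min), min(n_samples, k_cap)]`. Models selecting few
#' features are therefore validated with many folds (approaching
#' leave-one-out), while feature-rich models use few folds.
#'
#' @param n_samples Number of rows (>= 2).
#' @param n_features Number of selected features (>= 1).
#' @param k_min Lower clamp (default 2).
#' @param k_cap Optional upper clamp; useful to bound runtime on small
#'   problems where the rule would yield near-leave-one-out.
#' @return Integer fold count.
#' @export
adaptive_k <- function(n_samples, n_features, k_min = 2L, k_cap = NULL) {
  if (n_samples < 2) stop("need at least 2 samples for cross-validation")
  stopifnot(n_features >= 1)
  k <- ceiling(n_samples / n_features)
  k <- max(k, max(2L, as.integer(k_min)))
  cap <- if (is.null(k_cap)) n_samples else min(n_samples, as.integer(k_cap))
  as.integer(min(k, cap))
}

# Fold assignment: stratified per class for classification (each class's
# indices shuffled then dealt round-robin, so per-fold class counts differ
# by at most one), plain shuffled deal for regression.
assign_folds <- function(y, k, task) {
  n <- length(y)
  folds <- integer(n)
  if (task == "classification") {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

#' Out-of-fold cross-validated predictions
#'
#' Fits the inner model k times, each time holding out one fold, and
#' returns the held-out predictions assembled into a single vector so
#' that every sample receives exactly one out-of-fold prediction.
#' Classification predictions are probabilities of the positive class.
#'
#' If a training split lacks one of the classes, the fit is retried with
#' `k - 1` folds, down to `k = 2`.
#'
#' @param handle An [inner_model()] handle.
#' @param chromosome A chromosome (its hyperparameters are used; `X` must
#'   already be restricted to its features).
#' @param X Numeric matrix, samples x selected features.
#' @param y Target vector (0/1 for classification).
#' @param k Number of folds, see [adaptive_k()].
#' @return Numeric vector of out-of-fold predictions, length `nrow(X)`.
#' @export
crossval_predict <- function(handle, chromosome, X, y, k) {
  task <- handle$task
  repeat {
    folds <- assign_folds(y, k, task)
    if (task == "classification") {
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(y[folds != f])) == length(unique(y))
      }, logical(1)))
      if (!ok) {
        if (k <= 2L) stop("a class is absent from a training fold at k = 2")
        k <- k - 1L
        next
      }
    }
    break
  }
  preds <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_inner(handle, X[!test, , drop = FALSE], y[!test],
                     chromosome$hyperparameters)
    preds[test] <- predict_inner(fit, X[test, , drop = FALSE])
  }
  attr(preds, "k") <- k
  preds
}

#' Bayes Information Criterion for regression predictions
#'
#' Gaussian-residual form: `n * ln(max(SSE/n, eps)) + p * ln(n)` with
#' `eps = 1e-12` guarding perfect fits. Lower is better.
#'
#' @param y Observed values.
#' @param y_hat Predictions, same length.
#' @param p Parameter count (>= 1); here the number of selected features
#'   plus one for the intercept.
#' @return Finite scalar BIC.
#' @export
bic_regression <- function(y, y_hat, p) {
  if (length(y) != length(y_hat)) stop("y and y_hat length mismatch")
  n <- length(y)
  stopifnot(n >= 2, p >= 1)
  mse <- max(mean((y - y_hat)^2), 1e-12)
  n * log(mse) + p * log(n)
}

#' Bayes Information Criterion for classification probabilities
#'
#' Bernoulli log-likelihood form: `-2 * sum(log p_hat_i(y_i)) + p * ln(n)`
#' with probabilities clipped to `[1e-12, 1 - 1e-12]`. Lower is better;
#' always strictly positive.
#'
#' @param y Observed 0/1 labels.
#' @param prob Predicted probability of class 1, in `[0, 1]`.
#' @param p Parameter count (>= 1).
#' @return Finite scalar BIC.
#' @export
bic_classification <- function(y, prob, p) {
  if (length(y) != length(prob)) stop("y and prob length mismatch")
  if (any(prob < 0 | prob > 1)) stop("probabilities outside [0, 1]")
  stopifnot(p >= 1)
  n <- length(y)
  pr <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  ll <- sum(log(ifelse(y == 1, pr, 1 - pr)))
  -2 * ll + p * log(n)
}

classification_metrics <- function(y, prob) {
  yhat <- as.integer(prob > 0.5)
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1)
  c(accuracy = mean(yhat == y),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

regression_metrics <- function(y, y_hat) {
  sse <- sum((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  c(mse = mean((y - y_hat)^2),
    explained_variance = if (sst > 0) 1 - stats::var(y - y_hat) / stats::var(y) else 0,
    r2 = if (sst > 0) 1 - sse / sst else 0)
}

#' Evaluate one chromosome: cross-validated metrics, BIC fitness,
#' feature importances
#'
#' Restricts the data to the chromosome's features, cross-validates the
#' inner model with [adaptive_k()] folds, computes performance metrics and
#' the BIC on the pooled out-of-fold predictions (with parameter count
#' `|features| + 1`), then refits on all rows to extract per-feature
#' importances from the model adapter. A failed inner fit yields a
#' sentinel with `bic = Inf` and `failed = TRUE` rather than an error, so
#' an evolutionary run survives occasional pathological candidates.
#'
#' @param chromosome A chromosome.
#' @param X Full feature matrix (samples x all features, named columns).
#' @param y Target vector.
#' @param handle An [inner_model()] handle (fixes family and task).
#' @param k_cap Optional fold cap, passed to [adaptive_k()].
#' @return An `evaluated_model`: the chromosome plus `bic`, `metrics`,
#'   `importances` (keyed by the selected features), `n_folds_used`,
#'   `failed`.
#' @export
evaluate_chromosome <- function(chromosome, X, y, handle, k_cap = NULL) {
  feats <- chromosome$features
  Xs <- X[, feats, drop = FALSE]
  k <- adaptive_k(nrow(Xs), length(feats), k_cap = k_cap)
  res <- tryCatch({
    preds <- crossval_predict(handle, chromosome, Xs, y, k)
    p <- length(feats) + 1L
    if (handle$task == "classification") {
      list(bic = bic_classification(y, preds, p),
           metrics = classification_metrics(y, preds),
           k = attr(preds, "k"))
    } else {
      list(bic = bic_regression(y, preds, p),
           metrics = regression_metrics(y, preds),
           k = attr(preds, "k"))
    }
  }, error = function(e) NULL)
  if (is.null(res)) {
    return(structure(
      list(chromosome = chromosome, bic = Inf,
           metrics = NULL, importances = stats::setNames(rep(0, length(feats)), feats),
           n_folds_used = NA_integer_, failed = TRUE),
      class = "evaluated_model"
    ))
  }
  imp <- tryCatch({
    fit <- fit_inner(handle, Xs, y, chromosome$hyperparameters)
    importances_inner(fit, Xs, y)
  }, error = function(e) stats::setNames(rep(0, length(feats)), feats))
  structure(
    list(chromosome = chromosome, bic = res$bic, metrics = res$metrics,
         importances = imp, n_folds_used = res$k, failed = FALSE),
    class = "evaluated_model"
  )
}
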