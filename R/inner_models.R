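#' Construct an inner-model handle
#'
#' A handle fixes the model family, the task, and the non-evolved
#' settings (network architecture, boosting rounds, ...), and gives the
#' evolutionary loop one uniform contract: fit on a feature-restricted
#' matrix with a chromosome's hyperparameters, predict, and report
#' per-feature importances.
#'
#' Fixed settings and their defaults:
#' \describe{
#'   \item{linear}{none.}
#'   \item{tree}{`nrounds = 100` boosting rounds, learning rate
#'     `eta = 0.3` (library default).}
#'   \item{net}{`hidden = c(300, 300, 300)` (three ReLU layers of 300
#'     neurons), `epochs = 200`, `patience = 3` on a 10% validation
#'     split (`val_fraction = 0.1`). Width/depth are settings, not genes,
#'     and can be shrunk for small problems.}
#'   \item{all}{`importance_repeats = 5` permutation repeats (network
#'     importances only).}
#' }
#'
#' @param kind `"linear"` (elastic net), `"tree"` (gradient-boosted
#'   trees), or `"net"` (Adam-trained feedforward network).
#' @param task `"classification"` (binary, 0/1 labels) or `"regression"`.
#' @param settings Named list overriding the defaults above.
#' @return An object of class `inner_model`.
#' @export
inner_model <- function(kind = c("linear", "tree", "net"),
                        task = c("classification", "regression"),
                        settings = list()) {
  kind <- match.arg(kind)
  task <- match.arg(task)
  defaults <- switch(kind,
    linear = list(),
    tree = list(nrounds = 100L, eta = 0.3),
    net = list(hidden = c(300L, 300L, 300L), epochs = 200L,
               patience = 3L, val_fraction = 0.1)
  )
  defaults$importance_repeats <- 5L
  unknown <- setdiff(names(settings), names(defaults))
  if (length(unknown)) stop("unknown settings: ", paste(unknown, collapse = ", "))
  defaults[names(settings)] <- settings
  structure(list(kind = kind, task = task, settings = defaults),
            class = "inner_model")
}

fit_inner <- function(handle, X, y, hyperparameters) {
  stopifnot(inherits(handle, "inner_model"))
  if (!all(is.finite(as.matrix(X))) || !all(is.finite(y))) {
    stop("non-finite values in training data")
  }
  fit <- switch(handle$kind,
    linear = fit_linear(X, y, hyperparameters[["l1"]],
                        hyperparameters[["l2"]], handle$task),
    tree = fit_gbt(X, y, hyperparameters[["max_depth"]],
                   hyperparameters[["gamma"]], hyperparameters[["alpha"]],
                   handle$task, handle$settings),
    net = fit_ffn(X, y, hyperparameters[["learning_rate"]],
                  hyperparameters[["beta1"]], hyperparameters[["beta2"]],
                  handle$task, handle$settings)
  )
  fit$handle <- handle
  fit
}

predict_inner <- function(fit, X) fit$predict(X)

importances_inner <- function(fit, X, y) fit$importances(X, y)

#' Elastic-net linear learner
#'
#' The two genes are the L1 and L2 penalty weights applied directly, each
#' in `[0, 1]`. They are converted to the total-strength/mixing form the
#' fitting routine uses via the bijection `lambda = l1 + l2`,
#' `alpha = l1 / (l1 + l2)` (inverse: `l1 = alpha * lambda`,
#' `l2 = (1 - alpha) * lambda`); `l1 = l2 = 0` gives an unpenalized fit.
#' For regression the response is standardized internally (and
#' predictions/coefficients rescaled back) so the penalty weights act on
#' a fixed, scale-free objective:
#' `1/(2n) ||y_std - X b||^2 + l1 ||b||_1 + (l2 / 2) ||b||_2^2`.
#' Classification uses the logistic (binomial) family. The importance of
#' feature j is its signed coefficient on the original response scale;
#' rank by absolute value.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Target (0/1 for classification).
#' @param l1_penalty,l2_penalty Penalty weights in `[0, 1]`.
#' @param task `"classification"` or `"regression"`.
#' @return Fit object with `$predict(X)` and `$importances(X, y)`.
#' @export
fit_linear <- function(X, y, l1_penalty, l2_penalty,
                       task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(l1_penalty >= 0, l1_penalty <= 1, l2_penalty >= 0, l2_penalty <= 1)
  X <- as.matrix(X)
  lambda <- l1_penalty + l2_penalty
  mix <- if (lambda > 0) l1_penalty / lambda else 0
  padded <- ncol(X) < 2L
  Xf <- if (padded) cbind(X, .pad. = 0) else X
  family <- if (task == "classification") "binomial" else "gaussian"
  # standardize the response so the penalty strength is scale-free (the
  # fitting routine otherwise rescales lambda by sd(y) internally)
  if (task == "regression") {
    mu <- mean(y)
    s <- sqrt(stats::var(y) * (length(y) - 1) / length(y))
    if (!is.finite(s) || s == 0) s <- 1
    yf <- (y - mu) / s
  } else {
    mu <- 0; s <- 1; yf <- y
  }
  # fit a short descending path ending at the requested lambda, then
  # extract coefficients/predictions exactly at that lambda
  path <- sort(unique(c(lambda + 0.5, lambda + 0.1, lambda)), decreasing = TRUE)
  fit <- suppressWarnings(
    glmnet::glmnet(Xf, yf, family = family, alpha = mix, lambda = path,
                   standardize = FALSE)
  )
  cols <- colnames(X)
  list(
    model = fit, lambda = lambda, padded = padded, task = task,
    predict = function(newX) {
      newX <- as.matrix(newX)
      if (padded) newX <- cbind(newX, .pad. = 0)
      type <- if (task == "classification") "response" else "link"
      drop(stats::predict(fit, newX, s = lambda, type = type,
                          exact = FALSE)) * s + mu
    },
    importances = function(X, y) {
      beta <- drop(stats::coef(fit, s = lambda))[-1L] * s  # drop intercept
      if (padded) beta <- beta[seq_along(cols)]
      stats::setNames(as.numeric(beta), cols)
    }
  )
}

#' Gradient-boosted tree learner
#'
#' Ensemble of boosted regression/classification trees. Evolved genes:
#' maximum tree depth, the node-partition threshold (minimum loss
#' reduction required to split, "gamma"), and the L1 weight penalty
#' ("alpha"). Importances are the ensemble's native gain-based feature
#' importances; features never used in a split score 0.
#'
#' @param X Numeric matrix with column names.
#' @param y Target (0/1 for classification).
#' @param max_depth Integer depth in `[2, 10]` (the baseline default 6 is
#'   also accepted through the same range check).
#' @param gamma Minimum split loss reduction, >= 0.
#' @param alpha L1 weight penalty, >= 0.
#' @param task `"classification"` or `"regression"`.
#' @param settings List with `nrounds` and `eta`.
#' @return Fit object with `$predict(X)` and `$importances(X, y)`.
#' @export
fit_gbt <- function(X, y, max_depth, gamma, alpha,
                    task = c("classification", "regression"),
                    settings = list(nrounds = 100L, eta = 0.3)) {
  task <- match.arg(task)
  if (max_depth < 2 || max_depth > 10) stop("max_depth outside [2, 10]")
  stopifnot(gamma >= 0, alpha >= 0)
  X <- as.matrix(X)
  obj <- if (task == "classification") "binary:logistic" else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  model <- xgboost::xgb.train(
    params = list(objective = obj, max_depth = as.integer(round(max_depth)),
                  gamma = gamma, alpha = alpha, eta = settings$eta,
                  nthread = 1),
    data = dtrain, nrounds = settings$nrounds, verbose = 0
  )
  cols <- colnames(X)
  list(
    model = model, task = task,
    predict = function(newX) {
      stats::predict(model, xgboost::xgb.DMatrix(as.matrix(newX), nthread = 1))
    },
    importances = function(X, y) {
      imp <- stats::setNames(rep(0, length(cols)), cols)
      tab <- tryCatch(xgboost::xgb.importance(model = model),
                      error = function(e) NULL)
      if (!is.null(tab) && nrow(tab) > 0) {
        imp[tab$Feature] <- tab$Gain
      }
      imp
    }
  )
}

#' Feedforward neural network learner
#'
#' Fully connected network with ReLU hidden activations trained by Adam,
#' early-stopped on a held-out validation split (patience 3 on validation
#' loss), softmax output for classification. Evolved genes: the Adam
#' learning rate and the two moment-decay rates beta1/beta2. Architecture
#' (layers x width) is a fixed setting. Importances are computed by
#' permutation (see [permutation_importance()]) since the network has no
#' native per-feature attribution.
#'
#' @param X Numeric matrix.
#' @param y Target (0/1 for classification).
#' @param learning_rate Adam step size, > 0.
#' @param beta1,beta2 Adam moment decay rates in `[0.9, 0.999]`.
#' @param task `"classification"` or `"regression"`.
#' @param settings List with `hidden`, `epochs`, `patience`,
#'   `val_fraction`, `importance_repeats`.
#' @return Fit object with `$predict(X)` and `$importances(X, y)`.
#' @export
fit_ffn <- function(X, y, learning_rate, beta1, beta2,
                    task = c("classification", "regression"),
                    settings = list()) {
  task <- match.arg(task)
  stopifnot(learning_rate > 0)
  s <- utils::modifyList(
    list(hidden = c(300L, 300L, 300L), epochs = 200L, patience = 3L,
         val_fraction = 0.1, importance_repeats = 5L), settings)
  model <- mlp_fit(as.matrix(X), y, task, hidden = s$hidden,
                   learning_rate = learning_rate, beta1 = beta1,
                   beta2 = beta2, epochs = s$epochs, patience = s$patience,
                   val_fraction = s$val_fraction)
  list(
    model = model, task = task,
    predict = function(newX) mlp_predict(model, newX),
    importances = function(X, y) {
      self <- list(model = model, task = task,
                   predict = function(newX) mlp_predict(model, newX))
      permutation_importance(self, X, y, repeats = s$importance_repeats)
    }
  )
}

#' Permutation feature importance
#'
#' The importance of feature j is the mean drop in a performance metric
#' when column j is shuffled (within the evaluation set only), over
#' `repeats` independent shuffles: features the model does not rely on
#' score near zero, load-bearing features score positive.
#'
#' @param fit A fit object with `$predict(X)` and `$task`.
#' @param X Evaluation matrix.
#' @param y Evaluation target.
#' @param metric `"accuracy"`, `"r2"`, or a function `(y, pred) ->`
#'   scalar (larger is better). Default: accuracy for classification,
#'   r-squared for regression.
#' @param repeats Number of shuffles per feature (>= 1).
#' @return Named numeric vector, one entry per column of `X`.
#' @export
permutation_importance <- function(fit, X, y, metric = NULL, repeats = 5L) {
  if (repeats < 1) stop("repeats must be >= 1")
  X <- as.matrix(X)
  score <- if (is.function(metric)) metric else {
    metric <- if (is.null(metric)) {
      if (fit$task == "classification") "accuracy" else "r2"
    } else metric
    switch(metric,
      accuracy = function(y, p) mean(as.integer(p > 0.5) == y),
      r2 = function(y, p) {
        sst <- sum((y - mean(y))^2)
        if (sst > 0) 1 - sum((y - p)^2) / sst else 0
      },
      stop("unknown metric: ", metric)
    )
  }
  baseline <- score(y, fit$predict(X))
  vapply(seq_len(ncol(X)), function(j) {
    drops <- vapply(seq_len(repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      baseline - score(y, fit$predict(Xp))
    }, numeric(1))
    mean(drops)
  }, numeric(1)) |> stats::setNames(colnames(X))
}
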