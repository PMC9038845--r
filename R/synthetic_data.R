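#' Specification for a synthetic tabular dataset with planted signal
#'
#' Describes a dataset shaped like a multi-instrument bio-psycho-social
#' battery: many continuous features of which only a sparse subset drives
#' the target, collinear near-copies of informative features, a skewed
#' fraction of marginals, missing-completely-at-random cells at
#' per-feature rates up to `missing_max`, and (for classification) class
#' imbalance.
#'
#' @param n_samples Rows (default 1000).
#' @param n_features Columns (default 160).
#' @param n_informative Features that drive the target (default 5).
#' @param effect_sizes Linear coefficients of the informative features;
#'   default evenly spaced from 1.5 down to 0.5.
#' @param interaction_pairs Optional list of index pairs (into the
#'   informative set) whose product is added to the signal.
#' @param noise_sd Gaussian noise on the continuous target (default 0.5).
#' @param n_redundant Near-copies of informative features (default 5);
#'   copy noise sd is 0.1 of the parent's sd.
#' @param skewed_fraction Fraction of the pure-noise features that are
#'   exponentiated to produce skewed marginals (default 0.3).
#' @param missing_max Per-feature missingness rates are drawn uniformly
#'   from `[0, missing_max]` (default 0.5, the study-like ceiling).
#' @param task `"regression"` or `"classification"`.
#' @param imbalance Target case fraction for classification in `(0, 0.5]`
#'   (default 0.3).
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 1000L, n_features = 160L,
                           n_informative = 5L, effect_sizes = NULL,
                           interaction_pairs = NULL, noise_sd = 0.5,
                           n_redundant = 5L, skewed_fraction = 0.3,
                           missing_max = 0.5,
                           task = c("regression", "classification"),
                           imbalance = 0.3) {
  task <- match.arg(task)
  stopifnot(n_informative >= 1, n_informative + n_redundant <= n_features,
            imbalance > 0, imbalance <= 1, missing_max >= 0, missing_max <= 1)
  if (is.null(effect_sizes)) {
    effect_sizes <- if (n_informative == 1L) 1 else
      seq(1.5, 0.5, length.out = n_informative)
  }
  stopifnot(length(effect_sizes) == n_informative)
  structure(
    list(n_samples = as.integer(n_samples),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_sizes = effect_sizes, interaction_pairs = interaction_pairs,
         noise_sd = noise_sd, n_redundant = as.integer(n_redundant),
         skewed_fraction = skewed_fraction, missing_max = missing_max,
         task = task, imbalance = imbalance),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset with known ground truth
#'
#' Informative features drive the target linearly (plus optional pairwise
#' interactions). Regression targets add Gaussian noise; classification
#' targets are Bernoulli draws through a logistic link whose intercept is
#' tuned by bisection so the expected case fraction matches the requested
#' imbalance. Redundant features are informative features plus small
#' noise; a fraction of the noise features is exponentiated to produce
#' skew; finally cells go missing completely at random at per-feature
#' rates.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed; with a seed the dataset is fully
#'   reproducible.
#' @return List with `X` (named matrix, `NA` for missing), `X_complete`
#'   (before masking), `y`, `task`, and `ground_truth` (informative
#'   feature names, coefficients, redundant and skewed feature names).
#' @export
generate_synthetic <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_samples; p <- spec$n_features
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  inf_idx <- seq_len(spec$n_informative)
  signal <- drop(X[, inf_idx, drop = FALSE] %*% spec$effect_sizes)
  for (pr in spec$interaction_pairs) {
    signal <- signal + X[, inf_idx[pr[1]]] * X[, inf_idx[pr[2]]]
  }
  if (spec$task == "regression") {
    y <- signal + stats::rnorm(n, sd = spec$noise_sd)
  } else {
    # bisection on the intercept so that mean expected case probability
    # hits the requested imbalance
    target <- spec$imbalance
    f <- function(b) mean(stats::plogis(b + signal)) - target
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0) stop("requested imbalance unattainable")
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    y <- stats::rbinom(n, 1L, stats::plogis((lo + hi) / 2 + signal))
  }
  red_idx <- if (spec$n_redundant > 0) {
    idx <- spec$n_informative + seq_len(spec$n_redundant)
    parents <- rep_len(inf_idx, spec$n_redundant)
    for (i in seq_along(idx)) {
      ps <- stats::sd(X[, parents[i]])
      X[, idx[i]] <- X[, parents[i]] + stats::rnorm(n, sd = 0.1 * ps)
    }
    idx
  } else integer(0)
  noise_idx <- setdiff(seq_len(p), c(inf_idx, red_idx))
  n_skew <- round(spec$skewed_fraction * length(noise_idx))
  skew_idx <- if (n_skew > 0) sort(sample(noise_idx, n_skew)) else integer(0)
  for (j in skew_idx) X[, j] <- exp(X[, j])
  X_complete <- X
  if (spec$missing_max > 0) {
    rates <- stats::runif(p, 0, spec$missing_max)
    for (j in seq_len(p)) {
      miss <- stats::runif(n) < rates[j]
      # never blank out a full column
      if (sum(miss) >= n - 1L) miss[sample(which(miss), 2L)] <- FALSE
      X[miss, j] <- NA
    }
  }
  cols <- colnames(X)
  list(X = X, X_complete = X_complete, y = y, task = spec$task,
       ground_truth = list(
         informative = cols[inf_idx], coefficients = spec$effect_sizes,
         redundant = cols[red_idx], skewed = cols[skew_idx]))
}

#' Exhaustive best-subset oracle by cross-validated BIC
#'
#' Brute-force reference for small problems: enumerates every non-empty
#' feature subset (at most 15 features), scores each with out-of-fold
#' least-squares (regression) or logistic (classification) predictions
#' under the same fold scheme and BIC formulas as the evolutionary path,
#' and returns the minimizer. The model fits here are plain `lm.fit` /
#' `glm.fit`, an independent route from the package's inner-model
#' adapters.
#'
#' @param X Complete numeric matrix with at most 15 columns.
#' @param y Target.
#' @param task `"regression"` or `"classification"`.
#' @param k_cap Fold cap matching the evolutionary configuration.
#' @param seed Optional seed for the fold draws.
#' @return List with `features` (best subset), `bic`, and the full
#'   enumeration table `all` (subset, bic).
#' @export
oracle_best_subset <- function(X, y, task = c("regression", "classification"),
                               k_cap = NULL, seed = NULL) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (ncol(X) > 15L) stop("refusing exhaustive search over more than 15 features")
  if (!is.null(seed)) set.seed(seed)
  cols <- colnames(X)
  subsets <- unlist(lapply(seq_len(ncol(X)), function(k)
    utils::combn(ncol(X), k, simplify = FALSE)), recursive = FALSE)
  bics <- vapply(subsets, function(s) {
    Xs <- X[, s, drop = FALSE]
    k <- adaptive_k(nrow(Xs), length(s), k_cap = k_cap)
    folds <- assign_folds(y, k, task)
    preds <- numeric(length(y))
    for (f in seq_len(k)) {
      test <- folds == f
      Xtr <- cbind(1, Xs[!test, , drop = FALSE])
      Xte <- cbind(1, Xs[test, , drop = FALSE])
      if (task == "regression") {
        beta <- stats::lm.fit(Xtr, y[!test])$coefficients
        beta[is.na(beta)] <- 0
        preds[test] <- drop(Xte %*% beta)
      } else {
        fit <- suppressWarnings(
          stats::glm.fit(Xtr, y[!test], family = stats::binomial()))
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        preds[test] <- stats::plogis(drop(Xte %*% beta))
      }
    }
    p <- length(s) + 1L
    if (task == "regression") bic_regression(y, preds, p)
    else bic_classification(y, preds, p)
  }, numeric(1))
  best <- which.min(bics)
  list(features = cols[subsets[[best]]], bic = bics[best],
       all = data.frame(
         subset = vapply(subsets, function(s) paste(cols[s], collapse = ","),
                         character(1)),
         bic = bics, stringsAsFactors = FALSE))
}
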