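# Small seeded fixtures used across the suite.

small_regression <- function(seed = 1, n = 150, p = 12, informative = 2,
                             noise_sd = 0.3) {
  spec <- synthetic_spec(n_samples = n, n_features = p,
                         n_informative = informative, n_redundant = 0,
                         skewed_fraction = 0, missing_max = 0,
                         noise_sd = noise_sd, task = "regression")
  generate_synthetic(spec, seed = seed)
}

small_classification <- function(seed = 1, n = 200, p = 10, informative = 2,
                                 imbalance = 0.4) {
  spec <- synthetic_spec(n_samples = n, n_features = p,
                         n_informative = informative, n_redundant = 0,
                         skewed_fraction = 0, missing_max = 0,
                         task = "classification", imbalance = imbalance)
  generate_synthetic(spec, seed = seed)
}

linear_space <- function(pool, subset_max = 50) {
  builtin_space("linear", pool, subset_max = subset_max)
}

# evaluated_model stub with a prescribed fitness, for operator tests that
# do not need real model fits
stub_model <- function(bic, features, hp = c(l1 = 0.1, l2 = 0.1),
                       importances = NULL) {
  ch <- structure(list(hyperparameters = hp, features = features,
                       provenance = "random"), class = "chromosome")
  if (is.null(importances)) {
    importances <- stats::setNames(rep(1, length(features)), features)
  }
  structure(list(chromosome = ch, bic = bic, metrics = c(r2 = 0),
                 importances = importances, n_folds_used = 2L,
                 failed = !is.finite(bic)),
            class = "evaluated_model")
}
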