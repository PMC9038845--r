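#' Random train/test vs. validation split
#'
#' Partitions rows at random; all subsequent preparation statistics are
#' fitted independently within each partition so the held-out side never
#' leaks into the other.
#'
#' @param n_rows Number of rows, or a data frame / matrix.
#' @param fraction Proportion assigned to the train/test partition
#'   (default 0.7).
#' @return List with integer index vectors `train_test` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_data <- function(n_rows, fraction = 0.7) {
  if (!is.numeric(n_rows) || length(n_rows) > 1L) n_rows <- nrow(n_rows)
  stopifnot(fraction > 0, fraction < 1)
  n_tt <- round(fraction * n_rows)
  if (n_tt < 2L || n_rows - n_tt < 2L) {
    stop("split would leave fewer than 2 samples in a partition")
  }
  tt <- sort(sample.int(n_rows, n_tt))
  list(train_test = tt, validation = setdiff(seq_len(n_rows), tt))
}

#' Drop features with excessive missingness
#'
#' Removes features whose missing fraction is strictly greater than the
#' cutoff; a feature at exactly the cutoff is kept.
#'
#' @param X Matrix or data frame with `NA` for missing cells.
#' @param max_missing_fraction Cutoff in `[0, 1]` (default 0.4).
#' @return `X` without the dropped columns; dropped names in attribute
#'   `"dropped"`.
#' @export
drop_high_missing <- function(X, max_missing_fraction = 0.4) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  X <- as.matrix(X)
  frac <- colMeans(is.na(X))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("all features exceed the missingness cutoff")
  out <- X[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}

#' Winsorize features to mean +/- z standard deviations
#'
#' Outliers are clipped (not deleted): each column is clipped to
#' `[mean - z*sd, mean + z*sd]` with the moments computed from the input
#' column, ignoring missing entries. Zero-variance columns are left
#' unchanged. The fitted bounds are returned in attribute `"bounds"`;
#' re-applying them (`bounds =`) reproduces the output exactly, the
#' transformer-style idempotence used when a fitted pipeline is replayed.
#'
#' @param X Matrix or data frame (may contain `NA`).
#' @param z Number of standard deviations (default 3, > 0).
#' @param bounds Optional 2 x ncol matrix of precomputed clip bounds
#'   (rows: lower, upper); when given, `z` is ignored.
#' @return Clipped matrix, same shape, with attribute `"bounds"`.
#' @export
winsorize <- function(X, z = 3, bounds = NULL) {
  stopifnot(z > 0)
  X <- as.matrix(X)
  if (is.null(bounds)) {
    bounds <- vapply(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      m <- mean(x, na.rm = TRUE)
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s) || s == 0) c(-Inf, Inf) else c(m - z * s, m + z * s)
    }, numeric(2))
  }
  for (j in seq_len(ncol(X))) {
    X[, j] <- pmin(pmax(X[, j], bounds[1L, j]), bounds[2L, j])
  }
  attr(X, "bounds") <- bounds
  X
}

#' Impute missing values by masked non-negative matrix factorization
#'
#' If the matrix has negative entries it is shifted to be non-negative
#' (the shift is recorded and reversed afterwards; already non-negative
#' matrices are used as-is). It is factorized as `W %*% H` by multiplicative
#' updates computed only over the observed cells, and the missing cells
#' are filled from the low-rank reconstruction. Observed cells are never
#' altered.
#'
#' @param X Matrix with `NA` for missing cells.
#' @param rank Factorization rank (default `min(10, ceiling(ncol/4))`).
#' @param max_iter Maximum update iterations (default 500).
#' @param tol Relative change in observed-cell loss for convergence
#'   (default 1e-5).
#' @return Completed matrix; the per-iteration observed-cell loss in
#'   attribute `"loss"`.
#' @export
nmf_impute <- function(X, rank = NULL, max_iter = 500L, tol = 1e-5) {
  X <- as.matrix(X)
  M <- !is.na(X)
  if (all(M)) return(X)
  if (any(rowSums(M) == 0)) {
    stop("row(s) fully missing: ", paste(which(rowSums(M) == 0), collapse = ", "))
  }
  if (any(colSums(M) == 0)) {
    stop("column(s) fully missing: ",
         paste(colnames(X)[colSums(M) == 0], collapse = ", "))
  }
  if (is.null(rank)) rank <- max(1L, min(10L, ceiling(ncol(X) / 4)))
  shift <- min(0, min(X, na.rm = TRUE))
  A <- X - shift
  A[!M] <- 0
  eps <- 1e-9
  scale0 <- sqrt(mean(A[M]) / rank + eps)
  W <- matrix(stats::runif(nrow(A) * rank, 0, scale0), nrow(A), rank)
  H <- matrix(stats::runif(rank * ncol(A), 0, scale0), rank, ncol(A))
  loss <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    R <- (W %*% H) * M
    W <- W * ((A %*% t(H)) / (R %*% t(H) + eps))
    R <- (W %*% H) * M
    H <- H * ((t(W) %*% A) / (t(W) %*% R + eps))
    R <- (W %*% H) * M
    cur <- sum((A - R)[M]^2)
    loss <- c(loss, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, eps)) break
    prev <- cur
  }
  recon <- W %*% H + shift
  out <- X
  out[!M] <- recon[!M]
  attr(out, "loss") <- loss
  out
}

#' Min-max scale each feature to [0, 1]
#'
#' `x -> (x - min) / (max - min)`; constant features map to 0.
#'
#' @param X Complete numeric matrix.
#' @return Scaled matrix.
#' @export
minmax_scale <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("scale after imputation: matrix contains NA")
  apply(X, 2, function(x) {
    r <- max(x) - min(x)
    if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  })
}

sample_skewness <- function(x) e1071::skewness(x, type = 2)
sample_exkurtosis <- function(x) e1071::kurtosis(x, type = 2)

normality_score <- function(x) {
  abs(sample_skewness(x)) + abs(sample_exkurtosis(x))
}

yeo_johnson <- function(x, lambda) {
  pos <- x >= 0
  out <- numeric(length(x))
  if (abs(lambda) > 1e-8) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-8) {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

fit_yeo_johnson <- function(x) {
  # profile log-likelihood over a lambda grid (standard power-transform MLE)
  grid <- seq(-2, 2, by = 0.1)
  ll <- vapply(grid, function(l) {
    z <- yeo_johnson(x, l)
    s2 <- stats::var(z) * (length(z) - 1) / length(z)
    if (s2 <= 0) return(-Inf)
    -length(x) / 2 * log(s2) + (l - 1) * sum(sign(x) * log1p(abs(x)))
  }, numeric(1))
  grid[which.max(ll)]
}

#' Select the transform that best normalizes a feature
#'
#' Candidates: identity, rank-based normal-quantile transform
#' (`qnorm((rank - 0.5) / n)`), and a Yeo-Johnson power transform with
#' maximum-likelihood lambda. The normality score is
#' `|skewness| + |excess kurtosis|`; the lowest score wins, ties going to
#' the identity. Constant vectors return the identity.
#'
#' @param x Numeric vector with at least 20 non-missing values.
#' @return List with `x` (transformed vector), `transform` (one of
#'   `"identity"`, `"quantile_normal"`, `"power"`), and `scores`.
#' @export
select_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 20L) stop("need at least 20 non-missing values")
  if (stats::sd(x[ok]) == 0) {
    return(list(x = x, transform = "identity",
                scores = c(identity = 0, quantile_normal = NA, power = NA)))
  }
  qn <- x
  qn[ok] <- stats::qnorm((rank(x[ok]) - 0.5) / sum(ok))
  pw <- x
  pw[ok] <- yeo_johnson(x[ok], fit_yeo_johnson(x[ok]))
  cands <- list(identity = x, quantile_normal = qn, power = pw)
  scores <- vapply(cands, function(v) normality_score(v[ok]), numeric(1))
  best <- names(scores)[which.min(scores)]        # ties: identity is first
  list(x = cands[[best]], transform = best, scores = scores)
}

#' Collapse an item battery into one summary feature
#'
#' Items are standardized and recursively merged by Ward-linkage
#' agglomeration down to a single cluster; in that one-cluster limit the
#' summary is the equally weighted mean of the standardized items,
#' returned on the standardized scale. Symmetric in item order.
#'
#' @param items Matrix (samples x items), at least 2 items, no missing
#'   values.
#' @return Numeric summary vector, one value per sample, with the merge
#'   tree in attribute `"merge"`.
#' @export
agglomerate_summary <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items to agglomerate")
  if (anyNA(items)) stop("items contain missing values")
  Z <- apply(items, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  tree <- stats::hclust(stats::dist(t(Z)), method = "ward.D2")
  out <- rowMeans(Z)
  attr(out, "merge") <- tree$merge
  out
}

#' Discretize a continuous score into case / non-case labels
#'
#' @param scores Continuous target scores.
#' @param cutoff Threshold; label 1 (case) iff `score > cutoff`. There is
#'   no built-in default — the cutoff is a required, data-specific
#'   configuration input.
#' @return Integer 0/1 labels.
#' @export
discretize_target <- function(scores, cutoff) {
  labels <- as.integer(scores > cutoff)
  if (length(unique(labels)) < 2L) {
    stop("cutoff produces a single class; choose a cutoff inside the score range")
  }
  labels
}

knn_index <- function(A, B, k) {
  # rows of A queried against rows of B; returns index matrix (n_A x k)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

#' Balance binary classes by synthetic oversampling plus neighborhood
#' cleaning
#'
#' First the minority class is oversampled to parity: each synthetic
#' sample interpolates between a random minority sample and one of its k
#' nearest minority neighbours (`k = 5`, reduced to `minority - 1` when
#' fewer neighbours exist). Then edited-nearest-neighbour cleaning
#' (`k = 3`) removes every sample — original or synthetic — whose
#' neighbourhood majority disagrees with its own label, trimming the
#' ambiguous boundary region. Apply only to train/test data; held-out
#' validation stays native.
#'
#' @param X Numeric matrix.
#' @param y Binary 0/1 labels; minority count must be >= 2.
#' @param k_smote,k_enn Neighbourhood sizes.
#' @return List with resampled `X`, `y`, and a `report` of the class
#'   counts before/after each step.
#' @export
balance_classes <- function(X, y, k_smote = 5L, k_enn = 3L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  counts <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < 2L) stop("minority class needs at least 2 samples")
  Xs <- X; ys <- y
  n_syn <- n_maj - n_min
  if (n_syn > 0) {
    Xmin <- X[y == minority, , drop = FALSE]
    k <- min(k_smote, n_min - 1L)
    nn <- knn_index(Xmin, Xmin, k + 1L)[, -1L, drop = FALSE]  # drop self
    base <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    syn <- Xmin[base, , drop = FALSE] +
      u * (Xmin[pick, , drop = FALSE] - Xmin[base, , drop = FALSE])
    Xs <- rbind(X, syn)
    ys <- c(y, rep(minority, n_syn))
  }
  after_smote <- table(factor(ys, levels = c(0, 1)))
  nn_all <- knn_index(Xs, Xs, min(k_enn + 1L, nrow(Xs)))[, -1L, drop = FALSE]
  neigh_vote <- rowMeans(matrix(ys[nn_all], nrow = nrow(Xs)))
  keep <- as.integer(neigh_vote > 0.5) == ys
  if (!any(keep)) keep <- rep(TRUE, length(ys))
  list(X = Xs[keep, , drop = FALSE], y = ys[keep],
       report = list(before = as.vector(counts),
                     after_oversampling = as.vector(after_smote),
                     after_cleaning = as.vector(
                       table(factor(ys[keep], levels = c(0, 1))))))
}

#' Run the full preparation pipeline on one partition
#'
#' Fixed stage order: missingness filter, winsorize, NMF imputation,
#' min-max scaling, per-feature transform selection, then (classification
#' only) target discretization and SMOTE+ENN balancing. Statistics are
#' fitted on the given partition only; call once per partition.
#'
#' @param X Raw feature matrix (named columns, `NA` for missing).
#' @param y Raw continuous target.
#' @param task `"regression"` or `"classification"`.
#' @param cutoff Required when classifying: case threshold on `y`.
#' @param balance Apply SMOTE+ENN (classification train/test only;
#'   set `FALSE` for the validation partition).
#' @param max_missing_fraction,z,nmf_rank Stage parameters.
#' @return List with prepared `X`, `y`, and a `report` (dropped features,
#'   transforms chosen, resampling sizes).
#' @export
prepare_partition <- function(X, y, task = c("regression", "classification"),
                              cutoff = NULL, balance = TRUE,
                              max_missing_fraction = 0.4, z = 3,
                              nmf_rank = NULL) {
  task <- match.arg(task)
  X <- drop_high_missing(as.matrix(X), max_missing_fraction)
  dropped <- attr(X, "dropped")
  X <- winsorize(X, z)
  n_imputed <- sum(is.na(X))
  if (anyNA(X)) X <- nmf_impute(X, rank = nmf_rank)
  X <- minmax_scale(X)
  transforms <- character(ncol(X))
  for (j in seq_len(ncol(X))) {
    tr <- select_transform(X[, j])
    X[, j] <- tr$x
    transforms[j] <- tr$transform
  }
  names(transforms) <- colnames(X)
  report <- list(dropped_features = dropped, imputed_cells = n_imputed,
                 transforms = transforms)
  if (task == "classification") {
    if (is.null(cutoff)) stop("classification requires a case cutoff")
    y <- discretize_target(y, cutoff)
    if (balance) {
      bal <- balance_classes(X, y)
      X <- bal$X; y <- bal$y
      report$resampling <- bal$report
    }
  }
  list(X = X, y = y, report = report)
}
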