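test_that("splitting partitions rows disjointly at the requested fraction", {
  set.seed(81)
  sp <- split_data(1000, 0.7)
  expect_length(sp$train_test, 700)
  expect_length(sp$validation, 300)
  expect_length(intersect(sp$train_test, sp$validation), 0)
  expect_setequal(c(sp$train_test, sp$validation), 1:1000)
  set.seed(82); a <- split_data(100, 0.7)
  set.seed(82); b <- split_data(100, 0.7)
  expect_identical(a, b)
  expect_error(split_data(3, 0.7), "fewer than 2")
})

test_that("missingness filter is strict at the cutoff", {
  X <- cbind(a = c(NA, NA, NA, NA, 1, 2, 3, 4, 5, 6),     # 40%: kept
             b = c(NA, NA, NA, NA, NA, 2, 3, 4, 5, 6),    # 50%: dropped
             c = 1:10)
  out <- drop_high_missing(X, 0.4)
  expect_equal(colnames(out), c("a", "c"))
  expect_equal(attr(out, "dropped"), "b")
  # 41% > 40% is dropped
  X2 <- cbind(d = c(rep(NA, 41), runif(59)), e = runif(100))
  expect_equal(colnames(drop_high_missing(X2, 0.4)), "e")
  # no missing values: identity
  X3 <- matrix(1:20, 5, dimnames = list(NULL, paste0("k", 1:4)))
  expect_equal(drop_high_missing(X3)[, ], X3[, ])
  expect_error(drop_high_missing(matrix(NA_real_, 4, 2), 0.4), "all features")
})

test_that("winsorizing clips to mean +/- z sd and is idempotent", {
  set.seed(83)
  x <- c(rnorm(100), 50, -50)
  m <- mean(x); s <- sd(x)
  w <- winsorize(matrix(x, ncol = 1), z = 3)[, 1]
  expect_equal(max(w), m + 3 * s)
  expect_equal(min(w), m - 3 * s)
  expect_equal(w[1:100], x[1:100])  # interior points untouched
  # replaying the fitted bounds is exactly idempotent
  w1 <- winsorize(matrix(x, ncol = 1), z = 3)
  w2 <- winsorize(w1, bounds = attr(w1, "bounds"))
  expect_equal(w2[, 1], w1[, 1])
  # all values within bounds: identity
  y <- rnorm(50, sd = 0.1)
  expect_equal(winsorize(matrix(y, ncol = 1))[, 1], y)
  # zero-variance column unchanged, missing entries preserved
  z <- matrix(c(rep(2, 5), NA, 1, 2, 3, 100), ncol = 2)
  wz <- winsorize(z)
  expect_equal(wz[, 1], rep(2, 5))
  expect_true(is.na(wz[1, 2]))
})

test_that("masked NMF recovers a rank-1 structure and never touches observed cells", {
  set.seed(84)
  u <- runif(20, 1, 2); v <- runif(8, 1, 2)
  X <- u %*% t(v)
  Xm <- X; Xm[3, 5] <- NA
  out <- nmf_impute(Xm, rank = 1)
  expect_lt(abs(out[3, 5] - X[3, 5]) / X[3, 5], 0.01)
  expect_equal(out[-3, ], X[-3, ])  # observed cells untouched
  expect_equal(out[3, -5], X[3, -5])
  # observed-cell loss is non-increasing across iterations
  set.seed(85)
  Y <- matrix(runif(300, 0, 5), 30, 10)
  Y[sample(300, 60)] <- NA
  Y <- ifelse(is.na(Y) & (rowSums(!is.na(Y)) == 0), 1, Y)  # guard, no-op here
  res <- nmf_impute(Y, rank = 3)
  loss <- attr(res, "loss")
  expect_true(all(diff(loss) <= 1e-8 * max(loss)))
  expect_false(anyNA(res))
  # no missing cells: identity
  Z <- matrix(runif(20), 5, 4)
  expect_identical(nmf_impute(Z), Z)
  # fully missing column is a named error
  bad <- matrix(runif(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  bad[, 2] <- NA
  expect_error(nmf_impute(bad), "b")
})

test_that("negative-valued matrices are shifted, imputed, and shifted back", {
  set.seed(86)
  u <- runif(15, 1, 2); v <- runif(6, 1, 2)
  X <- u %*% t(v) - 3        # strictly negative entries exist
  Xm <- X; Xm[2, 2] <- NA
  out <- nmf_impute(Xm, rank = 2)  # the min-shift adds one rank
  expect_lt(abs(out[2, 2] - X[2, 2]), 0.1)
})

test_that("min-max scaling maps to [0, 1] with constant columns at 0", {
  X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  out <- minmax_scale(X)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0, 0, 0))
  set.seed(87)
  Y <- minmax_scale(matrix(rnorm(60), 20, 3))
  expect_equal(unname(apply(Y, 2, min)), rep(0, 3))
  expect_equal(unname(apply(Y, 2, max)), rep(1, 3))
})

test_that("transform selection picks the best-normalizing candidate by score", {
  set.seed(88)
  x <- rexp(500)
  res <- select_transform(x)
  expect_true(res$transform != "identity")
  expect_lt(res$scores[[res$transform]], res$scores[["identity"]])
  # already-normal data: identity wins or ties
  z <- rnorm(500)
  rz <- select_transform(z)
  expect_lte(rz$scores[["identity"]],
             min(rz$scores[["quantile_normal"]], rz$scores[["power"]]) + 0.5)
  # constant vector: identity
  expect_equal(select_transform(rep(1, 30))$transform, "identity")
  expect_error(select_transform(rnorm(10)), "20")
})

test_that("agglomerated summaries behave like standardized item means", {
  set.seed(89)
  a <- rnorm(40)
  two <- cbind(i1 = a, i2 = a)  # identical items
  s <- agglomerate_summary(two)
  expect_equal(unname(s[seq_along(a)]), unname(scale(a)[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # independent noise items: averaging shrinks variance
  M <- matrix(rnorm(200), 40, 5)
  expect_lt(var(agglomerate_summary(M)), 1)
  # symmetric in item order
  perm <- M[, c(3, 1, 5, 2, 4)]
  expect_equal(as.numeric(agglomerate_summary(M)),
               as.numeric(agglomerate_summary(perm)))
  expect_error(agglomerate_summary(M[, 1, drop = FALSE]), "at least 2")
})

test_that("target discretization thresholds strictly above the cutoff", {
  expect_equal(discretize_target(c(0, 0, 5, 9), 0), c(0L, 0L, 1L, 1L))
  expect_error(discretize_target(c(1, 2, 3), 10), "single class")
  labs <- discretize_target(rnorm(50), 0)
  expect_equal(length(labs), 50)
  expect_true(all(labs %in% 0:1))
})

test_that("SMOTE+ENN balances a 90/10 problem and synthesizes on segments", {
  set.seed(90)
  X <- rbind(matrix(rnorm(180 * 2, mean = 0), 180, 2),
             matrix(rnorm(20 * 2, mean = 4), 20, 2))
  y <- c(rep(0L, 180), rep(1L, 20))
  out <- balance_classes(X, y)
  expect_equal(out$report$after_oversampling, c(180L, 180L))
  ratio <- out$report$after_cleaning[2] / out$report$after_cleaning[1]
  expect_gte(ratio, 0.7); expect_lte(ratio, 1.3)
  # synthetic minority points lie in the minority's convex region: with
  # well-separated clusters every kept case is near the case centroid
  cases <- out$X[out$y == 1, , drop = FALSE]
  expect_true(all(rowSums(abs(cases - 4) < 4) == 2))
  # already balanced, separated clusters: cleaning removes almost nothing
  Xb <- rbind(matrix(rnorm(100, -5), 50, 2), matrix(rnorm(100, 5), 50, 2))
  yb <- rep(0:1, each = 50)
  outb <- balance_classes(Xb, yb)
  expect_gte(length(outb$y), 98)
  expect_error(balance_classes(X[1:181, ], y[1:181]), "at least 2")
})

test_that("synthetic interpolation stays on segments between minority neighbours", {
  # 1-D makes the segment property exact: synthetic values must lie within
  # the minority range
  set.seed(91)
  x <- matrix(c(rnorm(50, 0, 1), 10, 11, 12), ncol = 1)
  y <- c(rep(0L, 50), 1L, 1L, 1L)
  out <- balance_classes(x, y)
  syn <- out$X[out$y == 1, 1]
  expect_true(all(syn >= 10 - 1e-9 & syn <= 12 + 1e-9))
})

test_that("the full preparation pipeline runs in order and is seed-deterministic", {
  spec <- synthetic_spec(n_samples = 120, n_features = 15, n_informative = 2,
                         n_redundant = 2, skewed_fraction = 0.3,
                         missing_max = 0.3, task = "regression")
  d <- generate_synthetic(spec, seed = 92)
  set.seed(93)
  prep1 <- prepare_partition(d$X, d$y, task = "regression")
  set.seed(93)
  prep2 <- prepare_partition(d$X, d$y, task = "regression")
  expect_identical(prep1, prep2)
  expect_false(anyNA(prep1$X))
  expect_true(all(prep1$X >= -10 & is.finite(prep1$X)))
  expect_equal(prep1$report$imputed_cells, sum(is.na(d$X)))
  # classification branch discretizes and balances
  dc <- generate_synthetic(
    synthetic_spec(n_samples = 150, n_features = 10, n_informative = 2,
                   skewed_fraction = 0, missing_max = 0.2,
                   task = "regression"), seed = 94)
  set.seed(95)
  prepc <- prepare_partition(dc$X, dc$y, task = "classification",
                             cutoff = stats::median(dc$y))
  expect_true(all(prepc$y %in% 0:1))
  expect_true(!is.null(prepc$report$resampling))
  expect_error(prepare_partition(dc$X, dc$y, task = "classification"),
               "cutoff")
})

test_that("preparation statistics fitted on one partition never use the other", {
  spec <- synthetic_spec(n_samples = 200, n_features = 8, n_informative = 2,
                         skewed_fraction = 0, missing_max = 0.2,
                         task = "regression")
  d <- generate_synthetic(spec, seed = 96)
  set.seed(97)
  idx <- split_data(nrow(d$X), 0.7)
  set.seed(98)
  tt <- prepare_partition(d$X[idx$train_test, ], d$y[idx$train_test],
                          task = "regression")
  # perturbing the validation rows must not change the train/test output
  Xv <- d$X
  Xv[idx$validation, ] <- Xv[idx$validation, ] * 100
  set.seed(98)
  tt2 <- prepare_partition(Xv[idx$train_test, ], d$y[idx$train_test],
                           task = "regression")
  expect_identical(tt, tt2)
})
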