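# Small fully connected network trained with Adam, used as the
# feedforward inner learner. ReLU hidden activations; softmax +
# cross-entropy head for classification, linear + squared-error head for
# regression. Full-batch updates keep the fit deterministic given the
# ambient RNG state (weight initialization and the validation split are
# the only random draws).

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    nin <- sizes[i]; nout <- sizes[i + 1L]
    list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
         b = rep(0, nout))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  A <- X
  for (i in seq_along(layers)) {
    Z <- sweep(A %*% layers[[i]]$W, 2, layers[[i]]$b, `+`)
    A <- if (i < length(layers)) pmax(Z, 0) else Z
    acts[[i + 1L]] <- A
  }
  acts
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_loss <- function(layers, X, Y, task) {
  out <- mlp_forward(layers, X)[[length(layers) + 1L]]
  if (task == "classification") {
    P <- pmin(pmax(softmax(out), 1e-12), 1)
    -mean(rowSums(Y * log(P)))
  } else {
    mean((out - Y)^2)
  }
}

mlp_gradients <- function(layers, X, Y, task) {
  L <- length(layers)
  acts <- mlp_forward(layers, X)
  n <- nrow(X)
  out <- acts[[L + 1L]]
  # delta at the output: both heads reduce to (prediction - target) / n
  delta <- if (task == "classification") (softmax(out) - Y) / n
           else 2 * (out - Y) / n
  grads <- vector("list", L)
  for (i in L:1) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
    }
  }
  grads
}

# task: "classification" (y = 0/1 labels) or "regression" (numeric y).
mlp_fit <- function(X, y, task, hidden = c(16L, 16L),
                    learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                    epochs = 200L, patience = 3L, val_fraction = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (task == "classification") {
    classes <- sort(unique(y))
    Y <- outer(y, classes, `==`) * 1
  } else {
    classes <- NULL
    Y <- matrix(y, ncol = 1L)
  }
  # early-stopping split: ~10% validation, stratified for classification,
  # always leaving at least one sample of each class in training
  val <- rep(FALSE, n)
  if (task == "classification") {
    for (cl in classes) {
      idx <- which(y == cl)
      nv <- min(max(1L, round(val_fraction * length(idx))), length(idx) - 1L)
      val[sample(idx, nv)] <- TRUE
    }
  } else {
    nv <- min(max(1L, round(val_fraction * n)), n - 2L)
    val[sample.int(n, nv)] <- TRUE
  }
  sizes <- c(ncol(X), hidden, ncol(Y))
  layers <- mlp_init(sizes)
  m <- v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  eps <- 1e-8
  best <- list(loss = Inf, layers = layers)
  wait <- 0L
  for (t in seq_len(epochs)) {
    g <- mlp_gradients(layers, X[!val, , drop = FALSE],
                       Y[!val, , drop = FALSE], task)
    for (i in seq_along(layers)) {
      for (nm in c("W", "b")) {
        m[[i]][[nm]] <- beta1 * m[[i]][[nm]] + (1 - beta1) * g[[i]][[nm]]
        v[[i]][[nm]] <- beta2 * v[[i]][[nm]] + (1 - beta2) * g[[i]][[nm]]^2
        mhat <- m[[i]][[nm]] / (1 - beta1^t)
        vhat <- v[[i]][[nm]] / (1 - beta2^t)
        layers[[i]][[nm]] <- layers[[i]][[nm]] -
          learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    vl <- mlp_loss(layers, X[val, , drop = FALSE], Y[val, , drop = FALSE], task)
    if (!is.finite(vl)) stop("network training diverged (non-finite loss)")
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, layers = layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(layers = best$layers, task = task, classes = classes,
                 epochs_run = t, val_loss = best$loss),
            class = "evotune_mlp")
}

mlp_predict <- function(object, X) {
  X <- as.matrix(X)
  out <- mlp_forward(object$layers, X)[[length(object$layers) + 1L]]
  if (object$task == "classification") {
    # probability of the positive (largest-labelled) class
    softmax(out)[, length(object$classes)]
  } else {
    drop(out)
  }
}
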