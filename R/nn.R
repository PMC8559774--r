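#' Dense feedforward regressor trained with Adam
#'
#' Minimal multilayer perceptron for the weight-regression task:
#' fully-connected layers with rectified-linear activations between them
#' and a linear scalar output, squared-error loss, Adam updates on
#' shuffled mini-batches, and early stopping on a validation slice.
#' Inputs are standardized and the target linearly scaled internally;
#' predictions are returned on the original scale.
#'
#' @name nn
#' @keywords internal
NULL

nn_init_params <- function(sizes) {
  L <- length(sizes) - 1
  params <- vector("list", L)
  for (l in seq_len(L)) {
    params[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                              sd = sqrt(2 / sizes[l])),
                 sizes[l], sizes[l + 1]),
      b = numeric(sizes[l + 1])
    )
  }
  params
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

nn_forward_raw <- function(params, X) {
  A <- X
  L <- length(params)
  for (l in seq_len(L)) {
    A <- add_bias(A %*% params[[l]]$W, params[[l]]$b)
    if (l < L) A[A < 0] <- 0
  }
  A[, 1]
}

# forward keeping activations, then backprop of mean squared error;
# returns list(grads, loss)
nn_grad <- function(params, X, y) {
  L <- length(params)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- add_bias(acts[[l]] %*% params[[l]]$W, params[[l]]$b)
    if (l < L) Z[Z < 0] <- 0
    acts[[l + 1]] <- Z
  }
  n <- nrow(X)
  err <- acts[[L + 1]][, 1] - y
  delta <- matrix(2 * err / n, n, 1)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(params[[l]]$W)
      delta[acts[[l]] <= 0] <- 0
    }
  }
  list(grads = grads, loss = mean(err^2))
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0
  ))
}

adam_step <- function(params, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(params)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[l]]$W <- params[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

#' Train the dense regressor
#'
#' @param X Numeric matrix of inputs (rows = examples).
#' @param y Numeric target vector.
#' @param hidden Hidden-layer widths.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam step size.
#' @param val_frac Fraction of rows held out for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Seed for initialization and shuffling.
#' @return An `nn_model` list (parameters, scalers, loss curve, metadata).
#' @keywords internal
nn_train <- function(X, y, hidden = c(100, 50, 25), epochs = 500,
                     batch_size = 32, lr = 1e-3, val_frac = 0.1,
                     patience = 30, seed = 1L) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[!is.finite(x_scale) | x_scale < 1e-8] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-8) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  sizes <- c(ncol(X), hidden, 1)
  run <- function() {
    params <- nn_init_params(sizes)
    n <- nrow(Xs)
    perm <- sample.int(n)
    n_val <- if (n >= 20 && val_frac > 0) max(1L, floor(val_frac * n)) else 0L
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
    Xval <- Xs[val_idx, , drop = FALSE]; yval <- ys[val_idx]
    state <- adam_init(params)
    t <- 0
    best <- params
    best_val <- Inf
    wait <- 0
    curve <- numeric(0)
    ntr <- length(ytr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ntr)
      for (start in seq(1, ntr, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, ntr)]
        g <- nn_grad(params, Xtr[rows, , drop = FALSE], ytr[rows])
        t <- t + 1
        upd <- adam_step(params, g$grads, state, t, lr = lr)
        params <- upd$params
        state <- upd$state
      }
      monitor <- if (n_val > 0) {
        mean((nn_forward_raw(params, Xval) - yval)^2)
      } else {
        mean((nn_forward_raw(params, Xtr) - ytr)^2)
      }
      curve <- c(curve, monitor)
      if (monitor < best_val - 1e-9) {
        best_val <- monitor
        best <- params
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait > patience) break
      }
    }
    list(params = best, curve = curve, best_val = best_val,
         epochs_run = length(curve))
  }
  fit <- with_local_seed(seed, run())
  structure(list(params = fit$params, sizes = sizes,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 loss_curve = fit$curve, val_loss = fit$best_val,
                 epochs_run = fit$epochs_run, seed = seed),
            class = "nn_model")
}

#' Predict with a trained dense regressor
#' @param model An `nn_model`.
#' @param X Input matrix (or vector for a single example).
#' @return Numeric predictions on the original target scale (unclamped).
#' @keywords internal
nn_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  nn_forward_raw(model$params, Xs) * model$y_scale + model$y_center
}
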