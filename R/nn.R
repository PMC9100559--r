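# Fully connected network: plain matrix-algebra implementation with inverted
# dropout, Adam, and early stopping on validation loss. Kept internal; the
# exported surface is mlp_spec() / train_network() / predict_network() /
# cross_validate() / mc_predict().

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  z <- z - apply(z, 1, max) # numerical stability
  e <- exp(z)
  e / rowSums(e)
}

nn_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(
      W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
        fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  })
}

# Forward pass. With training = TRUE, fresh dropout masks are drawn from the
# current RNG stream and activations are scaled by 1/(1-p) (inverted
# dropout), so evaluation needs no rescaling. Returns the cache needed for
# backprop.
nn_forward <- function(params, X, dropout_rate = 0, training = FALSE) {
  L <- length(params)
  A <- X
  cache <- list(A = vector("list", L + 1), Z = vector("list", L),
    mask = vector("list", L))
  cache$A[[1]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% params[[l]]$W
    Z <- sweep(Z, 2, params[[l]]$b, "+")
    cache$Z[[l]] <- Z
    if (l < L) {
      A <- relu(Z)
      if (training && dropout_rate > 0) {
        mask <- matrix(runif(length(A)) >= dropout_rate, nrow(A), ncol(A))
        A <- A * mask / (1 - dropout_rate)
        cache$mask[[l]] <- mask
      }
    } else {
      A <- Z # output layer is linear; softmax applied in the loss/predict
    }
    cache$A[[l + 1]] <- A
  }
  cache
}

# Mean loss: cross-entropy over softmax (classifier, y is 0-based class) or
# mean squared error (regression, y numeric).
nn_loss <- function(out, y, mode) {
  if (mode == "classifier") {
    p <- softmax(out)
    -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
  } else {
    mean((out[, 1] - y)^2)
  }
}

# Gradient of the mean loss w.r.t. all parameters, given a forward cache.
nn_backward <- function(params, cache, y, mode, dropout_rate) {
  L <- length(params)
  n <- nrow(cache$A[[1]])
  out <- cache$A[[L + 1]]
  if (mode == "classifier") {
    P <- softmax(out)
    Y <- matrix(0, n, ncol(out))
    Y[cbind(seq_len(n), y + 1L)] <- 1
    dZ <- (P - Y) / n
  } else {
    dZ <- matrix(2 * (out[, 1] - y) / n, n, 1)
  }
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(
      W = crossprod(cache$A[[l]], dZ),
      b = colSums(dZ)
    )
    if (l > 1) {
      dA <- dZ %*% t(params[[l]]$W)
      if (dropout_rate > 0 && !is.null(cache$mask[[l - 1]])) {
        dA <- dA * cache$mask[[l - 1]] / (1 - dropout_rate)
      }
      dZ <- dA * (cache$Z[[l - 1]] > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0
  ))
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW_hat <- s$mW / (1 - beta1^t)
    vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t)
    vb_hat <- s$vb / (1 - beta2^t)
    params[[l]]$W <- params[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

#' Network specification
#'
#' Architecture and training hyperparameters of the fully connected network:
#' three hidden layers of 100, 60 and 20 rectified-linear units with dropout
#' rate 0.1 by default, trained with Adam and early stopping on validation
#' loss. `mode = "classifier"` uses a softmax output and cross-entropy;
#' `mode = "regression"` uses a single linear output trained against the
#' ordinal class indices with squared error.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param dropout_rate Dropout probability on hidden activations, in `[0, 1)`.
#' @param mode `"classifier"` or `"regression"`.
#' @param learning_rate,batch_size,max_epochs,patience Optimizer settings.
#' @param seed Integer seed controlling initialization, batching and dropout.
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden = c(100, 60, 20), dropout_rate = 0.1,
                     mode = c("classifier", "regression"),
                     learning_rate = 1e-2, batch_size = 256,
                     max_epochs = 1000, patience = 50, seed = 1L) {
  mode <- match.arg(mode)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (any(hidden <= 0)) stop("hidden layer sizes must be positive")
  structure(
    list(
      hidden = hidden, dropout_rate = dropout_rate, mode = mode,
      learning_rate = learning_rate, batch_size = batch_size,
      max_epochs = max_epochs, patience = patience, seed = as.integer(seed)
    ),
    class = "mlp_spec"
  )
}

#' Train a network
#'
#' Minimizes the mode's loss with Adam on minibatches; after every epoch the
#' validation loss is evaluated deterministically (dropout off) and training
#' stops once it has failed to improve for `patience` epochs. The parameters
#' from the best-validation-loss epoch are returned.
#'
#' @param x Normalized training feature matrix.
#' @param y Integer targets, 0-based (classifier) or ordinal values
#'   (regression).
#' @param x_val,y_val Validation set (required; drives early stopping).
#' @param spec An [mlp_spec()].
#' @param n_classes Number of classes (ignored for regression output size but
#'   kept for class decoding).
#' @return A list of class `trained_model`: `params`, `spec`, `n_classes`,
#'   `n_in`, `best_epoch`, `history` (per-epoch train/validation loss).
#' @export
train_network <- function(x, y, x_val, y_val, spec, n_classes) {
  stopifnot(inherits(spec, "mlp_spec"))
  x <- as.matrix(x)
  x_val <- as.matrix(x_val)
  if (!nrow(x_val)) stop("empty validation set")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  n_out <- if (spec$mode == "classifier") n_classes else 1L
  set.seed(spec$seed)
  params <- nn_init(ncol(x), spec$hidden, n_out)
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
    val_loss = numeric(0))
  t_step <- 0L
  wait <- 0L
  n <- nrow(x)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = spec$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + spec$batch_size - 1, n)]
      cache <- nn_forward(params, x[idx, , drop = FALSE],
        spec$dropout_rate, training = TRUE)
      out <- cache$A[[length(params) + 1]]
      loss <- nn_loss(out, y[idx], spec$mode)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d (lr=%g)",
          epoch, spec$learning_rate))
      }
      ep_loss <- ep_loss + loss * length(idx)
      grads <- nn_backward(params, cache, y[idx], spec$mode, spec$dropout_rate)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, t_step, spec$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    val_cache <- nn_forward(params, x_val, 0, training = FALSE)
    val_loss <- nn_loss(val_cache$A[[length(params) + 1]], y_val, spec$mode)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n, val_loss = val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(
    list(
      params = best$params, spec = spec, n_classes = n_classes,
      n_in = ncol(x), best_epoch = best$epoch, history = history
    ),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s, %d inputs -> (%s) -> %d classes; best epoch %d (val loss %.4f)\n",
    x$spec$mode, x$n_in, paste(x$spec$hidden, collapse = ", "), x$n_classes,
    x$best_epoch, min(x$history$val_loss)
  ))
  invisible(x)
}

#' Deterministic prediction
#'
#' Single forward pass with dropout disabled.
#'
#' @param model A `trained_model`.
#' @param x Feature matrix normalized with the training parameters.
#' @return Classifier: matrix of class probabilities (rows sum to 1).
#'   Regression: numeric score vector.
#' @export
predict_network <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_in) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
      model$n_in, ncol(x)))
  }
  cache <- nn_forward(model$params, x, 0, training = FALSE)
  out <- cache$A[[length(model$params) + 1]]
  if (model$spec$mode == "classifier") softmax(out) else out[, 1]
}

# Round half up, clip into [0, K-1]: the regression score -> class rule.
score_to_class <- function(score, n_classes) {
  pmin(pmax(floor(score + 0.5), 0), n_classes - 1)
}

#' Predicted class indices
#'
#' Classifier: argmax of the probability vector, ties broken toward the
#' less-threatened class (lowest index). Regression: score rounded half up
#' and clipped to the class range.
#'
#' @param model A `trained_model`.
#' @param x Normalized feature matrix.
#' @return Integer vector of 0-based class indices.
#' @export
predict_class <- function(model, x) {
  out <- predict_network(model, x)
  if (model$spec$mode == "classifier") {
    max.col(out, ties.method = "first") - 1L
  } else {
    as.integer(score_to_class(out, model$n_classes))
  }
}
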