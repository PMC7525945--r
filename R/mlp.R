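# The feed-forward classifier: fully-connected layers with ReLU activations
# and dropout, a two-unit output normalized to a probability pair, binary
# cross-entropy loss, minibatch training with adadelta (default) and early
# stopping on validation loss with best-weight restoration. Written directly
# on BLAS-backed matrix operations.

#' Classifier configuration
#'
#' The defaults reproduce the selected architecture: six hidden layers of
#' widths 128, 256, 512, 1024, 1024, 1024, dropout rate 0.3, at most 100
#' epochs with early stopping, and the adadelta optimizer (which needs no
#' learning rate).
#'
#' @param input_dim Width of the input layer (89 for the full feature set).
#' @param hidden_dims Integer vector of hidden-layer widths.
#' @param dropout_rate Fraction of hidden units dropped during training, in
#'   \[0, 1).
#' @param max_epochs Maximum number of training epochs.
#' @param patience Early stopping: stop once validation loss has failed to
#'   improve for this many consecutive epochs (best weights are restored).
#' @param batch_size Minibatch size.
#' @param optimizer One of "adadelta", "sgd", "adam", "rmsprop".
#' @param learning_rate Step size for sgd/adam/rmsprop; ignored by adadelta.
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling and dropout masks.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(input_dim = 89L,
                       hidden_dims = c(128L, 256L, 512L, 1024L, 1024L, 1024L),
                       dropout_rate = 0.3,
                       max_epochs = 100L,
                       patience = 10L,
                       batch_size = 256L,
                       optimizer = c("adadelta", "sgd", "adam", "rmsprop"),
                       learning_rate = 0.01,
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (length(hidden_dims) == 0 || any(hidden_dims < 1)) {
    stop_config("hidden_dims must be a non-empty vector of positive widths")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate must be in [0, 1)")
  }
  if (input_dim < 1 || max_epochs < 1 || batch_size < 1 || patience < 0) {
    stop_config("input_dim, max_epochs and batch_size must be positive; patience non-negative")
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropout_rate = dropout_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer,
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Build an (untrained) network from a configuration
#'
#' Weights use seeded He-normal initialization (sd = sqrt(2 / fan_in), suited
#' to ReLU units); biases start at zero. The output layer has two units whose
#' activations are normalized to a probability pair summing to one.
#'
#' @param config An `mlp_config`.
#' @return An `mlp_model` with untrained parameters.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "mlp_config"))
  dims <- c(config$input_dim, config$hidden_dims, 2L)
  with_local_seed(config$seed, {
    W <- vector("list", length(dims) - 1)
    b <- vector("list", length(dims) - 1)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                    sd = sqrt(2 / dims[l])),
                       nrow = dims[l], ncol = dims[l + 1])
      b[[l]] <- numeric(dims[l + 1])
    }
    structure(list(config = config, W = W, b = b, history = NULL,
                   stopped_epoch = NA_integer_, trained = FALSE),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d -> %s -> 2 (%s)%s\n",
              x$config$input_dim,
              paste(x$config$hidden_dims, collapse = " -> "),
              x$config$optimizer,
              if (x$trained) sprintf(", trained (stopped at epoch %d)",
                                     x$stopped_epoch) else ", untrained"))
  invisible(x)
}

# Forward pass. Returns the probability matrix (n x 2, columns
# non-essential/essential) and, if keep_cache, the layer activations needed
# for backpropagation. Dropout (inverted scaling) is applied to hidden
# activations only when dropout = TRUE, i.e. during training.
mlp_forward <- function(model, x, dropout = FALSE, keep_cache = FALSE) {
  n_layers <- length(model$W)
  p <- model$config$dropout_rate
  a <- x
  cache <- if (keep_cache) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers - 1)) {
    z <- a %*% model$W[[l]]
    z <- sweep(z, 2, model$b[[l]], "+")
    h <- pmax(z, 0)
    mask <- NULL
    if (dropout && p > 0) {
      mask <- matrix(stats::rbinom(length(h), 1, 1 - p) / (1 - p),
                     nrow = nrow(h))
      h <- h * mask
    }
    if (keep_cache) cache[[l]] <- list(input = a, pre = z, mask = mask)
    a <- h
  }
  z <- a %*% model$W[[n_layers]]
  z <- sweep(z, 2, model$b[[n_layers]], "+")
  if (keep_cache) cache[[n_layers]] <- list(input = a)
  # normalized-exponential two-unit output: the probability pair sums to 1
  z <- z - apply(z, 1, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  list(probs = probs, cache = cache)
}

# Mean binary cross-entropy of probability pairs against 0/1 labels.
cross_entropy <- function(probs, y) {
  eps <- 1e-12
  -mean(y * log(probs[, 2] + eps) + (1 - y) * log(probs[, 1] + eps))
}

make_optimizer <- function(config, W, b) {
  zeros <- function(tpl) lapply(tpl, function(m) array(0, dim = dim(m) %||% length(m)))
  state <- list(gW2 = zeros(W), gb2 = zeros(b),
                dW2 = zeros(W), db2 = zeros(b),
                mW = zeros(W), mb = zeros(b), t = 0)
  rho <- 0.95; eps <- 1e-6
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  lr <- config$learning_rate
  switch(config$optimizer,
    sgd = function(state, gW, gb) {
      list(state = state,
           dW = lapply(gW, function(g) -lr * g),
           db = lapply(gb, function(g) -lr * g))
    },
    adadelta = function(state, gW, gb) {
      dW <- vector("list", length(gW)); db <- vector("list", length(gb))
      for (l in seq_along(gW)) {
        state$gW2[[l]] <- rho * state$gW2[[l]] + (1 - rho) * gW[[l]]^2
        state$gb2[[l]] <- rho * state$gb2[[l]] + (1 - rho) * gb[[l]]^2
        dW[[l]] <- -sqrt(state$dW2[[l]] + eps) / sqrt(state$gW2[[l]] + eps) * gW[[l]]
        db[[l]] <- -sqrt(state$db2[[l]] + eps) / sqrt(state$gb2[[l]] + eps) * gb[[l]]
        state$dW2[[l]] <- rho * state$dW2[[l]] + (1 - rho) * dW[[l]]^2
        state$db2[[l]] <- rho * state$db2[[l]] + (1 - rho) * db[[l]]^2
      }
      list(state = state, dW = dW, db = db)
    },
    rmsprop = function(state, gW, gb) {
      dW <- vector("list", length(gW)); db <- vector("list", length(gb))
      for (l in seq_along(gW)) {
        state$gW2[[l]] <- rho * state$gW2[[l]] + (1 - rho) * gW[[l]]^2
        state$gb2[[l]] <- rho * state$gb2[[l]] + (1 - rho) * gb[[l]]^2
        dW[[l]] <- -lr * gW[[l]] / sqrt(state$gW2[[l]] + eps)
        db[[l]] <- -lr * gb[[l]] / sqrt(state$gb2[[l]] + eps)
      }
      list(state = state, dW = dW, db = db)
    },
    adam = function(state, gW, gb) {
      state$t <- state$t + 1
      corr1 <- 1 - beta1^state$t; corr2 <- 1 - beta2^state$t
      dW <- vector("list", length(gW)); db <- vector("list", length(gb))
      for (l in seq_along(gW)) {
        state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gW[[l]]
        state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb[[l]]
        state$gW2[[l]] <- beta2 * state$gW2[[l]] + (1 - beta2) * gW[[l]]^2
        state$gb2[[l]] <- beta2 * state$gb2[[l]] + (1 - beta2) * gb[[l]]^2
        dW[[l]] <- -lr * (state$mW[[l]] / corr1) /
          (sqrt(state$gW2[[l]] / corr2) + aeps)
        db[[l]] <- -lr * (state$mb[[l]] / corr1) /
          (sqrt(state$gb2[[l]] / corr2) + aeps)
      }
      list(state = state, dW = dW, db = db)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the classifier
#'
#' Minimizes mean binary cross-entropy by seeded minibatch gradient descent
#' with the configured optimizer. Training stops at `max_epochs`, or earlier
#' once validation loss has failed to improve for `patience` consecutive
#' epochs; parameters are then restored to the best-validation epoch. The
#' per-epoch train/validation losses are recorded in `history`.
#'
#' @param model An `mlp_model` from [build_model()].
#' @param x_train,y_train Standardized training features (matrix) and 0/1
#'   labels (1 = essential).
#' @param x_val,y_val Validation features and labels, disjoint from training.
#' @return The trained `mlp_model`.
#' @export
train_mlp <- function(model, x_train, y_train, x_val, y_val) {
  stopifnot(inherits(model, "mlp_model"))
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (nrow(x_train) == 0 || nrow(x_val) == 0) {
    stop_invalid_input("training and validation partitions must be non-empty")
  }
  if (ncol(x_train) != model$config$input_dim) {
    stop_config("feature dimension %d does not match model input width %d",
                ncol(x_train), model$config$input_dim)
  }
  if (!all(y_train %in% c(0, 1)) || !all(y_val %in% c(0, 1))) {
    stop_invalid_input("labels must be 0/1 (1 = essential)")
  }
  cfg <- model$config
  y1h <- cbind(1 - y_train, y_train)
  step <- make_optimizer(cfg, model$W, model$b)
  opt_state <- environment(step)$state
  n <- nrow(x_train)
  best <- list(loss = Inf, W = model$W, b = model$b, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stall <- 0L
  with_local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        xb <- x_train[idx, , drop = FALSE]
        yb <- y1h[idx, , drop = FALSE]
        fw <- mlp_forward(model, xb, dropout = TRUE, keep_cache = TRUE)
        loss <- cross_entropy(fw$probs, yb[, 2])
        if (!is.finite(loss)) {
          stop_training("non-finite training loss at epoch %d", epoch)
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        grads <- mlp_backward(model, fw, yb)
        upd <- step(opt_state, grads$gW, grads$gb)
        opt_state <- upd$state
        for (l in seq_along(model$W)) {
          model$W[[l]] <- model$W[[l]] + upd$dW[[l]]
          model$b[[l]] <- model$b[[l]] + upd$db[[l]]
        }
      }
      val_loss <- cross_entropy(mlp_forward(model, x_val)$probs, y_val)
      if (!is.finite(val_loss)) {
        stop_training("non-finite validation loss at epoch %d", epoch)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epoch_loss / n,
                                  val_loss = val_loss))
      if (val_loss < best$loss - 1e-8) {
        best <- list(loss = val_loss, W = model$W, b = model$b,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > cfg$patience) break
      }
    }
  })
  model$W <- best$W
  model$b <- best$b
  model$history <- history
  model$stopped_epoch <- nrow(history)
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

# Backpropagation through the affine/ReLU/dropout stack for the softmax +
# cross-entropy head (whose combined gradient is probs - targets).
mlp_backward <- function(model, fw, y1h) {
  n_layers <- length(model$W)
  m <- nrow(y1h)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- (fw$probs - y1h) / m
  for (l in rev(seq_len(n_layers))) {
    input <- fw$cache[[l]]$input
    gW[[l]] <- crossprod(input, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(model$W[[l]])
      if (!is.null(fw$cache[[l - 1]]$mask)) {
        delta <- delta * fw$cache[[l - 1]]$mask
      }
      delta <- delta * (fw$cache[[l - 1]]$pre > 0)
    }
  }
  list(gW = gW, gb = gb)
}

#' Predict the probability of essentiality
#'
#' Inference is deterministic (dropout disabled) and batch-order invariant.
#'
#' @param model An `mlp_model`.
#' @param x Feature matrix standardized with the train-fitted standardizer.
#' @param both If TRUE return the n x 2 probability matrix (non-essential,
#'   essential); otherwise the essential-class probability vector.
#' @return Numeric vector in \[0, 1\] (or matrix if `both`).
#' @export
predict_proba <- function(model, x, both = FALSE) {
  stopifnot(inherits(model, "mlp_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$config$input_dim) {
    stop_invalid_input("feature dimension %d does not match model input width %d",
                       ncol(x), model$config$input_dim)
  }
  probs <- mlp_forward(model, x)$probs
  colnames(probs) <- c("nonessential", "essential")
  if (both) probs else unname(probs[, "essential"])
}
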