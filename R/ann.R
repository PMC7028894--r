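#' Three-layer perceptron configuration
#'
#' The reference classifier is a feed-forward network with one hidden layer
#' (input, hidden, output) of sigmoid units and a single sigmoid output per
#' binary problem, trained by full-batch gradient descent on binary
#' cross-entropy.
#'
#' @param hidden_units hidden-layer width.
#' @param learning_rate gradient-descent step size.
#' @param epochs number of full-batch epochs.
#' @param seed RNG seed for the weight initialization.
#' @return an \code{ann_config} list.
#' @export
ann_config <- function(hidden_units = 20L, learning_rate = 0.05,
                       epochs = 500L, seed = 17L) {
  if (hidden_units < 1L || epochs < 1L || learning_rate <= 0)
    stop("ann_config: hidden_units and epochs must be positive, ",
         "learning_rate > 0")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 activation = "sigmoid", seed = as.integer(seed)),
            class = "ann_config")
}

#' Train a binary three-layer perceptron
#'
#' Weights (including biases) are initialized uniformly in [-0.5, 0.5] from
#' the configured seed, then updated by full-batch gradient descent on the
#' (optionally sample-weighted) mean binary cross-entropy. The per-epoch
#' training loss is recorded in the returned object.
#'
#' @param X numeric feature matrix (rows = samples), already scaled.
#' @param y binary labels in \code{{0, 1}}.
#' @param config an \code{\link{ann_config}}.
#' @param sample_weights optional non-negative weights, normalized to mean 1.
#' @return an \code{ann_binary} model with elements \code{W1}, \code{b1},
#'   \code{W2}, \code{b2}, \code{loss} (per-epoch vector) and \code{config}.
#' @export
train_ann_binary <- function(X, y, config = ann_config(),
                             sample_weights = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("train_ann_binary: X must be finite")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("train_ann_binary: y must be binary 0/1")
  n <- nrow(X); d <- ncol(X); h <- config$hidden_units
  w <- if (is.null(sample_weights)) rep(1, n)
       else sample_weights / mean(sample_weights)

  set.seed(config$seed)
  W1 <- matrix(runif(d * h, -0.5, 0.5), d, h)
  b1 <- runif(h, -0.5, 0.5)
  W2 <- matrix(runif(h, -0.5, 0.5), h, 1)
  b2 <- runif(1, -0.5, 0.5)

  lr <- config$learning_rate
  eps <- 1e-12
  loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    Z <- .sigmoid(sweep(X %*% W1, 2, b1, `+`))     # n x h
    p <- as.vector(.sigmoid(Z %*% W2 + b2))        # n
    loss[ep] <- -mean(w * (y * log(pmax(p, eps)) +
                           (1 - y) * log(pmax(1 - p, eps))))
    if (!is.finite(loss[ep]))
      stop("ANN training diverged (non-finite loss); ",
           "try a smaller learning rate")
    # gradients of weighted mean BCE; d(loss)/d(logit) = w*(p - y)/n
    delta_out <- w * (p - y) / n                   # n
    gW2 <- crossprod(Z, delta_out)                 # h x 1
    gb2 <- sum(delta_out)
    delta_h <- (delta_out %*% t(W2)) * Z * (1 - Z) # n x h
    gW1 <- crossprod(X, delta_h)                   # d x h
    gb1 <- colSums(delta_h)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, loss = loss,
                 config = config),
            class = "ann_binary")
}

#' Predict class-1 probabilities from a binary perceptron
#'
#' @param object an \code{ann_binary} model.
#' @param newdata feature matrix on the training scale.
#' @param ... unused.
#' @return numeric vector of probabilities in \code{[0, 1]}.
#' @export
predict.ann_binary <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Z <- .sigmoid(sweep(X %*% object$W1, 2, object$b1, `+`))
  as.vector(.sigmoid(Z %*% object$W2 + object$b2))
}
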