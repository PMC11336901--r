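## Minimal multilayer-perceptron autoencoder: tanh hidden layers, linear
## output, mean-squared-error loss, minibatch stochastic gradient
## descent. Deliberately small and dependency-free: the role of the
## autoencoder here is unsupervised feature ranking, not representation
## learning at scale.

ae_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(i) {
      fan_in <- sizes[i]
      list(W = matrix(stats::rnorm(fan_in * sizes[i + 1],
                                   sd = sqrt(1 / fan_in)),
                      fan_in, sizes[i + 1]),
           b = rep(0, sizes[i + 1]))
    })
  })
}

ae_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  n_lay <- length(layers)
  for (i in seq_len(n_lay)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, `+`)
    acts[[i + 1]] <- if (i < n_lay) tanh(z) else z  # linear output layer
  }
  acts
}

#' Fit a tanh autoencoder by stochastic gradient descent
#'
#' Trains an autoencoder with tanh hidden layers (default sizes
#' 100, 300, 100) and a linear reconstruction layer on the rows of `x`
#' for a fixed number of epochs of minibatch SGD under mean-squared
#' reconstruction error. Training is deterministic given `seed`.
#'
#' @param x numeric matrix, samples in rows, features (genes) in
#'   columns; expected to be standardized per feature.
#' @param hidden integer vector of hidden-layer sizes.
#' @param epochs passes over the data (default 10).
#' @param lr SGD learning rate.
#' @param batch_size minibatch size (capped at n samples).
#' @param seed integer seed for weight initialization and batch order.
#' @return list of class `autoencoder`: `layers` (weights), `sizes`,
#'   `loss` (per-epoch mean reconstruction MSE).
#' @export
autoencoder_fit <- function(x, hidden = c(100, 300, 100), epochs = 10,
                            lr = 0.01, batch_size = 32, seed = 1L) {
  check_that(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  n <- nrow(x); p <- ncol(x)
  check_that(n >= 2 && p >= 2, "need >= 2 samples and >= 2 features")
  sizes <- c(p, hidden, p)
  layers <- ae_init(sizes, seed)
  batch_size <- min(batch_size, n)
  loss <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (b in batches) {
        xb <- x[b, , drop = FALSE]
        acts <- ae_forward(layers, xb)
        nb <- length(b)
        err <- acts[[length(acts)]] - xb
        ep_loss <- ep_loss + sum(err^2)
        delta <- 2 * err / (nb * p)       # d(mse)/d(output)
        for (i in rev(seq_along(layers))) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1) {
            delta <- (delta %*% t(layers[[i]]$W)) * (1 - acts[[i]]^2)
          }
          layers[[i]]$W <- layers[[i]]$W - lr * gW
          layers[[i]]$b <- layers[[i]]$b - lr * gb
        }
      }
      loss[ep] <- ep_loss / (n * p)
    }
  })
  structure(list(layers = layers, sizes = sizes, loss = loss),
            class = "autoencoder")
}

#' @export
predict.autoencoder <- function(object, newdata, ...) {
  acts <- ae_forward(object$layers, newdata)
  acts[[length(acts)]]
}

#' Garson-style input importance of a fitted autoencoder
#'
#' Aggregates absolute connection weights along every input-to-output
#' path: the product of the absolute weight matrices gives, for each
#' input feature, the total absolute path magnitude through the network;
#' features whose reconstruction the network invests most weight in rank
#' highest. Importances are normalized to sum to 1.
#'
#' @param model an [autoencoder_fit()] result.
#' @return numeric vector of per-input-feature importances.
#' @export
ae_importance <- function(model) {
  stopifnot(inherits(model, "autoencoder"))
  path <- abs(model$layers[[1]]$W)
  for (i in seq_along(model$layers)[-1]) {
    path <- path %*% abs(model$layers[[i]]$W)
  }
  imp <- rowSums(path)
  imp / sum(imp)
}

#' Reconstruction-error input importance (alternative ranking)
#'
#' Scores each feature by how much better the autoencoder reconstructs
#' it than a mean predictor: 1 - MSE_feature / variance_feature. Exposed
#' as the alternative to the weight-path (Garson) ranking.
#'
#' @param model an [autoencoder_fit()] result.
#' @param x the (standardized) training matrix, samples in rows.
#' @return numeric vector of per-feature importances.
#' @export
ae_reconstruction_importance <- function(model, x) {
  rec <- predict(model, x)
  mse <- colMeans((rec - x)^2)
  v <- apply(x, 2, stats::var)
  ifelse(v > 0, 1 - mse / v, 0)
}
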