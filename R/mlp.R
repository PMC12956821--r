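# Small dense feedforward network for binary classification: tanh hidden
# layers, logistic output, cross-entropy loss, full-batch Adam. Sized for
# the architectures swept here (depth <= 4, width <= 5, 4 input features),
# where full-batch training is cheap and deterministic under a seed.

mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1)
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = 1 / sqrt(fan_in)),
        nrow = fan_in
      ),
      b = rep(0, sizes[l + 1])
    )
  })
}

mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < nl) tanh(z) else stats::plogis(z)
  }
  acts
}

#' Fit a small multilayer perceptron
#'
#' Trains a feedforward binary classifier with the given hidden-layer
#' widths by full-batch Adam on the cross-entropy loss. Training is
#' declared converged when the loss has changed by less than `tol` over the
#' last `patience` epochs; runs that exhaust `max_epochs` without a
#' plateau, or whose loss becomes non-finite, are flagged as not converged.
#'
#' @param x numeric matrix of (standardized) features.
#' @param y 0/1 response vector.
#' @param hidden integer vector of hidden-layer widths (depth = its length).
#' @param max_epochs,learning_rate,tol,patience training controls.
#' @param seed integer seed for weight initialization.
#' @return list with `layers`, `converged`, `epochs`, `loss`, `hidden`.
#' @export
mlp_fit <- function(x, y, hidden, max_epochs = 2000, learning_rate = 0.02,
                    tol = 1e-4, patience = 50, seed = 1) {
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  stopifnot(length(hidden) >= 1, all(hidden >= 1))
  layers <- with_seed(seed, mlp_init(ncol(x), hidden))
  nl <- length(layers)
  mom <- lapply(layers, function(l) {
    list(
      mW = 0 * l$W, vW = 0 * l$W,
      mb = 0 * l$b, vb = 0 * l$b
    )
  })
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  n <- nrow(x)
  loss_hist <- rep(NA_real_, max_epochs)
  converged <- FALSE
  epoch <- 0
  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(layers, x)
    p <- pmin(pmax(acts[[nl + 1]][, 1], 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    if (!is.finite(loss)) {
      return(list(
        layers = layers, converged = FALSE, epochs = epoch,
        loss = loss, hidden = hidden
      ))
    }
    loss_hist[epoch] <- loss
    if (epoch > patience &&
      abs(loss_hist[epoch - patience] - loss) < tol) {
      converged <- TRUE
      break
    }
    # backprop: delta at output is (p - y)/n for cross-entropy + logistic
    delta <- matrix((p - y) / n, ncol = 1)
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
      }
      mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * gW
      mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * gW^2
      mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * gb
      mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * gb^2
      corr1 <- 1 - b1^epoch
      corr2 <- 1 - b2^epoch
      layers[[l]]$W <- layers[[l]]$W -
        learning_rate * (mom[[l]]$mW / corr1) /
          (sqrt(mom[[l]]$vW / corr2) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        learning_rate * (mom[[l]]$mb / corr1) /
          (sqrt(mom[[l]]$vb / corr2) + eps)
    }
  }
  list(
    layers = layers, converged = converged, epochs = epoch,
    loss = loss_hist[epoch], hidden = hidden
  )
}

#' Predict class probabilities from a fitted MLP
#'
#' @param fit result of [mlp_fit()].
#' @param x feature matrix on the same scale as training.
#' @return vector of probabilities of class 1.
#' @export
mlp_predict <- function(fit, x) {
  acts <- mlp_forward(fit$layers, as.matrix(x))
  acts[[length(acts)]][, 1]
}
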