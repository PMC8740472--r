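# Small multilayer perceptron: rectified-linear hidden layers, logistic
# output, Adam optimiser, full-batch gradients. Written for the five-feature
# regulation-state classifier (two hidden layers of 5 and 3 units by
# default); inputs are standardised internally.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(d, hidden) {
  sizes <- c(d, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fan_in <- sizes[i]
    list(W = matrix(rnorm(fan_in * sizes[i + 1L], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[i + 1L]),
         b = rep(0, sizes[i + 1L]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  n <- length(layers)
  for (i in seq_len(n)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < n) relu(z) else sigmoid(z)
  }
  acts
}

# y in {0, 1}; returns fitted layers plus the input standardisation
mlp_fit <- function(X, y, hidden = c(5L, 3L), epochs = 400L, lr = 0.01,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  layers <- mlp_init(ncol(Xs), hidden)
  mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  n <- nrow(Xs)
  for (t in seq_len(epochs)) {
    acts <- mlp_forward(layers, Xs)
    p <- acts[[length(acts)]]
    delta <- (p - y) / n  # d(BCE)/d(z) at the logistic output
    for (i in rev(seq_along(layers))) {
      gW <- crossprod(acts[[i]], delta)
      gb <- colSums(delta)
      if (i > 1L) {
        delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
      }
      m <- mom[[i]]
      m$mW <- beta1 * m$mW + (1 - beta1) * gW
      m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
      m$mb <- beta1 * m$mb + (1 - beta1) * gb
      m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
      mom[[i]] <- m
      c1 <- 1 - beta1^t
      c2 <- 1 - beta2^t
      layers[[i]]$W <- layers[[i]]$W - lr * (m$mW / c1) / (sqrt(m$vW / c2) + eps)
      layers[[i]]$b <- layers[[i]]$b - lr * (m$mb / c1) / (sqrt(m$vb / c2) + eps)
    }
  }
  structure(list(layers = layers, center = center, scale = scale,
                 hidden = hidden), class = "ctap_mlp")
}

# probability of the positive class
mlp_prob <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2L, fit$center), 2L, fit$scale, "/")
  as.vector(mlp_forward(fit$layers, Xs)[[length(fit$layers) + 1L]])
}
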