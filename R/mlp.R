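# Small fully connected network: dense layers of widths 16/32/16/1 with
# rectified-linear hidden activations and a sigmoid output, trained on the
# hinge loss with labels encoded +/-1 (the sigmoid output s is mapped to the
# margin scale as 2s - 1). Stochastic gradient training with Adam-style
# per-parameter step sizes, mini-batches of 32, at most `epochs` epochs and
# early stopping on the validation hinge loss.

mlp_init <- function(n_in, widths, seed) {
  with_seed(seed, {
    sizes <- c(n_in, widths)
    lapply(seq_along(widths), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    A <- if (l < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[l + 1]] <- A
  }
  acts
}

mlp_hinge <- function(layers, X, y) {
  s <- mlp_forward(layers, X)[[length(layers) + 1]]
  mean(pmax(0, 1 - y * (2 * s - 1)))
}

mlp_train <- function(X, y, X_val, y_val, widths = c(16L, 32L, 16L, 1L),
                      epochs = 500L, batch = 32L, lr = 2e-3, patience = 25L,
                      seed = 1L) {
  layers <- mlp_init(ncol(X), widths, seed)
  nl <- length(layers)
  mom <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- layers; best_val <- Inf; wait <- 0L; step <- 0L
  with_seed(derive_seed(seed, 1L, 17L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      for (start in seq(1, nrow(X), by = batch)) {
        idx <- ord[start:min(start + batch - 1, nrow(X))]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        acts <- mlp_forward(layers, Xb)
        s <- acts[[nl + 1]]
        margin <- yb * (2 * s - 1)
        # d hinge / d s = -2 y on the active set
        dA <- matrix(ifelse(margin < 1, -2 * yb, 0) / length(yb), ncol = 1)
        dZ <- dA * s * (1 - s)
        step <- step + 1L
        for (l in nl:1) {
          gW <- crossprod(acts[[l]], dZ)
          gb <- colSums(dZ)
          if (l > 1) {
            dA_prev <- dZ %*% t(layers[[l]]$W)
            dZ <- dA_prev * (acts[[l]] > 0)
          }
          mom[[l]]$W <- beta1 * mom[[l]]$W + (1 - beta1) * gW
          mom[[l]]$b <- beta1 * mom[[l]]$b + (1 - beta1) * gb
          vel[[l]]$W <- beta2 * vel[[l]]$W + (1 - beta2) * gW^2
          vel[[l]]$b <- beta2 * vel[[l]]$b + (1 - beta2) * gb^2
          corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
          layers[[l]]$W <- layers[[l]]$W -
            lr * corr * mom[[l]]$W / (sqrt(vel[[l]]$W) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            lr * corr * mom[[l]]$b / (sqrt(vel[[l]]$b) + eps)
        }
      }
      val <- mlp_hinge(layers, X_val, y_val)
      if (val < best_val - 1e-6) {
        best_val <- val; best <- layers; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  structure(list(layers = best, val_loss = best_val), class = "usdot_mlp")
}

mlp_predict <- function(model, X) {
  s <- mlp_forward(model$layers, X)[[length(model$layers) + 1]]
  as.vector(s) > 0.5
}
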