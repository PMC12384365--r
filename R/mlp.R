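# Minimal multilayer perceptron: dense ReLU layers, softmax output,
# sparse categorical cross-entropy, Adam, early stopping with best-weight
# restoration. Deterministic under a fixed seed (single-threaded BLAS).

relu <- function(x) (x + abs(x)) / 2

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; returns activations of every layer (a[[1]] = input).
mlp_forward <- function(net, x) {
  a <- list(x)
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% net$W[[l]]
    z <- sweep(z, 2L, net$b[[l]], `+`)
    a[[l + 1L]] <- if (l < L) relu(z) else softmax_rows(z)
  }
  a
}

# Mean sparse categorical cross-entropy; y is 1-based class index.
mlp_loss <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

#' Fit a feedforward softmax classifier
#'
#' Dense ReLU network (default hidden sizes 128, 64, 32) with a K-unit
#' softmax output, trained by Adam (learning rate 0.001) on sparse
#' categorical cross-entropy. A seeded row shuffle sets aside the last
#' `val_fraction` of the rows for validation; training stops when the
#' validation loss has not improved for `patience` epochs and the best
#' weights are restored.
#'
#' @param x Numeric matrix of inputs (rows = examples).
#' @param y Integer class labels in `1..n_classes`.
#' @param n_classes Number of output classes.
#' @param hidden Hidden layer sizes.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs).
#' @param val_fraction Fraction of rows held out for validation.
#' @param seed Integer seed controlling initialization, the validation
#'   split and batch order.
#' @return Object of class `"mlp"`: weights, biases, training history,
#'   `best_epoch`, `val_loss`.
#' @export
mlp_fit <- function(x, y, n_classes, hidden = c(128L, 64L, 32L),
                    lr = 1e-3, batch_size = 128L, max_epochs = 100L,
                    patience = 10L, val_fraction = 0.1, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y >= 1L), all(y <= n_classes),
            val_fraction > 0, val_fraction < 0.5)
  set.seed(seed)
  n <- nrow(x)
  perm <- sample.int(n)
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- perm[(n - n_val + 1L):n]
  tr_idx <- perm[1L:(n - n_val)]
  xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]

  sizes <- c(ncol(x), hidden, n_classes)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  net <- list(W = W, b = b)
  ntr <- nrow(xt)
  bs <- min(batch_size, ntr)
  best_loss <- Inf; best <- net; best_epoch <- 0L; wait <- 0L
  history <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = bs)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1L, ntr)]
      xb <- xt[idx, , drop = FALSE]; yb <- yt[idx]
      a <- mlp_forward(net, xb)
      m <- length(idx)
      # output-layer gradient of mean CE wrt logits
      delta <- a[[L + 1L]]
      delta[cbind(seq_len(m), yb)] <- delta[cbind(seq_len(m), yb)] - 1
      delta <- delta / m
      step <- step + 1L
      corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
      for (l in L:1L) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(net$W[[l]])) * (a[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        net$W[[l]] <- net$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        net$b[[l]] <- net$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    vl <- mlp_loss(mlp_forward(net, xv)[[L + 1L]], yv)
    history <- c(history, vl)
    if (vl < best_loss - 1e-9) {
      best_loss <- vl; best <- net; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(
    list(W = best$W, b = best$b, sizes = sizes, history = history,
         best_epoch = best_epoch, val_loss = best_loss, seed = seed),
    class = "mlp"
  )
}

#' Class probabilities from a fitted MLP
#'
#' @param net An `"mlp"` object.
#' @param x Input matrix (width must match the trained input size).
#' @return Matrix of softmax probabilities, one row per input row.
#' @export
mlp_predict <- function(net, x) {
  x <- as.matrix(x)
  if (ncol(x) != net$sizes[1L]) {
    stop("input width ", ncol(x), " does not match model input size ",
         net$sizes[1L])
  }
  mlp_forward(net, x)[[length(net$W) + 1L]]
}
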