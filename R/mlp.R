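# Small feed-forward ReLU network for multiclass classification: He
# initialization, softmax cross-entropy loss, Adam updates, early stopping
# on a held-out validation slice.

.relu <- function(x) pmax(x, 0)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# x: n x p matrix; y: integer class index 1..k
mlp_fit <- function(x, y, k, hidden = c(8, 5, 8), learning_rate = 0.01,
                    batch_size = 32, epochs = 200, validation_frac = 0.15,
                    patience = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  sizes <- c(p, hidden, k)
  L <- length(sizes) - 1

  w <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    w[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1]) *
                       sqrt(2 / sizes[l]), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mw <- lapply(w, function(m) m * 0); vw <- mw
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  n_val <- floor(validation_frac * n)
  use_val <- n_val >= 5
  if (use_val) {
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    tr_idx <- seq_len(n)
  }
  xt <- x[tr_idx, , drop = FALSE]
  yt <- y[tr_idx]
  nt <- length(tr_idx)

  onehot <- function(yy) {
    m <- matrix(0, length(yy), k)
    m[cbind(seq_along(yy), yy)] <- 1
    m
  }

  forward <- function(xx) {
    act <- vector("list", L + 1)
    act[[1]] <- xx
    for (l in seq_len(L)) {
      z <- act[[l]] %*% w[[l]] + matrix(b[[l]], nrow(act[[l]]), sizes[l + 1],
                                        byrow = TRUE)
      act[[l + 1]] <- if (l < L) .relu(z) else z
    }
    act
  }

  val_loss <- function() {
    probs <- .softmax(forward(x[val_idx, , drop = FALSE])[[L + 1]])
    -mean(log(pmax(probs[cbind(seq_along(val_idx), y[val_idx])], 1e-12)))
  }

  best <- list(loss = Inf, w = w, b = b)
  stall <- 0
  step <- 0
  for (epoch in seq_len(epochs)) {
    perm <- sample(nt)
    for (start in seq(1, nt, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, nt)]
      xb <- xt[idx, , drop = FALSE]
      yb <- yt[idx]
      m <- length(idx)
      act <- forward(xb)
      probs <- .softmax(act[[L + 1]])
      delta <- (probs - onehot(yb)) / m
      step <- step + 1
      for (l in rev(seq_len(L))) {
        gw <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(w[[l]])) * (act[[l]] > 0)
        }
        mw[[l]] <- beta1 * mw[[l]] + (1 - beta1) * gw
        vw[[l]] <- beta2 * vw[[l]] + (1 - beta2) * gw^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        c1 <- 1 - beta1^step
        c2 <- 1 - beta2^step
        w[[l]] <- w[[l]] - learning_rate * (mw[[l]] / c1) /
          (sqrt(vw[[l]] / c2) + eps)
        b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / c1) /
          (sqrt(vb[[l]] / c2) + eps)
      }
    }
    if (use_val) {
      loss <- val_loss()
      if (loss < best$loss - 1e-6) {
        best <- list(loss = loss, w = w, b = b)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
  }
  if (use_val && is.finite(best$loss)) {
    w <- best$w
    b <- best$b
  }
  list(w = w, b = b, sizes = sizes, k = k)
}

mlp_predict_prob <- function(fit, x) {
  x <- as.matrix(x)
  L <- length(fit$w)
  a <- x
  for (l in seq_len(L)) {
    z <- a %*% fit$w[[l]] + matrix(fit$b[[l]], nrow(a), ncol(fit$w[[l]]),
                                   byrow = TRUE)
    a <- if (l < L) .relu(z) else z
  }
  .softmax(a)
}
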