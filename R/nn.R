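# Minimal neural-net engine on base BLAS matrix products: a three-layer
# dense classifier head (512 -> 256 -> n_classes, ReLU + dropout, sigmoid
# outputs) and a two-channel 1D convolutional sequence encoder (three conv
# layers, kernel 8, filter counts f/2f/3f, global max pooling). Trained
# with Adam on mean per-class binary cross-entropy, early stopping on
# validation loss with best-weight restoration. Gradients are verified
# against finite differences in the unit tests.

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(P, Y) {
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}
he <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# --- dense head -------------------------------------------------------------

head_init <- function(d_in, hidden, d_out) {
  p <- list()
  dims <- c(d_in, hidden)
  for (l in seq_along(hidden)) {
    p[[paste0("W", l)]] <- he(dims[l], dims[l + 1])
    p[[paste0("b", l)]] <- rep(0, dims[l + 1])
  }
  L <- length(hidden) + 1
  p[[paste0("W", L)]] <- glorot(dims[length(dims)], d_out)
  p[[paste0("b", L)]] <- rep(0, d_out)
  p
}

head_forward <- function(p, X, n_hidden, dropout, training) {
  A <- X
  cache <- list(A0 = X)
  for (l in seq_len(n_hidden)) {
    Z <- sweep(A %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
    A <- relu(Z)
    cache[[paste0("Z", l)]] <- Z
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout, nrow(A)) / (1 - dropout)
      A <- A * mask
      cache[[paste0("M", l)]] <- mask
    }
    cache[[paste0("A", l)]] <- A
  }
  L <- n_hidden + 1
  Zout <- sweep(A %*% p[[paste0("W", L)]], 2, p[[paste0("b", L)]], "+")
  cache$P <- sigmoid(Zout)
  cache
}

# dZout = dLoss/d(output logits); also returns dX for upstream encoders
head_backward <- function(p, cache, dZout, n_hidden, dropout, training) {
  g <- list()
  L <- n_hidden + 1
  dZ <- dZout
  for (l in rev(seq_len(L))) {
    A_prev <- cache[[paste0("A", l - 1)]]
    g[[paste0("W", l)]] <- crossprod(A_prev, dZ)
    g[[paste0("b", l)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, p[[paste0("W", l)]])
    if (l > 1) {
      if (training && dropout > 0) dA <- dA * cache[[paste0("M", l - 1)]]
      dZ <- dA * (cache[[paste0("Z", l - 1)]] > 0)
    } else {
      g$dX <- dA
    }
  }
  g
}

# --- 1D convolution ---------------------------------------------------------

conv_init <- function(k, c_in, f) {
  list(W = array(stats::rnorm(k * c_in * f, sd = sqrt(2 / (k * c_in))),
                 c(k, c_in, f)),
       b = rep(0, f))
}

# X: array(n, L, C); returns list(Z = relu output array(n, P, F), pre)
conv_forward <- function(X, W, b) {
  n <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  P <- L - k + 1
  Z2 <- matrix(0, n * P, f)
  for (j in seq_len(k)) {
    Xj <- matrix(X[, j:(j + P - 1), , drop = FALSE], n * P, C)
    Z2 <- Z2 + Xj %*% matrix(W[j, , ], C, f)
  }
  Z2 <- sweep(Z2, 2, b, "+")
  pre <- array(Z2, c(n, P, f))
  list(A = relu(pre), pre = pre)
}

# dA: gradient wrt the relu output; returns grads and dX
conv_backward <- function(X, W, pre, dA) {
  n <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  P <- L - k + 1
  dZ <- dA * (pre > 0)
  dZ2 <- matrix(dZ, n * P, f)
  dW <- array(0, dim(W))
  dX <- array(0, dim(X))
  for (j in seq_len(k)) {
    Xj <- matrix(X[, j:(j + P - 1), , drop = FALSE], n * P, C)
    dW[j, , ] <- crossprod(Xj, dZ2)
    dXj <- array(dZ2 %*% t(matrix(W[j, , ], C, f)), c(n, P, C))
    dX[, j:(j + P - 1), ] <- dX[, j:(j + P - 1), ] + dXj
  }
  list(dW = dW, db = colSums(dZ2), dX = dX)
}

# --- CNN channel: embedding -> 3 convs -> global max pool ------------------

channel_init <- function(vocab_size, d_emb, f, kernel) {
  E <- matrix(stats::rnorm((vocab_size + 2) * d_emb, sd = 0.1),
              vocab_size + 2, d_emb)
  E[1, ] <- 0  # index 0 = padding, frozen at zero
  list(E = E,
       c1 = conv_init(kernel, d_emb, f),
       c2 = conv_init(kernel, f, 2 * f),
       c3 = conv_init(kernel, 2 * f, 3 * f))
}

# crop width so every sample keeps at least one fully-padded window after
# three valid convs; makes pooled outputs identical to the full-length
# computation while skipping shared padding
crop_tokens <- function(tokens, kernel) {
  lens <- rowSums(tokens != 0)
  need <- 3 * (kernel - 1) + 1
  W <- max(need + kernel, min(ncol(tokens), max(lens, 1) + need + kernel))
  if (ncol(tokens) < W)
    tokens <- cbind(tokens, matrix(0L, nrow(tokens), W - ncol(tokens)))
  tokens[, seq_len(W), drop = FALSE]
}

channel_forward <- function(ch, tokens, kernel) {
  tokens <- crop_tokens(tokens, kernel)
  n <- nrow(tokens); L <- ncol(tokens); d <- ncol(ch$E)
  X0 <- array(ch$E[as.vector(tokens) + 1L, , drop = FALSE], c(n, L, d))
  f1 <- conv_forward(X0, ch$c1$W, ch$c1$b)
  f2 <- conv_forward(f1$A, ch$c2$W, ch$c2$b)
  f3 <- conv_forward(f2$A, ch$c3$W, ch$c3$b)
  P3 <- dim(f3$A)[2]; F3 <- dim(f3$A)[3]
  flat <- matrix(f3$A, n, P3 * F3)
  # global max pool over positions, per filter
  pool <- matrix(0, n, F3)
  amax <- matrix(0L, n, F3)
  for (fi in seq_len(F3)) {
    block <- flat[, ((fi - 1) * P3 + 1):(fi * P3), drop = FALSE]
    amax[, fi] <- max.col(block, ties.method = "first")
    pool[, fi] <- block[cbind(seq_len(n), amax[, fi])]
  }
  list(pool = pool, amax = amax, tokens = tokens,
       X0 = X0, f1 = f1, f2 = f2, f3 = f3)
}

channel_backward <- function(ch, cache, dPool, kernel) {
  n <- nrow(dPool); F3 <- ncol(dPool)
  P3 <- dim(cache$f3$A)[2]
  dA3 <- array(0, dim(cache$f3$A))
  for (fi in seq_len(F3))
    dA3[cbind(seq_len(n), cache$amax[, fi], fi)] <- dPool[, fi]
  b3 <- conv_backward(cache$f2$A, ch$c3$W, cache$f3$pre, dA3)
  b2 <- conv_backward(cache$f1$A, ch$c2$W, cache$f2$pre, b3$dX)
  b1 <- conv_backward(cache$X0, ch$c1$W, cache$f1$pre, b2$dX)
  # embedding rows accumulate gradients from every position using them
  dX0m <- matrix(b1$dX, n * ncol(cache$tokens), ncol(ch$E))
  dE <- matrix(0, nrow(ch$E), ncol(ch$E))
  sums <- rowsum(dX0m, group = as.vector(cache$tokens) + 1L)
  dE[as.integer(rownames(sums)), ] <- sums
  dE[1, ] <- 0  # padding row stays frozen
  list(E = dE,
       c1 = list(W = b1$dW, b = b1$db),
       c2 = list(W = b2$dW, b = b2$db),
       c3 = list(W = b3$dW, b = b3$db))
}

# --- Adam -------------------------------------------------------------------

# params/grads are arbitrarily nested lists of numeric arrays
adam_new_state <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0), how = "list")
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.numeric(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  out_p <- params; out_s <- state
  for (nm in names(params)) {
    r <- walk(params[[nm]], grads[[nm]], state[[nm]])
    out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
  }
  list(params = out_p, state = out_s)
}

# --- training loop ----------------------------------------------------------

# module contract:
#   module$forward(params, x, training) -> cache with $P
#   module$backward(params, cache, dZout, training) -> grads
#   module$slice(x, idx) -> x restricted to rows idx
#   module$n(x) -> number of samples
train_nn <- function(module, params, x_train, y_train, x_val, y_val, config) {
  local_seed(config$seed, {
    n <- module$n(x_train)
    state <- adam_new_state(params)
    best <- list(loss = Inf, params = params, epoch = 0)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    t_adam <- 0
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        b <- idx[start:min(start + config$batch_size - 1, n)]
        xb <- module$slice(x_train, b)
        yb <- y_train[b, , drop = FALSE]
        cache <- module$forward(params, xb, training = TRUE)
        dZ <- (cache$P - yb) / length(yb)  # sigmoid + mean BCE
        grads <- module$backward(params, cache, dZ, training = TRUE)
        t_adam <- t_adam + 1
        up <- adam_update(params, grads, state, config$lr, t_adam)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + bce_loss(cache$P, yb) * length(b)
        ep_n <- ep_n + length(b)
      }
      val_P <- module$forward(params, x_val, training = FALSE)$P
      val_loss <- bce_loss(val_P, y_val)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                  val_loss = val_loss))
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
    list(params = best$params, history = history, best_epoch = best$epoch,
         best_val_loss = best$loss)
  })
}
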