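# Plain-R building blocks for the ConvLSTM: LSTM and dense layers with
# explicit forward/backward passes, Glorot-uniform initialization and the
# Adam optimizer. The convolution/pooling kernels live in src/.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- LSTM -----------------------------------------------------------------
# Weights: Wx [4H x D], Wh [4H x H], b [4H]; gate order i, f, g, o.
# Forget-gate bias starts at 1 (standard remedy against early forgetting).

lstm_init <- function(input_dim, units) {
  H <- as.integer(units)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1
  list(Wx = glorot_uniform(c(4L * H, input_dim), input_dim, H),
       Wh = glorot_uniform(c(4L * H, H), H, H),
       b = b)
}

# x: [D, T, S]. Returns Hs [H, T, S]; cache holds per-step gates and states.
lstm_forward <- function(x, Wx, Wh, b, keep_cache = FALSE) {
  D <- dim(x)[1]; Tn <- dim(x)[2]; S <- dim(x)[3]
  H <- ncol(Wh)
  h <- matrix(0, H, S); cs <- matrix(0, H, S)
  Hs <- array(0, dim = c(H, Tn, S))
  cache <- NULL
  if (keep_cache)
    cache <- list(i = array(0, dim(Hs)), f = array(0, dim(Hs)),
                  g = array(0, dim(Hs)), o = array(0, dim(Hs)),
                  c = array(0, dim(Hs)), tc = array(0, dim(Hs)))
  ri <- 1:H; rf <- H + ri; rg <- 2L * H + ri; ro <- 3L * H + ri
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], D, S)
    z <- Wx %*% xt + Wh %*% h + b
    gi <- sigmoid(z[ri, , drop = FALSE])
    gf <- sigmoid(z[rf, , drop = FALSE])
    gg <- tanh(z[rg, , drop = FALSE])
    go <- sigmoid(z[ro, , drop = FALSE])
    cs <- gf * cs + gi * gg
    tc <- tanh(cs)
    h <- go * tc
    Hs[, t, ] <- h
    if (keep_cache) {
      cache$i[, t, ] <- gi; cache$f[, t, ] <- gf; cache$g[, t, ] <- gg
      cache$o[, t, ] <- go; cache$c[, t, ] <- cs; cache$tc[, t, ] <- tc
    }
  }
  list(Hs = Hs, cache = cache)
}

# Backpropagation through time. dH: [H, T, S] gradient on the outputs.
lstm_backward <- function(dH, x, Hs, cache, Wx, Wh) {
  D <- dim(x)[1]; Tn <- dim(x)[2]; S <- dim(x)[3]
  H <- ncol(Wh)
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4L * H)
  dx <- array(0, dim = c(D, Tn, S))
  dh_next <- matrix(0, H, S); dc_next <- matrix(0, H, S)
  for (t in rev(seq_len(Tn))) {
    dh <- matrix(dH[, t, ], H, S) + dh_next
    gi <- matrix(cache$i[, t, ], H, S); gf <- matrix(cache$f[, t, ], H, S)
    gg <- matrix(cache$g[, t, ], H, S); go <- matrix(cache$o[, t, ], H, S)
    tc <- matrix(cache$tc[, t, ], H, S)
    dc <- dh * go * (1 - tc^2) + dc_next
    cprev <- if (t > 1L) matrix(cache$c[, t - 1L, ], H, S) else matrix(0, H, S)
    dz <- rbind(dc * gg * gi * (1 - gi),          # i
                dc * cprev * gf * (1 - gf),       # f
                dc * gi * (1 - gg^2),             # g
                dh * tc * go * (1 - go))          # o
    xt <- matrix(x[, t, ], D, S)
    hprev <- if (t > 1L) matrix(Hs[, t - 1L, ], H, S) else matrix(0, H, S)
    dWx <- dWx + dz %*% t(xt)
    dWh <- dWh + dz %*% t(hprev)
    db <- db + rowSums(dz)
    dx[, t, ] <- crossprod(Wx, dz)
    dh_next <- crossprod(Wh, dz)
    dc_next <- dc * gf
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# ---- softmax / cross-entropy ---------------------------------------------

# Column-wise, max-stabilized softmax of a K x B logit matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Mean cross-entropy of probs [K x B] against 1-based class ids.
cross_entropy <- function(probs, y) {
  p <- probs[cbind(y, seq_along(y))]
  -mean(log(pmax(p, 1e-12)))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    p <- params[[nm]] - step
    dim(p) <- dim(params[[nm]])
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

# Inverted-dropout mask with the same shape as x.
dropout_mask <- function(x, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  array((stats::runif(length(x)) < keep) / keep, dim = dim(x) %||% length(x))
}
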