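# The ConvLSTM classifier: six zero-padded convolutions with max pooling
# after every second one, per-window feature flattening, two LSTM layers
# over the window sequence, and a three-layer dense head (two hidden layers
# plus the five-unit softmax output) applied at every sequence step.

#' ConvLSTM model configuration
#'
#' Defaults follow the reference architecture: kernel sizes 6x6 then 3x3,
#' filter counts non-decreasing with depth, pools 2x2 / 3x3 / 2x2 after conv
#' layers 2, 4 and 6, two LSTM layers whose width defaults to the number of
#' windows per sequence, dense head 1024/256, five softmax outputs,
#' Glorot-uniform initialization, Adam, L2 on the conv weights and dropout
#' 0.2 on the LSTM and dense layers. `conv_filters`, `lstm_units` and
#' `dense_units` can be scaled down for CPU-sized experiments without
#' changing the topology.
#'
#' @param conv_kernels list of 6 kernel sizes `c(kh, kw)`.
#' @param conv_filters 6 filter counts, non-decreasing.
#' @param pool_kernels list of 3 pool sizes, applied after conv 2, 4, 6.
#' @param lstm_units width of both LSTM layers.
#' @param dense_units widths of the two hidden dense layers.
#' @param n_classes number of output classes (5 gait phases).
#' @param dropout dropout rate on LSTM and dense layers.
#' @param l2_coeff L2 penalty on convolution weights.
#' @param learning_rate Adam learning rate.
#' @param seed parameter-initialization seed.
#' @return A validated `model_config` list.
#' @export
model_config <- function(conv_kernels = rep(list(c(3L, 3L)), 6L),
                         conv_filters = c(16L, 16L, 32L, 32L, 64L, 64L),
                         pool_kernels = list(c(2L, 2L), c(3L, 3L), c(2L, 2L)),
                         lstm_units = 480L,
                         dense_units = c(1024L, 256L),
                         n_classes = 5L,
                         dropout = 0.2,
                         l2_coeff = 1e-4,
                         learning_rate = 1e-3,
                         seed = 1L) {
  if (identical(conv_kernels, rep(list(c(3L, 3L)), 6L)))
    conv_kernels[[1]] <- c(6L, 6L)               # AlexNet-style opening kernel
  if (length(conv_kernels) != 6L) stop_config("conv_kernels", "exactly 6 conv stages required")
  if (length(conv_filters) != 6L) stop_config("conv_filters", "exactly 6 filter counts required")
  if (any(diff(conv_filters) < 0L))
    stop_config("conv_filters", "filter counts must be non-decreasing with depth")
  if (length(pool_kernels) != 3L) stop_config("pool_kernels", "exactly 3 pool stages required")
  if (length(dense_units) != 2L) stop_config("dense_units", "exactly 2 hidden dense layers required")
  if (n_classes < 2L) stop_config("n_classes", "must be >= 2")
  if (dropout < 0 || dropout >= 1) stop_config("dropout", "must lie in [0, 1)")
  if (l2_coeff < 0) stop_config("l2_coeff", "must be >= 0")
  if (learning_rate <= 0) stop_config("learning_rate", "must be > 0")
  if (lstm_units < 1L) stop_config("lstm_units", "must be >= 1")
  structure(list(conv_kernels = lapply(conv_kernels, as.integer),
                 conv_filters = as.integer(conv_filters),
                 pool_kernels = lapply(pool_kernels, as.integer),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 l2_coeff = l2_coeff, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs training epochs (the reference run converged in 10).
#' @param batch_sequences sequences per minibatch.
#' @param seed seed for sequence shuffling and dropout.
#' @param early_stop stop when validation accuracy has not improved for
#'   `patience` epochs; best-validation weights are retained either way.
#' @param patience epochs without improvement tolerated when `early_stop`.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_sequences = 2L, seed = 1L,
                         early_stop = FALSE, patience = 3L) {
  if (epochs < 1L) stop_config("epochs", "must be >= 1")
  if (batch_sequences < 1L) stop_config("batch_sequences", "must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_sequences = as.integer(batch_sequences),
                 seed = as.integer(seed), early_stop = isTRUE(early_stop),
                 patience = as.integer(patience)),
            class = "train_config")
}

# Pooling arithmetic (floor division); errors name the offending stage.
conv_stack_dims <- function(cfg, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  pool_after <- c(2L, 4L, 6L)
  dims <- vector("list", 6L)
  for (l in 1:6) {
    dims[[l]] <- c(h, w)                        # 'same' padding: unchanged
    if (l %in% pool_after) {
      p <- cfg$pool_kernels[[match(l, pool_after)]]
      h <- h %/% p[1]; w <- w %/% p[2]
      if (h < 1L || w < 1L)
        stop_config(paste0("pool_kernels[", match(l, pool_after), "]"),
                    sprintf("pooling after conv stage %d reduces the %dx%d map below 1x1",
                            l, dims[[l]][1], dims[[l]][2]))
      dims[[l]] <- c(h, w)                      # post-pool size at this stage
    }
  }
  list(per_stage = dims, final = c(h, w), pool_after = pool_after)
}

#' Build an untrained ConvLSTM network
#'
#' @param cfg a [model_config()].
#' @param input_shape `c(window_len, n_columns)` of one input window
#'   (50 x 70 for 10 IMUs x 7 channels at the default window length).
#' @return A `convlstm_net` with Glorot-initialized parameters.
#' @export
build_model <- function(cfg, input_shape = c(50L, 70L)) {
  stopifnot(inherits(cfg, "model_config"))
  input_shape <- as.integer(input_shape)
  geom <- conv_stack_dims(cfg, input_shape)
  feat_dim <- prod(geom$final) * cfg$conv_filters[6]

  params <- with_seed(cfg$seed, {
    p <- list()
    in_ch <- 1L
    for (l in 1:6) {
      k <- cfg$conv_kernels[[l]]; f <- cfg$conv_filters[l]
      p[[paste0("conv", l, "_w")]] <-
        glorot_uniform(c(k[1], k[2], in_ch, f),
                       fan_in = prod(k) * in_ch, fan_out = prod(k) * f)
      p[[paste0("conv", l, "_b")]] <- numeric(f)
      in_ch <- f
    }
    l1 <- lstm_init(feat_dim, cfg$lstm_units)
    l2 <- lstm_init(cfg$lstm_units, cfg$lstm_units)
    p$lstm1_Wx <- l1$Wx; p$lstm1_Wh <- l1$Wh; p$lstm1_b <- l1$b
    p$lstm2_Wx <- l2$Wx; p$lstm2_Wh <- l2$Wh; p$lstm2_b <- l2$b
    du <- cfg$dense_units
    p$dense1_W <- glorot_uniform(c(du[1], cfg$lstm_units), cfg$lstm_units, du[1])
    p$dense1_b <- numeric(du[1])
    p$dense2_W <- glorot_uniform(c(du[2], du[1]), du[1], du[2])
    p$dense2_b <- numeric(du[2])
    p$dense3_W <- glorot_uniform(c(cfg$n_classes, du[2]), du[2], cfg$n_classes)
    p$dense3_b <- numeric(cfg$n_classes)
    p
  })

  structure(list(cfg = cfg, input_shape = input_shape, geom = geom,
                 feat_dim = feat_dim, params = params, trained = FALSE),
            class = "convlstm_net")
}

# ---- forward / backward ---------------------------------------------------

# x: [wl, D, 1, B] with B = Tn*S, batch index b = (s-1)*Tn + t (t fastest).
net_forward <- function(net, x, Tn, S, train = FALSE, keep_cache = FALSE) {
  p <- net$params; cfg <- net$cfg
  pool_after <- net$geom$pool_after
  cache <- list(conv_in = vector("list", 6L), conv_mask = vector("list", 6L),
                pool = vector("list", 6L))
  a <- x
  for (l in 1:6) {
    if (keep_cache) cache$conv_in[[l]] <- a
    a <- relu(.conv2d_forward(a, p[[paste0("conv", l, "_w")]],
                              p[[paste0("conv", l, "_b")]]))
    if (keep_cache) cache$conv_mask[[l]] <- a > 0
    if (l %in% pool_after) {
      kp <- cfg$pool_kernels[[match(l, pool_after)]]
      mp <- .maxpool_forward(a, kp[1], kp[2])
      if (keep_cache) cache$pool[[l]] <- list(idx = mp$idx, xdim = dim(a))
      a <- mp$y
    }
  }
  conv6 <- a                                    # [h, w, F6, B] after pool 3
  B <- dim(a)[4]
  feat <- matrix(a, net$feat_dim, B)
  x1 <- array(feat, dim = c(net$feat_dim, Tn, S))

  l1 <- lstm_forward(x1, p$lstm1_Wx, p$lstm1_Wh, p$lstm1_b, keep_cache)
  h1 <- l1$Hs
  m1 <- if (train) dropout_mask(h1, cfg$dropout) else NULL
  if (!is.null(m1)) h1 <- h1 * m1
  l2 <- lstm_forward(h1, p$lstm2_Wx, p$lstm2_Wh, p$lstm2_b, keep_cache)
  h2 <- l2$Hs
  m2 <- if (train) dropout_mask(h2, cfg$dropout) else NULL
  if (!is.null(m2)) h2 <- h2 * m2

  Hmat <- matrix(h2, cfg$lstm_units, Tn * S)
  z1 <- p$dense1_W %*% Hmat + p$dense1_b
  d1 <- relu(z1)
  m3 <- if (train) dropout_mask(d1, cfg$dropout) else NULL
  if (!is.null(m3)) d1 <- d1 * m3
  z2 <- p$dense2_W %*% d1 + p$dense2_b
  d2 <- relu(z2)
  m4 <- if (train) dropout_mask(d2, cfg$dropout) else NULL
  if (!is.null(m4)) d2 <- d2 * m4
  logits <- p$dense3_W %*% d2 + p$dense3_b
  probs <- softmax_cols(logits)

  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- list(conv_in = cache$conv_in, conv_mask = cache$conv_mask,
                      pool = cache$pool,
                      x1 = x1, l1 = l1, h1 = h1, l2 = l2, h2 = h2,
                      Hmat = Hmat, d1 = d1, d2 = d2,
                      masks = list(m1, m2, m3, m4), Tn = Tn, S = S,
                      conv6 = conv6)
  }
  out
}

# Cross-entropy + L2 gradient for one batch; returns loss and grads.
net_backward <- function(net, fwd, y) {
  p <- net$params; cfg <- net$cfg; cc <- fwd$cache
  B <- length(y)
  grads <- list()

  dlogits <- fwd$probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B

  grads$dense3_W <- dlogits %*% t(cc$d2)
  grads$dense3_b <- rowSums(dlogits)
  dd2 <- crossprod(p$dense3_W, dlogits)
  if (!is.null(cc$masks[[4]])) dd2 <- dd2 * cc$masks[[4]]
  dd2 <- dd2 * (cc$d2 > 0)
  grads$dense2_W <- dd2 %*% t(cc$d1)
  grads$dense2_b <- rowSums(dd2)
  dd1 <- crossprod(p$dense2_W, dd2)
  if (!is.null(cc$masks[[3]])) dd1 <- dd1 * cc$masks[[3]]
  dd1 <- dd1 * (cc$d1 > 0)
  grads$dense1_W <- dd1 %*% t(cc$Hmat)
  grads$dense1_b <- rowSums(dd1)
  dH2 <- array(crossprod(p$dense1_W, dd1), dim = c(cfg$lstm_units, cc$Tn, cc$S))

  if (!is.null(cc$masks[[2]])) dH2 <- dH2 * cc$masks[[2]]
  bl2 <- lstm_backward(dH2, cc$h1, cc$l2$Hs, cc$l2$cache, p$lstm2_Wx, p$lstm2_Wh)
  grads$lstm2_Wx <- bl2$dWx; grads$lstm2_Wh <- bl2$dWh; grads$lstm2_b <- bl2$db
  dH1 <- bl2$dx
  if (!is.null(cc$masks[[1]])) dH1 <- dH1 * cc$masks[[1]]
  bl1 <- lstm_backward(dH1, cc$x1, cc$l1$Hs, cc$l1$cache, p$lstm1_Wx, p$lstm1_Wh)
  grads$lstm1_Wx <- bl1$dWx; grads$lstm1_Wh <- bl1$dWh; grads$lstm1_b <- bl1$db

  da <- bl1$dx                                   # [feat, Tn, S]
  da <- array(da, dim = dim(cc$conv6))           # back to [h, w, F6, B]
  pool_after <- net$geom$pool_after
  for (l in 6:1) {
    if (l %in% pool_after) {
      pl <- cc$pool[[l]]
      da <- .maxpool_backward(pl$idx, da, pl$xdim)
    }
    w <- net$params[[paste0("conv", l, "_w")]]
    xin <- cc$conv_in[[l]]
    da <- da * cc$conv_mask[[l]]
    bk <- .conv2d_backward(xin, w, da)
    grads[[paste0("conv", l, "_w")]] <- bk$dw + cfg$l2_coeff * w
    grads[[paste0("conv", l, "_b")]] <- bk$db
    da <- bk$dx
  }

  l2pen <- 0
  for (l in 1:6) l2pen <- l2pen + sum(net$params[[paste0("conv", l, "_w")]]^2)
  loss <- cross_entropy(fwd$probs, y) + 0.5 * cfg$l2_coeff * l2pen
  list(loss = loss, grads = grads)
}

# Build the [wl, D, 1, B] input tensor and label vector for a list of
# sequences (all must yield the same number of windows).
sequences_to_batch <- function(seqs, window_len, shift = 1L,
                               label_frame = "last") {
  L <- nrow(seqs[[1]]$frames); D <- ncol(seqs[[1]]$frames)
  Tn <- (L - window_len) %/% shift + 1L
  S <- length(seqs)
  x <- array(0, dim = c(window_len, D, 1L, Tn * S))
  y <- integer(Tn * S)
  lab_off <- if (label_frame == "last") window_len - 1L else (window_len - 1L) %/% 2L
  row_idx <- outer(seq_len(window_len), (seq_len(Tn) - 1L) * shift, `+`)
  for (s in seq_len(S)) {
    fr <- seqs[[s]]$frames
    if (nrow(fr) != L) stop("sequences in one batch must share their length")
    xs <- fr[as.vector(row_idx), , drop = FALSE]        # (wl*Tn) x D
    x[, , 1L, (s - 1L) * Tn + seq_len(Tn)] <-
      aperm(array(xs, dim = c(window_len, Tn, D)), c(1L, 3L, 2L))
    y[(s - 1L) * Tn + seq_len(Tn)] <-
      seqs[[s]]$frame_labels[(seq_len(Tn) - 1L) * shift + lab_off + 1L] + 1L
  }
  list(x = x, y = y, Tn = Tn, S = S)
}

check_batch_shape <- function(net, seqs) {
  D <- ncol(seqs[[1]]$frames)
  if (D != net$input_shape[2])
    stop("shape mismatch: network expects ", net$input_shape[1], "x",
         net$input_shape[2], " windows but received ", D, " columns")
}

eval_on_sequences <- function(net, seqs, shift = 1L) {
  n_ok <- 0L; n <- 0L; loss <- 0
  for (s in seqs) {
    b <- sequences_to_batch(list(s), net$input_shape[1], shift)
    fwd <- net_forward(net, b$x, b$Tn, b$S, train = FALSE)
    pred <- apply(fwd$probs, 2L, which.max)
    n_ok <- n_ok + sum(pred == b$y)
    n <- n + length(b$y)
    loss <- loss + cross_entropy(fwd$probs, b$y) * length(b$y)
  }
  list(accuracy = n_ok / n, loss = loss / n)
}

#' Train a ConvLSTM on sequence lists
#'
#' Minibatch Adam over whole sequences (shuffled at sequence granularity
#' every epoch), cross-entropy loss with L2 on the conv weights and
#' inverted dropout. The parameters with the best validation accuracy are
#' retained.
#'
#' @param net an untrained (or warm) `convlstm_net` from [build_model()].
#' @param train_seqs,val_seqs disjoint lists of sequences from
#'   [make_sequences()].
#' @param tcfg a [train_config()].
#' @param shift window shift used when unrolling sequences into windows.
#' @param verbose print one line per epoch.
#' @return `list(net, history)`; `history` is a data.frame with columns
#'   `epoch, train_loss, train_acc, val_loss, val_acc`.
#' @export
train_model <- function(net, train_seqs, val_seqs, tcfg = train_config(),
                        shift = 1L, verbose = FALSE) {
  if (length(train_seqs) == 0L) stop("empty training set")
  check_batch_shape(net, train_seqs)
  lr <- net$cfg$learning_rate
  state <- adam_init(net$params)
  hist <- data.frame()
  best <- list(acc = -Inf, params = net$params)
  wait <- 0L

  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(length(train_seqs))
      ep_loss <- 0; ep_ok <- 0L; ep_n <- 0L
      for (start in seq(1L, length(ord), by = tcfg$batch_sequences)) {
        take <- ord[start:min(start + tcfg$batch_sequences - 1L, length(ord))]
        b <- sequences_to_batch(train_seqs[take], net$input_shape[1], shift)
        fwd <- net_forward(net, b$x, b$Tn, b$S, train = TRUE, keep_cache = TRUE)
        bk <- net_backward(net, fwd, b$y)
        upd <- adam_step(net$params, bk$grads, state, lr)
        net$params <- upd$params
        state <- upd$state
        pred <- apply(fwd$probs, 2L, which.max)
        ep_ok <- ep_ok + sum(pred == b$y); ep_n <- ep_n + length(b$y)
        ep_loss <- ep_loss + bk$loss * length(b$y)
      }
      va <- if (length(val_seqs) > 0L) eval_on_sequences(net, val_seqs, shift)
            else list(accuracy = NA_real_, loss = NA_real_)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / ep_n,
                                     train_acc = ep_ok / ep_n,
                                     val_loss = va$loss, val_acc = va$accuracy))
      if (verbose)
        message(sprintf("epoch %d: train %.4f/%.4f val %.4f/%.4f", epoch,
                        ep_loss / ep_n, ep_ok / ep_n, va$loss, va$accuracy))
      track <- if (is.na(va$accuracy)) ep_ok / ep_n else va$accuracy
      if (track >= best$acc) {
        best$acc <- track; best$params <- net$params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (tcfg$early_stop && wait >= tcfg$patience) break
      }
    }
  })
  net$params <- best$params
  net$trained <- TRUE
  list(net = net, history = hist)
}

#' Predict gait phases for a list of sequences
#'
#' Runs the network window by window over each sequence (dropout off) and
#' collects the softmax rows, argmax classes (ties broken toward the lowest
#' class index), true labels and bookkeeping ids.
#'
#' @param net a `convlstm_net`.
#' @param seqs list of sequences from [make_sequences()].
#' @param shift window shift.
#' @return A `prediction_set`: `probs [W x 5]`, integer `pred` and `true`
#'   (codes 0..4), `subject_ids`, `sequence_ids`, `label_frames` (0-based
#'   frame of each prediction within its sequence).
#' @export
predict_phases <- function(net, seqs, shift = 1L) {
  if (length(seqs) == 0L) stop("no sequences to predict on")
  check_batch_shape(net, seqs)
  wl <- net$input_shape[1]
  probs <- NULL; pred <- integer(); true <- integer()
  sub <- character(); sq <- character(); lf <- integer()
  for (s in seqs) {
    b <- sequences_to_batch(list(s), wl, shift)
    fwd <- net_forward(net, b$x, b$Tn, b$S, train = FALSE)
    pr <- t(fwd$probs)
    probs <- rbind(probs, pr)
    pred <- c(pred, apply(fwd$probs, 2L, which.max) - 1L)
    true <- c(true, b$y - 1L)
    sub <- c(sub, rep(s$subject_id %||% "subject", b$Tn))
    sq <- c(sq, rep(s$sequence_id %||% "seq", b$Tn))
    lf <- c(lf, (seq_len(b$Tn) - 1L) * shift + wl - 1L)
  }
  colnames(probs) <- gait_phases()
  structure(list(probs = probs, pred = pred, true = true,
                 subject_ids = sub, sequence_ids = sq, label_frames = lf),
            class = "prediction_set")
}

#' @export
predict.convlstm_net <- function(object, newdata, ...) {
  predict_phases(object, newdata, ...)
}
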