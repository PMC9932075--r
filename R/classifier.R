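# Sequence-to-sequence behavior classifier: a two-layer bidirectional LSTM
# over reduced per-frame features, trained with Adam, a stepped learning
# rate, and validation-based early stopping. All forward/backward passes
# are implemented with base matrix algebra; sequences in a minibatch are
# padded to the longest member and padded frames are masked out of the
# loss and the recurrent state.

#' Default training hyperparameters
#'
#' Maximum 16 epochs; validation every epoch with patience 2 (training
#' stops once the validation loss has been >= the smallest previous
#' validation loss more than twice); initial learning rate 0.001 dropped by
#' a factor of 10 every 4 epochs; minibatch size 8; dropout 0.5 after each
#' BiLSTM layer; 15-second sequences.
#'
#' @param max_epochs,validation_patience,initial_lr,lr_drop_period,lr_drop_factor,minibatch_size,dropout,hidden_units,sequence_seconds
#'   Override any default.
#' @return Named list of class `hyperparameters`.
#' @export
default_hyperparameters <- function(max_epochs = 16L,
                                    validation_patience = 2L,
                                    initial_lr = 1e-3,
                                    lr_drop_period = 4L,
                                    lr_drop_factor = 0.1,
                                    minibatch_size = 8L,
                                    dropout = 0.5,
                                    hidden_units = 128L,
                                    sequence_seconds = 15) {
  hp <- list(max_epochs = as.integer(max_epochs),
             validation_frequency = 1L,
             validation_patience = as.integer(validation_patience),
             initial_lr = initial_lr,
             lr_drop_period = as.integer(lr_drop_period),
             lr_drop_factor = lr_drop_factor,
             minibatch_size = as.integer(minibatch_size),
             dropout = dropout,
             hidden_units = as.integer(hidden_units),
             sequence_seconds = sequence_seconds)
  stopifnot(hp$max_epochs >= 1, hp$validation_patience >= 0,
            hp$initial_lr > 0, hp$lr_drop_period >= 1,
            hp$lr_drop_factor > 0, hp$lr_drop_factor < 1,
            hp$minibatch_size >= 1, hp$dropout >= 0, hp$dropout < 1,
            hp$hidden_units >= 1, hp$sequence_seconds > 0)
  structure(hp, class = "hyperparameters")
}

#' Learning rate at a given epoch under the stepped schedule
#'
#' @param epoch Epoch number (1-based).
#' @param hp A [default_hyperparameters()] list.
#' @return `initial_lr * lr_drop_factor^floor((epoch - 1) / lr_drop_period)`:
#'   1e-3 for epochs 1-4, 1e-4 for 5-8, ... under the defaults.
#' @export
lr_at_epoch <- function(epoch, hp = default_hyperparameters()) {
  hp$initial_lr * hp$lr_drop_factor^((epoch - 1) %/% hp$lr_drop_period)
}

#' Early-stopping epoch implied by a validation-loss trace
#'
#' Scans the trace in order, counting epochs whose loss is greater than or
#' equal to the smallest loss seen before them; training stops at the epoch
#' where that count first exceeds `patience`.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Allowed number of non-improving epochs (default 2).
#' @return The stopping epoch, or `length(val_losses)` if the rule never
#'   triggers within the trace.
#' @export
early_stopping_epoch <- function(val_losses, patience = 2L) {
  best <- Inf
  violations <- 0L
  for (e in seq_along(val_losses)) {
    if (e > 1L && val_losses[e] >= best) {
      violations <- violations + 1L
      if (violations > patience) return(e)
    }
    best <- min(best, val_losses[e])
  }
  length(val_losses)
}

#' Split one clip into training sequences
#'
#' Clips are cut into sequences of `round(sequence_seconds * fps)` frames
#' (15 s by default) plus a shorter final remainder; concatenating the
#' pieces reconstructs the clip exactly.
#'
#' @param features `n x d` feature matrix for the clip.
#' @param labels Optional length-n label vector.
#' @param fps Frames per second of the source video (> 0).
#' @param sequence_seconds Sequence duration in seconds (default 15).
#' @return List of sequences, each `list(x = matrix, y = labels or NULL)`.
#' @export
split_into_sequences <- function(features, labels = NULL, fps,
                                 sequence_seconds = 15) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n == 0L)
    abort_invalid("clip has no frames")
  check_scalar_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_scalar_number(sequence_seconds, "sequence_seconds", lower = 0,
                      strict_lower = TRUE)
  if (!is.null(labels) && length(labels) != n)
    abort_invalid("%d labels for %d frames", length(labels), n)
  len <- max(1L, as.integer(round_half_up(sequence_seconds * fps)))
  starts <- seq.int(1L, n, by = len)
  lapply(starts, function(s) {
    e <- min(s + len - 1L, n)
    list(x = features[s:e, , drop = FALSE],
         y = if (is.null(labels)) NULL else labels[s:e])
  })
}

lstm_init_dir <- function(d_in, H) {
  r <- 1 / sqrt(H)
  b <- stats::runif(4L * H, -r, r)
  b[(H + 1L):(2L * H)] <- b[(H + 1L):(2L * H)] + 1   # forget-gate bias offset
  list(W = matrix(stats::runif(d_in * 4L * H, -r, r), d_in, 4L * H),
       U = matrix(stats::runif(H * 4L * H, -r, r), H, 4L * H),
       b = b)
}

#' Build an untrained sequence classification network
#'
#' Layer order: sequence input (d_in) -> BiLSTM -> dropout -> BiLSTM ->
#' dropout -> per-frame fully-connected (K) -> softmax, trained with
#' cross-entropy over K mutually exclusive classes. Each BiLSTM layer has
#' `hidden_units` units per direction (so outputs `2 * hidden_units`
#' features per frame).
#'
#' @param K Number of classes (>= 2).
#' @param d_in Input feature dimensionality (default 512).
#' @param hidden_units LSTM units per direction (default 128).
#' @param dropout Dropout probability after each BiLSTM layer (default 0.5).
#' @param bidirectional Use both temporal directions (default TRUE; FALSE
#'   gives the forward-only ablation).
#' @param seed Integer seed for weight initialization.
#' @param behaviors Optional [behavior_set()] stored with the network.
#' @return Object of class `sequence_network`.
#' @export
build_network <- function(K, d_in = 512L, hidden_units = 128L, dropout = 0.5,
                          bidirectional = TRUE, seed = 0L, behaviors = NULL) {
  check_scalar_number(K, "K", lower = 2)
  check_scalar_number(d_in, "d_in", lower = 1)
  check_scalar_number(hidden_units, "hidden_units", lower = 1)
  H <- as.integer(hidden_units)
  ndir <- if (bidirectional) 2L else 1L
  with_substream(seed, "network_init", {
    params <- list()
    for (layer in 1:2) {
      din_l <- if (layer == 1L) as.integer(d_in) else ndir * H
      params[[paste0("l", layer, "f")]] <- lstm_init_dir(din_l, H)
      if (bidirectional)
        params[[paste0("l", layer, "b")]] <- lstm_init_dir(din_l, H)
    }
    r <- 1 / sqrt(ndir * H)
    params$fc <- list(W = matrix(stats::runif(ndir * H * K, -r, r),
                                 ndir * H, K),
                      b = numeric(K))
    structure(
      list(params = params, K = as.integer(K), d_in = as.integer(d_in),
           H = H, dropout = dropout, bidirectional = bidirectional,
           seed = seed, behaviors = behaviors, trained = FALSE),
      class = "sequence_network"
    )
  })
}

#' @export
print.sequence_network <- function(x, ...) {
  cat(sprintf(
    "<sequence_network> %s2x%sLSTM(%d) %d-d input -> %d classes%s\n",
    if (x$trained) "trained " else "untrained ",
    if (x$bidirectional) "Bi" else "", x$H, x$d_in, x$K,
    if (x$trained) sprintf(" (stopped: %s)", x$stopping_reason) else ""))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM direction over a padded batch.
# X: [B*T, d] time-major blocks (rows (t-1)*B + 1:B); mask: [B, T] in {0,1}.
lstm_dir_forward <- function(X, p, B, T, mask, reverse = FALSE) {
  H <- ncol(p$U) / 4L
  XW <- X %*% p$W
  gi <- matrix(0, B * T, H); gf <- gi; gg <- gi; go <- gi
  cc <- gi; tc <- gi; hh <- gi
  h <- matrix(0, B, H)
  c <- matrix(0, B, H)
  steps <- if (reverse) T:1 else 1:T
  for (t in steps) {
    idx <- (t - 1L) * B + seq_len(B)
    a <- XW[idx, , drop = FALSE] + h %*% p$U
    a <- sweep(a, 2L, p$b, `+`)
    i_g <- sigmoid(a[, 1:H, drop = FALSE])
    f_g <- sigmoid(a[, H + 1:H, drop = FALSE])
    g_g <- tanh(a[, 2L * H + 1:H, drop = FALSE])
    o_g <- sigmoid(a[, 3L * H + 1:H, drop = FALSE])
    m <- mask[, t]
    c <- (f_g * c + i_g * g_g) * m
    tch <- tanh(c)
    h <- (o_g * tch) * m
    gi[idx, ] <- i_g; gf[idx, ] <- f_g; gg[idx, ] <- g_g; go[idx, ] <- o_g
    cc[idx, ] <- c; tc[idx, ] <- tch; hh[idx, ] <- h
  }
  list(h = hh, cache = list(gi = gi, gf = gf, gg = gg, go = go, cc = cc,
                            tc = tc, X = X, reverse = reverse))
}

lstm_dir_backward <- function(dH, fwd, p, B, T, mask) {
  ca <- fwd$cache
  H <- ncol(p$U) / 4L
  dW <- matrix(0, nrow(p$W), 4L * H)
  dU <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- matrix(0, nrow(ca$X), ncol(ca$X))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  steps <- if (ca$reverse) 1:T else T:1   # reverse of the forward order
  for (t in steps) {
    idx <- (t - 1L) * B + seq_len(B)
    m <- mask[, t]
    dh <- (dH[idx, , drop = FALSE] + dh_next) * m
    o_g <- ca$go[idx, , drop = FALSE]
    tch <- ca$tc[idx, , drop = FALSE]
    dc <- (dc_next + dh * o_g * (1 - tch^2)) * m
    i_g <- ca$gi[idx, , drop = FALSE]
    f_g <- ca$gf[idx, , drop = FALSE]
    g_g <- ca$gg[idx, , drop = FALSE]
    prev_t <- if (ca$reverse) t + 1L else t - 1L
    c_prev <- if (prev_t >= 1L && prev_t <= T)
      ca$cc[(prev_t - 1L) * B + seq_len(B), , drop = FALSE]
    else matrix(0, B, H)
    h_prev <- if (prev_t >= 1L && prev_t <= T)
      fwd$h[(prev_t - 1L) * B + seq_len(B), , drop = FALSE]
    else matrix(0, B, H)
    da <- cbind(dc * g_g * i_g * (1 - i_g),
                dc * c_prev * f_g * (1 - f_g),
                dc * i_g * (1 - g_g^2),
                dh * tch * o_g * (1 - o_g))
    dW <- dW + crossprod(ca$X[idx, , drop = FALSE], da)
    dU <- dU + crossprod(h_prev, da)
    db <- db + colSums(da)
    dX[idx, ] <- da %*% t(p$W)
    dh_next <- da %*% t(p$U)
    dc_next <- dc * f_g
  }
  list(dX = dX, grads = list(W = dW, U = dU, b = db))
}

bilstm_layer_forward <- function(X, pf, pb, B, T, mask) {
  f <- lstm_dir_forward(X, pf, B, T, mask, reverse = FALSE)
  if (is.null(pb)) return(list(h = f$h, f = f, b = NULL))
  b <- lstm_dir_forward(X, pb, B, T, mask, reverse = TRUE)
  list(h = cbind(f$h, b$h), f = f, b = b)
}

bilstm_layer_backward <- function(dH, layer, pf, pb, B, T, mask) {
  H <- ncol(pf$U) / 4L
  bf <- lstm_dir_backward(dH[, 1:H, drop = FALSE], layer$f, pf, B, T, mask)
  if (is.null(pb))
    return(list(dX = bf$dX, f = bf$grads, b = NULL))
  bb <- lstm_dir_backward(dH[, H + 1:H, drop = FALSE], layer$b, pb, B, T,
                          mask)
  list(dX = bf$dX + bb$dX, f = bf$grads, b = bb$grads)
}

# Pack sequences into a padded time-major batch.
pack_batch <- function(seqs, K = NULL) {
  B <- length(seqs)
  lens <- vapply(seqs, function(s) nrow(s$x), integer(1))
  T <- max(lens)
  d <- ncol(seqs[[1L]]$x)
  X <- matrix(0, B * T, d)
  Y <- matrix(0L, B, T)
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    for (t in seq_len(lens[b])) X[(t - 1L) * B + b, ] <- s$x[t, ]
    mask[b, seq_len(lens[b])] <- 1
    if (!is.null(s$y)) Y[b, seq_len(lens[b])] <- s$y
  }
  list(X = X, Y = Y, mask = mask, B = B, T = T, lens = lens)
}

# Full forward pass; dropout masks are drawn by the caller (NULL = eval).
network_forward <- function(net, batch, drop_masks = NULL) {
  p <- net$params
  l1 <- bilstm_layer_forward(batch$X, p$l1f, p$l1b, batch$B, batch$T,
                             batch$mask)
  h1 <- if (is.null(drop_masks)) l1$h else l1$h * drop_masks[[1L]]
  l2 <- bilstm_layer_forward(h1, p$l2f, p$l2b, batch$B, batch$T, batch$mask)
  h2 <- if (is.null(drop_masks)) l2$h else l2$h * drop_masks[[2L]]
  logits <- sweep(h2 %*% p$fc$W, 2L, p$fc$b, `+`)
  list(l1 = l1, h1 = h1, l2 = l2, h2 = h2, logits = logits)
}

masked_ce_loss <- function(logits, Y, mask, B, T) {
  # time-major row (t-1)*B + b is column-major position (b, t) of [B, T]
  mvec <- as.vector(mask)
  yvec <- as.vector(Y)
  P <- softmax_rows(logits)
  valid <- mvec > 0 & yvec > 0L
  n_valid <- sum(valid)
  ll <- -sum(log(pmax(P[cbind(which(valid), yvec[valid])], 1e-300)))
  dlogits <- P
  dlogits[cbind(which(valid), yvec[valid])] <-
    dlogits[cbind(which(valid), yvec[valid])] - 1
  dlogits[!valid, ] <- 0
  list(loss = ll / n_valid, dlogits = dlogits / n_valid, n_valid = n_valid)
}

network_backward <- function(net, batch, fwd, loss) {
  p <- net$params
  grads <- list()
  grads$fc <- list(W = crossprod(fwd$h2, loss$dlogits),
                   b = colSums(loss$dlogits))
  dh2 <- loss$dlogits %*% t(p$fc$W)
  if (!is.null(fwd$drop2)) dh2 <- dh2 * fwd$drop2
  g2 <- bilstm_layer_backward(dh2, fwd$l2, p$l2f, p$l2b, batch$B, batch$T,
                              batch$mask)
  grads$l2f <- g2$f
  if (!is.null(g2$b)) grads$l2b <- g2$b
  dh1 <- g2$dX
  if (!is.null(fwd$drop1)) dh1 <- dh1 * fwd$drop1
  g1 <- bilstm_layer_backward(dh1, fwd$l1, p$l1f, p$l1b, batch$B, batch$T,
                              batch$mask)
  grads$l1f <- g1$f
  if (!is.null(g1$b)) grads$l1b <- g1$b
  grads
}

# Adam over the nested parameter list.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (is.null(state$m[[nm]][[pn]])) {
        state$m[[nm]][[pn]] <- g * 0
        state$v[[nm]][[pn]] <- g * 0
      }
      state$m[[nm]][[pn]] <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      state$v[[nm]][[pn]] <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g^2
      params[[nm]][[pn]] <- params[[nm]][[pn]] -
        lr * (state$m[[nm]][[pn]] / bc1) /
        (sqrt(state$v[[nm]][[pn]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

eval_loss <- function(net, seqs, minibatch_size) {
  tot <- 0
  n <- 0
  for (chunk in split(seq_along(seqs),
                      ceiling(seq_along(seqs) / minibatch_size))) {
    batch <- pack_batch(seqs[chunk])
    fwd <- network_forward(net, batch)
    loss <- masked_ce_loss(fwd$logits, batch$Y, batch$mask, batch$B, batch$T)
    tot <- tot + loss$loss * loss$n_valid
    n <- n + loss$n_valid
  }
  tot / n
}

resolve_seq_labels <- function(seqs, net) {
  lapply(seqs, function(s) {
    if (!is.null(s$y) && !is.numeric(s$y)) {
      s$y <- resolve_label_index(s$y, net$K, net$behaviors)
    }
    s
  })
}

#' Train a sequence network
#'
#' Adam optimization with the stepped learning-rate schedule of
#' [lr_at_epoch()], shuffled minibatches of padded sequences, per-epoch
#' validation loss, and early stopping once the validation loss has been
#' greater than or equal to the smallest previous validation loss more than
#' `validation_patience` times. The returned model carries the parameters
#' of the best-validation epoch.
#'
#' @param network An untrained [build_network()] model.
#' @param train_seqs,val_seqs Lists of sequences `list(x = m x d matrix, y =
#'   labels)`, e.g. from [split_into_sequences()] over the training and
#'   validation clips.
#' @param hp Hyperparameters from [default_hyperparameters()].
#' @param seed Integer seed driving shuffling and dropout.
#' @return The trained `sequence_network`, with `log` (per-epoch
#'   data.frame: epoch, lr, train_loss, val_loss), `stopping_reason`
#'   (`"patience"` or `"max_epochs"`) and `best_epoch`.
#' @export
train_network <- function(network, train_seqs, val_seqs,
                          hp = default_hyperparameters(), seed = 0L) {
  stopifnot(inherits(network, "sequence_network"))
  if (length(train_seqs) == 0L || length(val_seqs) == 0L)
    abort_invalid("training and validation sets must be non-empty")
  train_seqs <- resolve_seq_labels(train_seqs, network)
  val_seqs <- resolve_seq_labels(val_seqs, network)
  all_y <- unlist(lapply(train_seqs, `[[`, "y"))
  if (length(unique(all_y)) < 2L)
    warning("training labels contain a single class; the fit is degenerate",
            call. = FALSE)
  net <- network
  state <- list(t = 0L, m = list(), v = list())
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_loss = numeric())
  best_loss <- Inf
  best_params <- net$params
  best_epoch <- 0L
  violations <- 0L
  stopping <- "max_epochs"
  ndir <- if (net$bidirectional) 2L else 1L
  for (epoch in seq_len(hp$max_epochs)) {
    lr <- lr_at_epoch(epoch, hp)
    ord <- with_substream(seed, paste0("shuffle_epoch", epoch),
                          sample.int(length(train_seqs)))
    epoch_loss <- 0
    epoch_n <- 0
    batch_no <- 0L
    for (chunk in split(ord, ceiling(seq_along(ord) / hp$minibatch_size))) {
      batch_no <- batch_no + 1L
      batch <- pack_batch(train_seqs[chunk])
      drop_masks <- if (hp$dropout > 0) {
        with_substream(seed, sprintf("dropout_e%d_b%d", epoch, batch_no), {
          lapply(1:2, function(i)
            matrix(stats::rbinom(nrow(batch$X) * ndir * net$H, 1L,
                                 1 - hp$dropout) / (1 - hp$dropout),
                   nrow(batch$X), ndir * net$H))
        })
      } else NULL
      fwd <- network_forward(net, batch, drop_masks)
      if (!is.null(drop_masks)) {
        fwd$drop1 <- drop_masks[[1L]]
        fwd$drop2 <- drop_masks[[2L]]
      }
      loss <- masked_ce_loss(fwd$logits, batch$Y, batch$mask, batch$B,
                             batch$T)
      grads <- network_backward(net, batch, fwd, loss)
      upd <- adam_step(net$params, grads, state, lr)
      net$params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + loss$loss * loss$n_valid
      epoch_n <- epoch_n + loss$n_valid
    }
    val_loss <- eval_loss(net, val_seqs, hp$minibatch_size)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = epoch_loss / epoch_n,
                                 val_loss = val_loss))
    if (epoch > 1L && val_loss >= best_loss) {
      violations <- violations + 1L
    }
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_params <- net$params
      best_epoch <- epoch
    }
    if (violations > hp$validation_patience) {
      stopping <- "patience"
      break
    }
  }
  if (best_epoch == 0L) {   # first epoch never improved on Inf: impossible,
    best_params <- net$params; best_epoch <- nrow(log)   # defensive only
  }
  net$params <- best_params
  net$trained <- TRUE
  net$log <- log
  net$stopping_reason <- stopping
  net$best_epoch <- best_epoch
  net$hp <- hp
  net$train_seed <- seed
  net
}

#' Per-frame predictions for a clip
#'
#' Splits the clip's features into sequences (same rule as training),
#' runs the network in evaluation mode (dropout disabled), and
#' re-concatenates the per-frame outputs.
#'
#' @param model A trained `sequence_network`.
#' @param features `n x d_in` feature matrix for the clip.
#' @param fps Frames per second (used for the 15-s sequence split).
#' @param hp Hyperparameters (for `sequence_seconds`).
#' @return Object of class `prediction_result`: `logits` (n x K), `probs`
#'   (n x K, rows sum to 1), `labels` (argmax; behavior names when the
#'   network has a behavior set, else 1-based indices), `label_idx`.
#' @export
predict_frames <- function(model, features, fps,
                           hp = model$hp %||% default_hyperparameters()) {
  stopifnot(inherits(model, "sequence_network"))
  features <- as.matrix(features)
  if (ncol(features) != model$d_in)
    abort_invalid("model expects %d feature columns, got %d", model$d_in,
                  ncol(features))
  seqs <- split_into_sequences(features, NULL, fps, hp$sequence_seconds)
  logits <- matrix(0, 0L, model$K)
  for (s in seqs) {
    batch <- pack_batch(list(s))
    fwd <- network_forward(model, batch)
    logits <- rbind(logits, fwd$logits[seq_len(nrow(s$x)), , drop = FALSE])
  }
  probs <- softmax_rows(logits)
  idx <- max.col(probs, ties.method = "first")
  labels <- if (!is.null(model$behaviors)) model$behaviors$labels[idx] else idx
  structure(
    list(logits = logits, probs = probs, labels = labels, label_idx = idx,
         n = nrow(logits), K = model$K),
    class = "prediction_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d frames x %d classes\n", x$n, x$K))
  invisible(x)
}
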