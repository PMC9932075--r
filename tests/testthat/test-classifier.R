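test_that("clips split into 15-s sequences that reconstruct exactly", {
  set.seed(1)
  x <- matrix(rnorm(600 * 4), 600, 4)   # 60 s at 10 fps
  y <- sample(1:3, 600, TRUE)
  seqs <- split_into_sequences(x, y, fps = 10)
  expect_length(seqs, 4L)
  expect_true(all(vapply(seqs, function(s) nrow(s$x), integer(1)) == 150L))

  # shorter than one sequence: unchanged
  seqs1 <- split_into_sequences(x[1:80, ], y[1:80], fps = 10)
  expect_length(seqs1, 1L)
  expect_equal(seqs1[[1]]$x, x[1:80, ])

  # remainder case + exact reconstruction
  seqs2 <- split_into_sequences(x[1:400, ], y[1:400], fps = 10)
  expect_equal(vapply(seqs2, function(s) nrow(s$x), integer(1)),
               c(150L, 150L, 100L))
  expect_equal(do.call(rbind, lapply(seqs2, `[[`, "x")), x[1:400, ])
  expect_equal(unlist(lapply(seqs2, `[[`, "y")), y[1:400])

  expect_error(split_into_sequences(x[0, , drop = FALSE], NULL, 10),
               "no frames")
})

test_that("the network outputs per-frame probability rows deterministically", {
  net <- build_network(K = 4, d_in = 6, hidden_units = 5, seed = 2)
  set.seed(3)
  seqs <- list(list(x = matrix(rnorm(7 * 6), 7, 6), y = NULL))
  batch <- ethocoder:::pack_batch(seqs)
  f1 <- ethocoder:::network_forward(net, batch)
  f2 <- ethocoder:::network_forward(net, batch)
  expect_identical(f1$logits, f2$logits)   # eval mode: no dropout
  probs <- ethocoder:::softmax_rows(f1$logits)
  expect_equal(dim(probs), c(7L, 4L))
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-6)
  expect_error(build_network(K = 1, d_in = 6), "K")
})

test_that("backpropagated gradients match finite differences", {
  net <- build_network(K = 3, d_in = 4, hidden_units = 3, dropout = 0,
                       seed = 5)
  set.seed(7)
  seqs <- list(list(x = matrix(rnorm(20), 5, 4), y = c(1, 2, 3, 1, 2)),
               list(x = matrix(rnorm(12), 3, 4), y = c(2, 1, 3)))
  batch <- ethocoder:::pack_batch(seqs)
  fwd <- ethocoder:::network_forward(net, batch)
  loss <- ethocoder:::masked_ce_loss(fwd$logits, batch$Y, batch$mask,
                                     batch$B, batch$T)
  grads <- ethocoder:::network_backward(net, batch, fwd, loss)
  loss_at <- function(par) {
    n2 <- net
    n2$params <- par
    f2 <- ethocoder:::network_forward(n2, batch)
    ethocoder:::masked_ce_loss(f2$logits, batch$Y, batch$mask, batch$B,
                               batch$T)$loss
  }
  set.seed(8)
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      for (i in sample(seq_along(g), min(length(g), 6))) {
        up <- net$params; up[[nm]][[pn]][i] <- up[[nm]][[pn]][i] + 1e-5
        dn <- net$params; dn[[nm]][[pn]][i] <- dn[[nm]][[pn]][i] - 1e-5
        gn <- (loss_at(up) - loss_at(dn)) / 2e-5
        expect_equal(g[i], gn, tolerance = 1e-3)
      }
    }
  }
})

test_that("the early-stopping rule and learning-rate schedule are followed", {
  # scripted trace: three epochs >= the running minimum stop training
  expect_equal(early_stopping_epoch(c(1.0, 0.9, 0.95, 0.92, 0.91, 0.89)), 5L)
  # monotone decreasing: runs to the end of the trace
  expect_equal(early_stopping_epoch(seq(1, 0.1, length.out = 16)), 16L)
  # equality counts against patience
  expect_equal(early_stopping_epoch(c(0.5, 0.5, 0.5, 0.5)), 4L)

  hp <- default_hyperparameters()
  expect_equal(hp$max_epochs, 16L)
  expect_equal(hp$minibatch_size, 8L)
  expect_equal(vapply(1:8, lr_at_epoch, numeric(1), hp = hp),
               c(rep(1e-3, 4), rep(1e-4, 4)))
})

test_that("training learns separable sequences, reproducibly, logging the schedule", {
  clips <- lapply(1:12, function(i)
    markov_gaussian_clip(120, K = 3, d = 8, delta = 8, sigma = 0.8,
                         seed = i))
  tr <- clips_to_seqs(clips[1:9], fps = 2)
  va <- clips_to_seqs(clips[10:12], fps = 2)
  hp <- default_hyperparameters(hidden_units = 16, max_epochs = 6)
  net <- build_network(3, d_in = 8, hidden_units = 16, seed = 1)
  m <- train_network(net, tr, va, hp, seed = 4)
  expect_true(m$trained)
  expect_lte(nrow(m$log), 6L)
  expect_true(m$stopping_reason %in% c("patience", "max_epochs"))
  expect_equal(m$log$lr, vapply(m$log$epoch, lr_at_epoch, numeric(1),
                                hp = hp))
  # validation loss of the restored parameters equals the best logged loss
  expect_equal(ethocoder:::eval_loss(m, va, hp$minibatch_size),
               min(m$log$val_loss), tolerance = 1e-10)

  te <- markov_gaussian_clip(200, K = 3, d = 8, delta = 8, sigma = 0.8,
                             seed = 77)
  pr <- predict_frames(m, te$x, fps = 2)
  expect_equal(pr$n, 200L)
  expect_equal(pr$label_idx, max.col(pr$probs, ties.method = "first"))
  expect_equal(rowSums(pr$probs), rep(1, 200), tolerance = 1e-6)
  expect_gt(mean(pr$label_idx == te$y), 0.5)

  # identical seeds reproduce the run end-to-end
  m2 <- train_network(build_network(3, d_in = 8, hidden_units = 16, seed = 1),
                      tr, va, hp, seed = 4)
  expect_identical(m$log, m2$log)
  expect_identical(predict_frames(m2, te$x, fps = 2)$logits, pr$logits)

  # single-class training labels warn but proceed
  tr1 <- lapply(tr[1:2], function(s) { s$y[] <- 1L; s })
  expect_warning(
    train_network(build_network(3, d_in = 8, hidden_units = 4, seed = 1),
                  tr1, va[1], default_hyperparameters(max_epochs = 1,
                                                      hidden_units = 4),
                  seed = 1),
    "single class")

  expect_error(predict_frames(m, te$x[, 1:5], fps = 2), "feature columns")
})

test_that("bidirectional context beats a forward-only network on future-dependent labels", {
  K <- 2; d <- 6
  mkseq <- function(n, seed) {
    set.seed(seed)
    c_j <- sample(1:K, n, TRUE)
    x <- 2 * diag(K)[c_j, ] + matrix(rnorm(n * K, sd = 0.3), n, K)
    x <- cbind(x, matrix(rnorm(n * (d - K), sd = 0.3), n, d - K))
    list(x = x, y = c_j[pmin(seq_len(n) + 3, n)])   # label set 3 frames ahead
  }
  tr <- lapply(1:30, function(i) mkseq(40, i))
  va <- lapply(31:36, function(i) mkseq(40, i))
  te <- mkseq(400, 99)
  hp <- default_hyperparameters(hidden_units = 16)
  mb <- train_network(build_network(K, d, 16, bidirectional = TRUE, seed = 1),
                      tr, va, hp, seed = 7)
  mf <- train_network(build_network(K, d, 16, bidirectional = FALSE, seed = 1),
                      tr, va, hp, seed = 7)
  acc_bi <- mean(predict_frames(mb, te$x, 2)$label_idx == te$y)
  acc_fwd <- mean(predict_frames(mf, te$x, 2)$label_idx == te$y)
  expect_gt(acc_bi, acc_fwd + 0.05)
})
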