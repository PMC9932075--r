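test_that("Markov label sequences have the requested bout structure", {
  b2 <- behavior_set(c("a", "b"))
  # p_stay = 0 with two classes alternates strictly
  spec <- synthetic_behavior_spec(b2, p_stay = 0)
  y <- generate_label_sequence(spec, 50, seed = 1)
  expect_true(all(y[-1] != y[-50]))

  # p_stay = 0.9: geometric bouts with mean 1 / (1 - 0.9) = 10 frames
  spec <- synthetic_behavior_spec(behavior_set(c("a", "b", "c")),
                                  p_stay = 0.9)
  y <- generate_label_sequence(spec, 1e5, seed = 2)
  mean_bout <- mean(bout_lengths(y)$bouts$length)
  expect_lt(abs(mean_bout - 10) / 10, 0.1)

  # reproducibility
  expect_identical(generate_label_sequence(spec, 500, seed = 9),
                   generate_label_sequence(spec, 500, seed = 9))
  # transition matrix rows are stochastic
  P <- transition_matrix(spec)
  expect_equal(rowSums(P), rep(1, 3))

  # class imbalance arises from unequal bout lengths: the long-bout
  # behavior occupies the stationary fraction of frames
  spec_w <- synthetic_behavior_spec(b2, p_stay = c(0.9, 0.6))
  pi_w <- stationary_weights(spec_w)
  expect_equal(sum(pi_w), 1)
  expect_gt(pi_w[["a"]], 0.6)
  yw <- generate_label_sequence(spec_w, 2e4, seed = 3)
  expect_lt(abs(mean(yw == "a") - pi_w[["a"]]), 0.05)
})

test_that("synthetic video motion follows the behavior kernels", {
  spec <- synthetic_behavior_spec(c("rest", "walk"), p_stay = 0.95,
                                  jitter = 0,
                                  velocity = rbind(c(0, 0), c(3, 0)),
                                  frame_size = 64, fps = 10)
  v <- generate_video(spec, 40, seed = 8)
  expect_length(v$frames, 40L)
  expect_length(v$labels, 40L)
  expect_true(all(vapply(v$frames, function(f)
    all(dim(f) == c(64, 64)) && all(f >= 0 & f <= 1), logical(1))))

  r <- rle(v$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  checked <- c(rest = FALSE, walk = FALSE)
  for (i in seq_along(r$values)) {
    if (r$lengths[i] < 4 || checked[r$values[i]]) next
    t1 <- starts[i] + 1
    f <- compute_tvl1_flow(v$frames[[t1]], v$frames[[t1 + 1]])
    med <- median(flow_magnitude(f))
    if (r$values[i] == "rest") expect_lt(med, 0.2)
    else expect_lt(abs(med - 3), 0.5)
    checked[r$values[i]] <- TRUE
  }
  expect_true(all(checked))
})

test_that("class-conditional features separate according to delta", {
  bset <- behavior_set(c("a", "b", "c"))
  y <- generate_label_sequence(synthetic_behavior_spec(bset), 600, seed = 4)
  idx <- match(y, bset$labels)

  spec6 <- synthetic_feature_spec(3, d = 64, delta = 6, sigma = 1)
  X <- generate_features(spec6, idx, seed = 5)
  expect_equal(dim(X), c(600L, 64L))
  # nearest-class-mean classification is near-perfect at delta = 6 sigma
  d2 <- sapply(1:3, function(k)
    rowSums(sweep(X, 2, spec6$means[k, ])^2))
  expect_gt(mean(max.col(-d2) == idx), 0.95)

  # delta = 0: features carry no class signal
  spec0 <- synthetic_feature_spec(3, d = 64, delta = 0, sigma = 1)
  X0 <- generate_features(spec0, idx, seed = 5)
  d2 <- sapply(1:3, function(k)
    rowSums(sweep(X0, 2, spec0$means[k, ])^2))
  expect_lt(mean(max.col(-d2) == idx), 0.5)

  expect_identical(generate_features(spec6, idx, seed = 5), X)
})

test_that("calibrated logits have the requested accuracy and calibration", {
  bset <- behavior_set(c("a", "b", "c"))
  y <- generate_label_sequence(synthetic_behavior_spec(bset), 1e4, seed = 6)
  g <- generate_calibrated_logits(y, K = 3, base_accuracy = 0.75, seed = 7,
                                  behaviors = bset)
  expect_lt(abs(mean(g$pred == g$labels) - 0.75), 0.02)
  # emitted probabilities are calibrated: confidence matches accuracy
  conf <- softmax_confidence(g$logits)
  expect_lt(abs(mean(conf) - mean(g$pred == g$labels)), 0.02)
  expect_error(
    generate_calibrated_logits(y, K = 3, base_accuracy = 0.2,
                               behaviors = bset),
    "base_accuracy")
})
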