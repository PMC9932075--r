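test_that("max-softmax confidence evaluates the softmax correctly", {
  z <- matrix(c(2, 0, 0), 1)
  expect_equal(softmax_confidence(z), exp(2) / (exp(2) + 2),
               tolerance = 1e-12)
  expect_equal(softmax_confidence(matrix(1, 1, 5)), 0.2)
  # shift invariance
  set.seed(1)
  z <- matrix(rnorm(30), 10, 3)
  expect_equal(softmax_confidence(z), softmax_confidence(z + 100))
  # range [1/K, 1]
  expect_true(all(softmax_confidence(z) >= 1 / 3 - 1e-12))
  expect_true(all(softmax_confidence(z) <= 1))
  expect_error(softmax_confidence(matrix(c(1, Inf), 1)), "finite")
  expect_error(softmax_confidence(matrix(1, 2, 1)), "K >= 2")
})

test_that("temperature scaling softens confidence without changing labels", {
  set.seed(2)
  z <- matrix(rnorm(60, sd = 2), 20, 3)
  expect_equal(scaled_confidence(z, 1), softmax_confidence(z))
  expect_equal(scaled_confidence(z, 1e6), rep(1 / 3, 20), tolerance = 1e-4)
  # T > 1 strictly lowers non-uniform confidences
  expect_true(all(scaled_confidence(z, 2) < softmax_confidence(z)))
  # argmax labels unchanged by any T
  for (T in c(0.3, 2, 7)) {
    expect_equal(max.col(z / T), max.col(z))
  }
  expect_error(scaled_confidence(z, 0), "T")
})

test_that("fitted temperature recovers the miscalibration scale", {
  bset <- behavior_set(c("a", "b", "c"))
  spec <- synthetic_behavior_spec(bset)
  y <- generate_label_sequence(spec, 8000, seed = 4)

  g1 <- generate_calibrated_logits(y, K = 3, base_accuracy = 0.8,
                                   overconfidence_scale = 1, seed = 5,
                                   behaviors = bset)
  t1 <- fit_temperature(g1$logits, g1$labels)
  expect_lt(abs(t1$T - 1), 0.05)
  expect_lte(t1$nll, t1$nll_1)

  g2 <- generate_calibrated_logits(y, K = 3, base_accuracy = 0.8,
                                   overconfidence_scale = 2, seed = 5,
                                   behaviors = bset)
  t2 <- fit_temperature(g2$logits, g2$labels)
  expect_lt(abs(t2$T - 2), 0.1)
  expect_lte(t2$nll, t2$nll_1)

  # grid-search oracle agrees with the 1-D minimization
  grid <- exp(seq(log(0.05), log(20), length.out = 2000))
  nlls <- vapply(grid, function(T)
    ethocoder:::nll_at_temperature(g2$logits, g2$labels, T), numeric(1))
  expect_lt(abs(t2$T - grid[which.min(nlls)]), 0.02)

  expect_error(fit_temperature(g1$logits, rep(1L, nrow(g1$logits))),
               "2 classes")
})

test_that("clip and dataset aggregation are the stated means", {
  expect_equal(clip_confidence(c(1, 0.5, 0.75, 0.75)), 0.75)
  expect_equal(clip_confidence(rep(0.8, 5)), 0.8)
  p <- runif(10, 0.4, 1)
  expect_gte(clip_confidence(p), min(p))
  expect_lte(clip_confidence(p), max(p))

  expect_equal(clip_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "a")),
               0.75)
  expect_equal(clip_accuracy(c("a", "b"), c("a", "b")), 1)
  # identical computation to frame accuracy
  set.seed(6)
  p <- sample(letters[1:3], 30, TRUE); t <- sample(letters[1:3], 30, TRUE)
  expect_equal(clip_accuracy(p, t), accuracy(p, t))

  # frame-count weighting
  expect_equal(dataset_confidence(c(0.8, 0.6), c(100, 300)), 0.65)
  expect_equal(dataset_confidence(c(0.9, 0.5), c(10, 10)), 0.7)
  expect_equal(dataset_confidence(0.42, 77), 0.42)
})

test_that("calibration errors decompose into PE, AE, MAE, MSD", {
  rep1 <- calibration_errors(c(0.9, 0.7), c(0.8, 0.8))
  expect_equal(rep1$clips$PE, c(0.1, -0.1))
  expect_equal(rep1$clips$AE, c(0.1, 0.1))
  expect_equal(rep1$MAE, 0.1)
  expect_equal(rep1$MSD, 0)

  rep2 <- calibration_errors(c(0.5, 0.75), c(0.5, 0.75))
  expect_equal(rep2$MAE, 0)
  expect_equal(rep2$MSD, 0)

  set.seed(7)
  conf <- runif(20); acc <- runif(20)
  rep3 <- calibration_errors(conf, acc)
  expect_gte(rep3$MAE, abs(rep3$MSD))
  expect_equal(rep3$clips$AE, abs(rep3$clips$PE))
  expect_error(calibration_errors(conf, acc[1:3]), "differ in length")
})

test_that("temperature scaling shrinks the signed calibration bias", {
  bset <- behavior_set(c("a", "b", "c"))
  y <- generate_label_sequence(synthetic_behavior_spec(bset), 8000, seed = 8)
  g <- generate_calibrated_logits(y, K = 3, base_accuracy = 0.8,
                                  overconfidence_scale = 2, seed = 9,
                                  behaviors = bset)
  tm <- fit_temperature(g$logits, g$labels)
  grp <- rep(seq_len(80), each = 100)   # 80 clips of 100 frames
  acc_clip <- as.numeric(tapply(g$pred == g$labels, grp, mean))
  msd_sm <- calibration_errors(
    as.numeric(tapply(softmax_confidence(g$logits), grp, mean)), acc_clip)$MSD
  msd_ts <- calibration_errors(
    as.numeric(tapply(scaled_confidence(g$logits, tm$T), grp, mean)),
    acc_clip)$MSD
  expect_lt(abs(msd_ts), abs(msd_sm))
})
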