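# Independent brute-force oracles used throughout: naive loops over frames.
oracle_counts <- function(pred, true, k) {
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == k && true[i] == k) tp <- tp + 1
    if (pred[i] == k && true[i] != k) fp <- fp + 1
    if (pred[i] != k && true[i] == k) fn <- fn + 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

oracle_bouts <- function(labels) {
  out <- list()
  start <- 1
  for (i in seq_along(labels)) {
    if (i == length(labels) || labels[i + 1] != labels[i]) {
      out[[length(out) + 1]] <- list(label = labels[start],
                                     length = i - start + 1)
      start <- i + 1
    }
  }
  out
}

test_that("accuracy counts correct frames", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "a", "b", "b"), c("a", "b", "b", "b")), 0.75)
  expect_equal(accuracy(c("a", "a"), c("b", "b")), 0)
  expect_error(accuracy(c("a"), c("a", "b")), "differ in length")
  expect_error(accuracy(character(0), character(0)), "non-empty")
})

test_that("precision/recall/F1 match hand computation and the oracle", {
  bset <- behavior_set(c("pos", "neg"))
  # TP = 8, FP = 2, FN = 4 for class "pos"
  true <- c(rep("pos", 12), rep("neg", 8))
  pred <- c(rep("pos", 8), rep("neg", 4), rep("pos", 2), rep("neg", 6))
  res <- per_class_prf(pred, true, bset)
  row <- res$per_class[res$per_class$class == "pos", ]
  expect_equal(unname(unlist(row[c("TP", "FP", "FN")])), c(8, 2, 4))
  expect_equal(row$precision, 0.8)
  expect_equal(row$recall, 0.6667, tolerance = 1e-4)
  expect_equal(row$F1, 0.7273, tolerance = 1e-4)
  oc <- oracle_counts(pred, true, "pos")
  expect_equal(unname(unlist(row[c("TP", "FP", "FN")])), unname(oc))

  # perfect prediction
  res <- per_class_prf(true, true, bset)
  expect_true(all(res$per_class$F1 == 1))
  expect_equal(res$F1_all, 1)

  # class absent from both: zero by convention, flagged, still averaged
  bset3 <- behavior_set(c("pos", "neg", "ghost"))
  res <- per_class_prf(pred, true, bset3)
  ghost <- res$per_class[res$per_class$class == "ghost", ]
  expect_equal(ghost$F1, 0)
  expect_true(ghost$degenerate)
  expect_equal(res$F1_all, mean(res$per_class$F1))   # mean over all K

  # randomized cross-check against oracle loops
  set.seed(20)
  for (i in 1:5) {
    p <- sample(bset3$labels, 60, TRUE)
    t <- sample(bset3$labels, 60, TRUE)
    res <- per_class_prf(p, t, bset3)
    for (k in bset3$labels) {
      oc <- oracle_counts(p, t, k)
      row <- res$per_class[res$per_class$class == k, ]
      expect_equal(unname(unlist(row[c("TP", "FP", "FN")])), unname(oc))
    }
    # micro-averaged recall equals accuracy for mutually exclusive labels
    expect_equal(sum(res$per_class$TP) / 60, accuracy(p, t))
  }
})

test_that("confusion matrices normalize by true class", {
  bset <- behavior_set(c("a", "b", "c"))
  true <- c("a", "a", "b", "b", "c")
  cm <- confusion_matrix(true, true, bset)
  expect_equal(unname(cm), diag(3))

  set.seed(4)
  p <- sample(bset$labels, 50, TRUE)
  t <- sample(bset$labels, 50, TRUE)
  cmn <- confusion_matrix(p, t, bset)
  expect_equal(unname(rowSums(cmn)), rep(1, 3))
  cmr <- confusion_matrix(p, t, bset, normalize = "none")
  expect_equal(sum(cmr), 50)
})

test_that("bout tables are maximal runs matching a brute-force scan", {
  bt <- bout_lengths(c("a", "a", "a"))
  expect_equal(bt$bouts$length, 3L)
  bt <- bout_lengths(c("a", "a", "b", "a"))
  expect_equal(bt$bouts$label, c("a", "b", "a"))
  expect_equal(bt$bouts$length, c(2L, 1L, 1L))
  expect_equal(sum(bt$bouts$length), 4L)

  set.seed(9)
  for (i in 1:5) {
    labs <- sample(c("x", "y", "z"), 40, TRUE)
    bt <- bout_lengths(labs)
    ob <- oracle_bouts(labs)
    expect_equal(nrow(bt$bouts), length(ob))
    expect_equal(bt$bouts$length,
                 vapply(ob, function(b) as.integer(b$length), integer(1)))
    expect_equal(bt$bouts$label,
                 vapply(ob, function(b) b$label, character(1)))
    expect_equal(sum(bt$bouts$length), length(labs))
    expect_true(all(bt$bouts$length >= 1))
  }
})

test_that("inter-observer agreement is symmetric frame-wise accuracy", {
  a <- c(rep("w", 7), rep("r", 3))
  b <- c(rep("w", 4), rep("r", 6))
  expect_equal(agreement(a, a), 1)
  expect_equal(agreement(a, b), 0.7)
  expect_equal(agreement(a, b), agreement(b, a))
  expect_equal(agreement(a, b), accuracy(a, b))
  expect_error(agreement(a, b[1:5]), "different frame sets")
})
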