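test_that("accuracy after review corrects reviewed clips to 1", {
  acc <- c(0.5, 0.9)
  sizes <- c(100, 100)
  expect_equal(accuracy_after_review(acc, sizes, k = 0), 0.7)
  expect_equal(accuracy_after_review(acc, sizes, k = 2), 1)
  # worst-first vs best-first at k = 1
  expect_equal(accuracy_after_review(acc, sizes, c(1, 2), 1), 0.95)
  expect_equal(accuracy_after_review(acc, sizes, c(2, 1), 1), 0.75)
  # frame weighting
  expect_equal(accuracy_after_review(c(0.5, 1), c(300, 100), c(1, 2), 1), 1)
  expect_error(accuracy_after_review(acc, sizes, k = 3), "k")
  expect_error(accuracy_after_review(acc, sizes, c(1, 1), 1), "permutation")
})

test_that("random baseline matches exhaustive enumeration and closed form", {
  acc <- c(0.5, 0.9)
  sizes <- c(50, 50)
  rc <- random_review_curve(acc, sizes)
  expect_true(rc$exhaustive)
  expect_equal(rc$acc_k, c(0.7, 0.85, 1))   # mean of 0.95 and 0.75 at k = 1

  # equal-size clips: E[acc_k] = acc0 + (k/n)(1 - acc0)
  set.seed(3)
  acc <- runif(9)
  sizes <- rep(120, 9)
  rc <- random_review_curve(acc, sizes, n_permutations = 200, seed = 4)
  expect_false(rc$exhaustive)
  a0 <- mean(acc)
  expected <- a0 + (0:9) / 9 * (1 - a0)
  expect_true(all(abs(rc$acc_k - expected) <= 3 * rc$se_k + 1e-12))
  # endpoints are exact for every ordering
  expect_equal(rc$acc_k[1], a0)
  expect_equal(rc$acc_k[10], 1)
})

test_that("IOR series and review efficiency behave as defined", {
  acc <- c(0.5, 0.9)
  sizes <- c(50, 50)
  rand <- random_review_curve(acc, sizes)
  opt <- review_curve(acc, sizes, optimal_ordering(acc), "optimal")
  ior_opt <- improvement_over_random(opt, rand)
  expect_equal(ior_opt$IOR_k, c(0, 0.1, 0))   # 0.95 - 0.85 at k = 1
  expect_equal(ior_opt$mean_IOR, 0.1 / 2)     # (n+1)-term sum over n

  ior_rand <- improvement_over_random(rand, rand)
  expect_true(all(ior_rand$IOR_k == 0))

  expect_equal(review_efficiency(ior_opt$mean_IOR, ior_opt$mean_IOR), 1)
  # anti-sorted (best first) is worse than random
  anti <- review_curve(acc, sizes, rev(optimal_ordering(acc)), "anti")
  ior_anti <- improvement_over_random(anti, rand)
  expect_lt(review_efficiency(ior_anti$mean_IOR, ior_opt$mean_IOR), 0)
  # undefined when no ordering can beat random
  eff <- review_efficiency(0.0, 0.0)
  expect_true(is.na(eff))
  expect_true(attr(eff, "undefined"))
})

test_that("review curves are monotone, bounded, and dominated by the optimal order", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 5
    acc <- runif(n)
    # monotonicity and endpoints hold for any clip sizes
    sizes <- sample(50:150, n, TRUE)
    a0 <- sum(acc * sizes) / sum(sizes)
    for (p in ethocoder:::all_permutations(n)) {
      cv <- review_curve(acc, sizes, unlist(p))
      expect_true(all(diff(cv$acc_k) >= -1e-12))        # non-decreasing
      expect_true(all(cv$acc_k >= a0 - 1e-12 & cv$acc_k <= 1 + 1e-12))
      expect_equal(cv$acc_k[1], a0)
      expect_equal(cv$acc_k[n + 1], 1)
    }
    # the ascending-accuracy ordering dominates every ordering at every k
    # when clips weigh equally (the review gain of a clip is (1 - acc) * size,
    # so with unequal sizes the accuracy order need not be the optimum)
    sizes_eq <- rep(100, n)
    opt_curve <- review_curve(acc, sizes_eq, optimal_ordering(acc), "optimal")
    for (p in ethocoder:::all_permutations(n)) {
      cv <- review_curve(acc, sizes_eq, unlist(p))
      expect_true(all(opt_curve$acc_k >= cv$acc_k - 1e-12))  # dominance
    }
  }
})

test_that("informative confidence orders review better than shuffled scores", {
  set.seed(6)
  n <- 12
  acc <- runif(n, 0.3, 0.95)
  sizes <- rep(100, n)
  conf <- pmin(pmax(acc + rnorm(n, sd = 0.05), 0), 1)  # well-calibrated
  shuffled <- sample(conf)
  rs_good <- evaluate_review(conf, acc, sizes, n_permutations = 200, seed = 7)
  rs_bad <- evaluate_review(shuffled, acc, sizes, n_permutations = 200,
                            seed = 7)
  expect_gte(as.numeric(rs_good$efficiency), as.numeric(rs_bad$efficiency))
  expect_gt(as.numeric(rs_good$efficiency), 0.8)
})
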