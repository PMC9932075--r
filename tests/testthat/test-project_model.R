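test_that("clip splitting tiles videos exactly with the remainder kept", {
  v <- video_record("v1", n_frames = 100, fps = 1)
  cl <- split_video_into_clips(v, 100)
  expect_length(cl, 1L)
  expect_equal(c(cl[[1]]$start, cl[[1]]$end), c(0L, 100L))

  v <- video_record("v2", n_frames = 250, fps = 1)
  cl <- split_video_into_clips(v, 100)
  expect_equal(vapply(cl, `[[`, integer(1), "start"), c(0L, 100L, 200L))
  expect_equal(vapply(cl, `[[`, integer(1), "end"), c(100L, 200L, 250L))

  # default clip length is one minute
  v <- video_record("v3", n_frames = 1800, fps = 10)
  cl <- split_video_into_clips(v)
  expect_equal(cl[[1]]$size, 600L)

  # randomized tiling property
  set.seed(11)
  for (i in 1:20) {
    nf <- sample(5:500, 1)
    fps <- sample(c(1, 2, 5, 12.5, 30), 1)
    secs <- runif(1, 0.5, 40)
    v <- video_record("r", nf, fps)
    cl <- split_video_into_clips(v, secs)
    starts <- vapply(cl, `[[`, integer(1), "start")
    ends <- vapply(cl, `[[`, integer(1), "end")
    expect_equal(starts[1], 0L)
    expect_equal(ends[length(ends)], nf)
    if (length(cl) > 1) expect_equal(starts[-1], ends[-length(ends)])
    expect_true(all(ends > starts))
  }

  expect_error(split_video_into_clips(v, 0), "clip_seconds")
})

test_that("labeled-clip selection sizes follow round-half-away with floor 1", {
  v <- video_record("v", 1000, fps = 1)
  clips <- split_video_into_clips(v, 100)  # 10 clips
  s <- select_labeled_clips(clips, 0.2, seed = 1)
  expect_length(s$D_labeled, 2L)
  s <- select_labeled_clips(clips, 0.25, seed = 1)
  expect_length(s$D_labeled, 3L)   # 2.5 rounds away from zero
  s <- select_labeled_clips(clips, 0.01, seed = 1)
  expect_length(s$D_labeled, 1L)   # never empty

  s1 <- select_labeled_clips(clips, 0.3, seed = 99)
  s2 <- select_labeled_clips(clips, 0.3, seed = 99)
  expect_identical(s1$D_labeled, s2$D_labeled)

  # partition validity
  expect_length(intersect(s1$D_labeled, s1$D_unlabeled), 0L)
  expect_setequal(c(s1$D_labeled, s1$D_unlabeled),
                  vapply(clips, `[[`, character(1), "clip_id"))

  expect_error(select_labeled_clips(clips[1], 0.5, 1), "at least 2")
  expect_error(select_labeled_clips(clips, 1.2, 1), "prop_labeled")
})

test_that("train/validate split holds out 20 percent by default", {
  ids <- sprintf("c%02d", 1:10)
  tv <- split_train_validate(ids, seed = 3)
  expect_length(tv$D_validate, 2L)
  expect_length(tv$D_train, 8L)
  expect_setequal(c(tv$D_train, tv$D_validate), ids)
  expect_length(intersect(tv$D_train, tv$D_validate), 0L)

  tv <- split_train_validate(ids[1:2], 0.2, seed = 1)
  expect_length(tv$D_validate, 1L)
  expect_length(tv$D_train, 1L)

  expect_error(split_train_validate(ids[1], 0.2, 1), "at least 2")
})

test_that("k-fold partitions are near-equal and cover every clip once", {
  ids <- sprintf("c%02d", 1:12)
  folds <- kfold_clips(ids, 12, seed = 5)
  expect_length(folds, 12L)
  expect_true(all(vapply(folds, function(f) length(f$test_ids), integer(1)) == 1L))

  folds <- kfold_clips(sprintf("c%02d", 1:10), 2, seed = 5)
  sizes <- vapply(folds, function(f) length(f$test_ids), integer(1))
  expect_equal(sizes, c(5L, 5L))

  folds <- kfold_clips(ids, 5, seed = 2)
  test_all <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(test_all, ids)
  expect_equal(length(test_all), length(ids))   # each clip in exactly one fold
  sizes <- vapply(folds, function(f) length(f$test_ids), integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) expect_setequal(c(f$train_ids, f$test_ids), ids)

  expect_error(kfold_clips(ids, 13, 1), "exceeds")
})

test_that("the labeled-proportion sweep is the standard 24-value grid", {
  g <- prop_labeled_grid()
  expect_length(g, 24L)
  expect_equal(g[1], 0.02)
  expect_equal(g[10], 0.20)
  expect_equal(g[11], 0.25)
  expect_equal(g[24], 0.90)
  expect_true(all(diff(g) > 0))
})

test_that("bout and per-frame annotation representations round-trip", {
  labs <- c("a", "a", "b", "a", "a", "a", "c")
  b <- labels_to_bouts(labs, "v1", offset = 10L)
  expect_equal(b$start_frame, c(10L, 12L, 13L, 16L))
  expect_equal(b$end_frame, c(12L, 13L, 16L, 17L))
  expect_equal(bouts_to_labels(b), labs)

  tmp <- tempfile(fileext = ".csv")
  write_annotation_csv(b, tmp)
  expect_equal(bouts_to_labels(read_annotation_csv(tmp)), labs)

  # per-frame CSV round trip via attach_labels
  bset <- behavior_set(c("a", "b", "c"))
  v <- video_record("v1", 7, fps = 1)
  clips <- split_video_into_clips(v, 4)
  df <- data.frame(video_id = "v1", frame = 0:6, label = labs)
  clips <- attach_labels(clips, df, bset)
  expect_equal(clips[[1]]$labels, labs[1:4])
  expect_equal(clips[[2]]$labels, labs[5:7])
  expect_error(attach_labels(clips, transform(df, label = "zz"), bset),
               "not in the behavior set")
})

test_that("behavior sets enforce unique labels and a valid background", {
  expect_error(behavior_set(character(0)), "non-empty")
  expect_error(behavior_set(c("a", "a")), "unique")
  expect_error(behavior_set(c("a", "b"), background = "c"), "background")
  b <- behavior_set(c("rest", "walk", "other"), background = "other")
  expect_equal(b$K, 3L)
})
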