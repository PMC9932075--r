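# Project data model: behavior sets, videos, clips, annotation tables and
# the labeled/unlabeled/train/validate/test splitting machinery.
#
# Conventions used throughout the package:
#   * frame coordinates are 0-based, half-open [start, end)
#   * clips of one video are disjoint and tile it exactly
#   * all splits are reproducible from an integer seed

#' Define the set of mutually exclusive behavior classes
#'
#' @param labels Character vector of unique behavior names, in a fixed order.
#' @param background Optional single label (member of `labels`) flagged as the
#'   catch-all "other/background" class.
#' @return An object of class `behavior_set` with elements `labels`, `K` and
#'   `background`.
#' @examples
#' behavior_set(c("rest", "walk", "groom"))
#' @export
behavior_set <- function(labels, background = NULL) {
  if (!is.character(labels) || length(labels) == 0L || anyNA(labels))
    abort_invalid("`labels` must be a non-empty character vector")
  if (anyDuplicated(labels))
    abort_invalid("behavior labels must be unique")
  if (!is.null(background)) {
    if (length(background) != 1L || !background %in% labels)
      abort_invalid("`background` must be one of `labels`")
  }
  structure(
    list(labels = labels, K = length(labels), background = background),
    class = "behavior_set"
  )
}

#' @export
print.behavior_set <- function(x, ...) {
  cat("<behavior_set> K =", x$K, ":", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Describe one (possibly multi-camera) video
#'
#' Synchronized camera streams of a single video share `n_frames` and `fps`.
#'
#' @param video_id Character identifier.
#' @param n_frames Total frame count (>= 1).
#' @param fps Frames per second (> 0).
#' @param cameras Number of synchronized camera views (>= 1).
#' @return An object of class `video_record`.
#' @export
video_record <- function(video_id, n_frames, fps, cameras = 1L) {
  if (!is.character(video_id) || length(video_id) != 1L || !nzchar(video_id))
    abort_invalid("`video_id` must be a non-empty string")
  check_scalar_number(n_frames, "n_frames", lower = 1)
  check_scalar_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_scalar_number(cameras, "cameras", lower = 1)
  structure(
    list(video_id = video_id, n_frames = as.integer(n_frames), fps = fps,
         cameras = as.integer(cameras)),
    class = "video_record"
  )
}

new_clip_record <- function(clip_id, video_id, start, end, labels = NULL) {
  if (start < 0 || end <= start)
    abort_invalid("clip frame range [%d, %d) is invalid", start, end)
  if (!is.null(labels) && length(labels) != end - start)
    abort_invalid("clip `%s`: %d labels for %d frames", clip_id,
                  length(labels), end - start)
  structure(
    list(clip_id = clip_id, video_id = video_id, start = as.integer(start),
         end = as.integer(end), size = as.integer(end - start),
         labels = labels),
    class = "clip_record"
  )
}

#' @export
print.clip_record <- function(x, ...) {
  cat(sprintf("<clip_record> %s: video %s frames [%d, %d)%s\n", x$clip_id,
              x$video_id, x$start, x$end,
              if (is.null(x$labels)) "" else " (labeled)"))
  invisible(x)
}

#' Divide a video into fixed-length clips
#'
#' Clips tile the frame range `[0, n_frames)` in order. Every clip holds
#' `round(clip_seconds * fps)` frames except possibly the last, which keeps
#' the remainder (it is retained whenever it has at least one frame, so the
#' clips always tile the video exactly).
#'
#' @param video A [video_record()].
#' @param clip_seconds Clip duration in seconds (> 0); default 60.
#' @return List of `clip_record` objects.
#' @examples
#' v <- video_record("v1", n_frames = 250, fps = 1)
#' length(split_video_into_clips(v, 100)) # 3 clips: 100, 100, 50 frames
#' @export
split_video_into_clips <- function(video, clip_seconds = 60) {
  stopifnot(inherits(video, "video_record"))
  check_scalar_number(clip_seconds, "clip_seconds", lower = 0,
                      strict_lower = TRUE)
  if (video$n_frames < 1L)
    abort_invalid("video has no frames")
  len <- max(1L, as.integer(round_half_up(clip_seconds * video$fps)))
  starts <- seq.int(0L, video$n_frames - 1L, by = len)
  ends <- pmin(starts + len, video$n_frames)
  lapply(seq_along(starts), function(i) {
    new_clip_record(
      clip_id = sprintf("%s_clip%04d", video$video_id, i),
      video_id = video$video_id, start = starts[i], end = ends[i]
    )
  })
}

clip_ids <- function(clips) vapply(clips, `[[`, character(1), "clip_id")
clip_sizes <- function(clips) vapply(clips, `[[`, integer(1), "size")

#' Select which clips are (simulated to be) manually labeled
#'
#' Draws `max(1, round(prop_labeled * N))` clip ids uniformly without
#' replacement (half counts round away from zero). The complement forms the
#' unlabeled pool, which doubles as the test set when simulating partial
#' annotation of a fully labeled dataset.
#'
#' @param clips List of `clip_record`s (length >= 2).
#' @param prop_labeled Fraction of clips in (0, 1) to treat as labeled.
#' @param seed Integer seed; identical seeds give identical selections.
#' @return A `data_split` list with `D_labeled`, `D_unlabeled` (clip-id
#'   character vectors), `prop_labeled` and `seed`.
#' @export
select_labeled_clips <- function(clips, prop_labeled, seed) {
  check_scalar_number(prop_labeled, "prop_labeled", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  ids <- clip_ids(clips)
  n <- length(ids)
  if (n < 2L)
    abort_invalid("need at least 2 clips to form a labeled/unlabeled split")
  n_lab <- max(1L, as.integer(round_half_up(prop_labeled * n)))
  lab <- with_substream(seed, "select_labeled",
                        sort(sample.int(n, n_lab)))
  structure(
    list(D_labeled = ids[lab], D_unlabeled = ids[-lab],
         prop_labeled = prop_labeled, seed = seed),
    class = "data_split"
  )
}

#' Split the labeled clips into training and validation sets
#'
#' `max(1, round(prop_validate * |D_labeled|))` clips are held out for
#' validation (used for early stopping and temperature fitting); the rest
#' train the classifier. Default holds out 20 percent.
#'
#' @param D_labeled Character vector of labeled clip ids (length >= 2).
#' @param prop_validate Validation fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with `D_train` and `D_validate` (disjoint, exhaustive).
#' @export
split_train_validate <- function(D_labeled, prop_validate = 0.2, seed = 0L) {
  check_scalar_number(prop_validate, "prop_validate", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  n <- length(D_labeled)
  if (n < 2L)
    abort_invalid("need at least 2 labeled clips to split train/validate")
  n_val <- min(n - 1L, max(1L, as.integer(round_half_up(prop_validate * n))))
  val <- with_substream(seed, "train_validate",
                        sort(sample.int(n, n_val)))
  list(D_train = D_labeled[-val], D_validate = D_labeled[val])
}

#' Random k-fold partition of clips
#'
#' Clips are shuffled once and dealt into `k` folds whose sizes differ by at
#' most one; each clip lands in exactly one test fold.
#'
#' @param clips List of `clip_record`s or a character vector of clip ids.
#' @param k Number of folds, `2 <= k <= N`.
#' @param seed Integer seed.
#' @return List of `k` lists, each with `train_ids` and `test_ids`.
#' @export
kfold_clips <- function(clips, k, seed = 0L) {
  ids <- if (is.character(clips)) clips else clip_ids(clips)
  n <- length(ids)
  check_scalar_number(k, "k", lower = 2)
  if (k > n)
    abort_invalid("k = %d exceeds the number of clips (%d)", k, n)
  perm <- with_substream(seed, "kfold", sample.int(n))
  # deal shuffled clips round-robin: fold sizes differ by at most one
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) {
    list(train_ids = ids[fold_of != f], test_ids = ids[fold_of == f])
  })
}

#' The standard sweep of labeled-data proportions
#'
#' A fine grid (step 0.02) up to 0.20, where accuracy changes fastest with
#' added annotation, then a coarser grid (step 0.05) up to 0.90: 24 values.
#'
#' @return Numeric vector of length 24: 0.02, 0.04, ..., 0.20, 0.25, ..., 0.90.
#' @export
prop_labeled_grid <- function() {
  c(seq(0.02, 0.20, by = 0.02), seq(0.25, 0.90, by = 0.05))
}

# ---- Annotation tables -----------------------------------------------------

#' Convert per-frame labels to bout intervals
#'
#' A bout is a maximal run of consecutive frames sharing one label. Intervals
#' are 0-based and half-open.
#'
#' @param labels Character vector of per-frame labels.
#' @param video_id Video identifier stored in the output.
#' @param offset Frame index of `labels[1]` within the video.
#' @return data.frame with columns `video_id`, `start_frame`, `end_frame`,
#'   `label`.
#' @export
labels_to_bouts <- function(labels, video_id = "video", offset = 0L) {
  if (length(labels) == 0L)
    abort_invalid("`labels` must be non-empty")
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(video_id = video_id, start_frame = starts + offset,
             end_frame = ends + offset, label = r$values,
             stringsAsFactors = FALSE)
}

#' Convert bout intervals back to per-frame labels
#'
#' @param bouts data.frame as produced by [labels_to_bouts()]; intervals must
#'   tile a contiguous half-open frame range.
#' @return Character vector of per-frame labels.
#' @export
bouts_to_labels <- function(bouts) {
  bouts <- bouts[order(bouts$start_frame), , drop = FALSE]
  if (any(bouts$end_frame <= bouts$start_frame))
    abort_invalid("bout intervals must be non-empty and half-open")
  if (nrow(bouts) > 1L &&
      any(bouts$start_frame[-1L] != bouts$end_frame[-nrow(bouts)]))
    abort_invalid("bout intervals must tile the frame range without gaps")
  rep(bouts$label, bouts$end_frame - bouts$start_frame)
}

#' Read / write per-frame annotation CSVs
#'
#' Per-frame files have columns `video_id`, `frame` (0-based), `label`;
#' bout files have `video_id`, `start_frame`, `end_frame` (half-open),
#' `label`.
#'
#' @param path CSV file path.
#' @return `read_annotation_csv()` returns a data.frame.
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_frame <- c("video_id", "frame", "label")
  need_bout <- c("video_id", "start_frame", "end_frame", "label")
  if (all(need_frame %in% names(df)) || all(need_bout %in% names(df)))
    return(df)
  abort_invalid("`%s` is neither a per-frame nor a bout annotation CSV", path)
}

#' @param df Annotation data.frame (either schema).
#' @rdname read_annotation_csv
#' @export
write_annotation_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach per-frame labels from an annotation table to clips
#'
#' @param clips List of `clip_record`s.
#' @param frames_df Per-frame annotation data.frame (`video_id`, `frame`,
#'   `label`).
#' @param behaviors A [behavior_set()]; labels outside it are an error.
#' @return The clips, with `labels` filled in where fully covered.
#' @export
attach_labels <- function(clips, frames_df, behaviors) {
  stopifnot(inherits(behaviors, "behavior_set"))
  bad <- setdiff(unique(frames_df$label), behaviors$labels)
  if (length(bad))
    abort_invalid("labels not in the behavior set: %s",
                  paste(bad, collapse = ", "))
  lapply(clips, function(cl) {
    sel <- frames_df$video_id == cl$video_id &
      frames_df$frame >= cl$start & frames_df$frame < cl$end
    sub <- frames_df[sel, , drop = FALSE]
    if (nrow(sub) == 0L) return(cl)
    if (nrow(sub) != cl$size)
      abort_invalid("clip `%s`: annotations cover %d of %d frames",
                    cl$clip_id, nrow(sub), cl$size)
    cl$labels <- sub$label[order(sub$frame)]
    cl
  })
}
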