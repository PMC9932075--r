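# Frame-wise classifier evaluation: accuracy, per-class precision/recall/F1,
# confusion matrices, bout-length tables and inter-observer agreement.

check_label_pair <- function(pred, true) {
  if (length(pred) == 0L)
    abort_invalid("label vectors must be non-empty")
  if (length(pred) != length(true))
    abort_invalid("predicted (%d) and true (%d) label vectors differ in length",
                  length(pred), length(true))
}

#' Overall frame-wise accuracy
#'
#' The fraction of frames whose predicted label equals the true label,
#' `correct / (correct + incorrect)`.
#'
#' @param pred,true Equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(pred, true) {
  check_label_pair(pred, true)
  mean(as.character(pred) == as.character(true))
}

#' Per-class precision, recall and F1
#'
#' For class k: `precision_k = TP_k / (TP_k + FP_k)`,
#' `recall_k = TP_k / (TP_k + FN_k)`, and F1 their harmonic mean. The macro
#' score `F1_all` is the unweighted mean of `F1_k` over all K classes of the
#' behavior set, including classes absent from both vectors; a class with a
#' zero denominator scores 0 and is flagged `degenerate`.
#'
#' @param pred,true Equal-length label vectors.
#' @param behaviors A [behavior_set()] fixing the class list K.
#' @return List with a per-class data.frame (`class`, `TP`, `FP`, `FN`, `TN`,
#'   `precision`, `recall`, `F1`, `degenerate`) and the scalar `F1_all`.
#' @export
per_class_prf <- function(pred, true, behaviors) {
  check_label_pair(pred, true)
  stopifnot(inherits(behaviors, "behavior_set"))
  pred <- as.character(pred); true <- as.character(true)
  bad <- setdiff(unique(c(pred, true)), behaviors$labels)
  if (length(bad))
    abort_invalid("labels not in the behavior set: %s",
                  paste(bad, collapse = ", "))
  n <- length(pred)
  rows <- lapply(behaviors$labels, function(k) {
    tp <- sum(pred == k & true == k)
    fp <- sum(pred == k & true != k)
    fn <- sum(pred != k & true == k)
    tn <- n - tp - fp - fn
    degenerate <- (tp + fp == 0L) || (tp + fn == 0L)
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(class = k, TP = tp, FP = fp, FN = fn, TN = tn,
               precision = precision, recall = recall, F1 = f1,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, F1_all = mean(per_class$F1))
}

#' Confusion matrix over the behavior set
#'
#' Rows are true classes, columns predicted classes. With
#' `normalize = "true-class"` each row with at least one true frame is
#' rescaled to sum to one; `normalize = "none"` returns raw counts.
#'
#' @param pred,true Equal-length label vectors.
#' @param behaviors A [behavior_set()].
#' @param normalize `"true-class"` (default) or `"none"`.
#' @return A `K x K` numeric matrix with dimnames.
#' @export
confusion_matrix <- function(pred, true, behaviors,
                             normalize = c("true-class", "none")) {
  check_label_pair(pred, true)
  stopifnot(inherits(behaviors, "behavior_set"))
  normalize <- match.arg(normalize)
  lv <- behaviors$labels
  m <- table(factor(as.character(true), levels = lv),
             factor(as.character(pred), levels = lv))
  m <- matrix(as.numeric(m), nrow = length(lv),
              dimnames = list(true = lv, pred = lv))
  if (normalize == "true-class") {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  m
}

#' Bout (run-length) table of a label sequence
#'
#' A bout is a maximal run of consecutive frames with one label. Bouts are
#' returned in temporal order together with per-behavior length lists.
#'
#' @param labels Non-empty label vector.
#' @return List of class `bout_table`: `bouts` (data.frame `label`, `start`,
#'   `length`, half-open 0-based) and `by_behavior` (named list of length
#'   vectors).
#' @export
bout_lengths <- function(labels) {
  if (length(labels) == 0L)
    abort_invalid("`labels` must be non-empty")
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  bouts <- data.frame(label = r$values, start = ends - r$lengths,
                      length = r$lengths, stringsAsFactors = FALSE)
  structure(
    list(bouts = bouts,
         by_behavior = split(bouts$length, bouts$label),
         n_frames = length(labels)),
    class = "bout_table"
  )
}

#' Frame-wise agreement between two annotation tracks
#'
#' The inter-observer reliability measure: the fraction of frames on which
#' two independent annotations agree. Symmetric, and numerically identical
#' to [accuracy()] with either track as reference.
#'
#' @param annotations_1,annotations_2 Equal-length label vectors covering the
#'   same frames.
#' @return A number in `[0, 1]`.
#' @export
agreement <- function(annotations_1, annotations_2) {
  if (length(annotations_1) != length(annotations_2))
    abort_invalid("annotation tracks cover different frame sets")
  accuracy(annotations_1, annotations_2)
}
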