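# Confidence scoring: per-frame max-softmax and temperature-scaled scores,
# clip- and dataset-level aggregation, and calibration error metrics.

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

as_logit_matrix <- function(logits) {
  logits <- as.matrix(logits)
  if (ncol(logits) < 2L)
    abort_invalid("logits must have K >= 2 columns")
  if (!all(is.finite(logits)))
    abort_invalid("logits must be finite")
  logits
}

#' Max-softmax frame confidence
#'
#' For each frame j with logits z_j, the confidence is the largest softmax
#' probability, `max_k softmax(z_j)_k` -- an estimate of the probability that
#' the predicted label is correct. Values lie in `[1/K, 1]`.
#'
#' @param logits `n x K` matrix of per-frame logits.
#' @return Numeric vector of length n.
#' @export
softmax_confidence <- function(logits) {
  logits <- as_logit_matrix(logits)
  apply(softmax_rows(logits), 1L, max)
}

#' Temperature-scaled frame confidence
#'
#' Divides logits by a scalar temperature T before the softmax:
#' `max_k softmax(z_j / T)_k`. T > 1 softens (decreases) confidence, T < 1
#' sharpens it; the argmax label is unchanged for any T > 0.
#'
#' @param logits `n x K` matrix of per-frame logits.
#' @param T Temperature (> 0), typically from [fit_temperature()].
#' @return Numeric vector of length n.
#' @export
scaled_confidence <- function(logits, T) {
  check_scalar_number(T, "T", lower = 0, strict_lower = TRUE)
  softmax_confidence(as_logit_matrix(logits) / T)
}

nll_at_temperature <- function(logits, label_idx, T) {
  p <- softmax_rows(logits / T)
  -mean(log(pmax(p[cbind(seq_along(label_idx), label_idx)], 1e-300)))
}

#' Fit a calibration temperature on validation data
#'
#' Selects T > 0 minimizing the negative log likelihood of the validation
#' labels under `softmax(z / T)`, by deterministic 1-D minimization of NLL
#' over `log T` in `[log 0.05, log 20]`.
#'
#' @param logits `n x K` validation logit matrix.
#' @param labels Validation labels: integer class indices (1-based) or
#'   characters resolved against `behaviors`.
#' @param behaviors Optional [behavior_set()] used to map character labels to
#'   column indices.
#' @return Object of class `temperature_model`: `T`, `nll` (at T), `nll_1`
#'   (at T = 1), `n`.
#' @export
fit_temperature <- function(logits, labels, behaviors = NULL) {
  logits <- as_logit_matrix(logits)
  label_idx <- resolve_label_index(labels, ncol(logits), behaviors)
  if (length(label_idx) != nrow(logits))
    abort_invalid("got %d labels for %d logit rows", length(label_idx),
                  nrow(logits))
  if (length(unique(label_idx)) < 2L)
    abort_invalid("temperature fitting needs >= 2 classes present in the validation labels")
  opt <- stats::optimize(
    function(logT) nll_at_temperature(logits, label_idx, exp(logT)),
    lower = log(0.05), upper = log(20), tol = 1e-7
  )
  T_hat <- exp(opt$minimum)
  nll1 <- nll_at_temperature(logits, label_idx, 1)
  if (opt$objective > nll1) {    # optimum is (numerically) at T = 1
    T_hat <- 1
    opt$objective <- nll1
  }
  structure(
    list(T = T_hat, nll = opt$objective, nll_1 = nll1, n = nrow(logits)),
    class = "temperature_model"
  )
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf("<temperature_model> T = %.4f (NLL %.4f vs %.4f at T=1, n=%d)\n",
              x$T, x$nll, x$nll_1, x$n))
  invisible(x)
}

resolve_label_index <- function(labels, K, behaviors = NULL) {
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
    if (any(idx < 1L | idx > K))
      abort_invalid("label indices must lie in 1..K")
    return(idx)
  }
  if (is.null(behaviors))
    abort_invalid("character labels need a `behaviors` set to resolve indices")
  idx <- match(as.character(labels), behaviors$labels)
  if (anyNA(idx))
    abort_invalid("labels not in the behavior set")
  idx
}

#' Clip-level confidence: mean frame confidence
#'
#' @param frame_conf Numeric vector of frame confidences for one clip.
#' @return Their arithmetic mean.
#' @export
clip_confidence <- function(frame_conf) {
  if (length(frame_conf) == 0L)
    abort_invalid("clip has no frames")
  mean(frame_conf)
}

#' Clip-level accuracy: fraction of correctly labeled frames
#'
#' @param pred,true Equal-length per-frame label vectors for one clip.
#' @return A number in `[0, 1]`.
#' @export
clip_accuracy <- function(pred, true) {
  if (anyNA(pred) || anyNA(true))
    abort_invalid("clip accuracy needs labels for every frame")
  accuracy(pred, true)
}

#' Frame-weighted dataset confidence (or accuracy)
#'
#' Aggregates clip scores to a dataset score, weighting each clip by its
#' frame count: `sum_i conf(clip_i) * |clip_i| / sum_j |clip_j|`. Used with
#' clip accuracies, the identical formula gives dataset accuracy.
#'
#' @param clip_scores Per-clip confidences (or accuracies).
#' @param clip_sizes Per-clip frame counts.
#' @return The weighted mean.
#' @export
dataset_confidence <- function(clip_scores, clip_sizes) {
  if (length(clip_scores) == 0L)
    abort_invalid("need at least one clip")
  if (length(clip_scores) != length(clip_sizes))
    abort_invalid("scores and sizes differ in length")
  sum(clip_scores * clip_sizes) / sum(clip_sizes)
}

#' Clip-level calibration errors
#'
#' Per clip, the prediction error `PE = conf - acc` (positive means
#' overconfident) and absolute error `AE = |PE|`; aggregated as the mean
#' absolute error `MAE = mean(AE)` and mean signed difference
#' `MSD = mean(PE)` -- both unweighted means over clips.
#'
#' @param conf Per-clip confidences.
#' @param acc Per-clip accuracies (same order).
#' @param sizes Optional per-clip frame counts, stored for reporting.
#' @param T Optional fitted temperature, stored for reporting.
#' @return Object of class `calibration_report`: per-clip data.frame
#'   (`conf`, `acc`, `PE`, `AE`, `size`) plus `MAE`, `MSD` and `T`.
#' @export
calibration_errors <- function(conf, acc, sizes = NULL, T = NULL) {
  if (length(conf) != length(acc))
    abort_invalid("`conf` (%d) and `acc` (%d) differ in length",
                  length(conf), length(acc))
  pe <- conf - acc
  clips <- data.frame(conf = conf, acc = acc, PE = pe, AE = abs(pe))
  clips$size <- if (is.null(sizes)) NA_integer_ else sizes
  structure(
    list(clips = clips, MAE = mean(abs(pe)), MSD = mean(pe), T = T),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d clips: MAE = %.4f, MSD = %+.4f%s\n",
              nrow(x$clips), x$MAE, x$MSD,
              if (is.null(x$T)) "" else sprintf(", T = %.3f", x$T)))
  invisible(x)
}
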