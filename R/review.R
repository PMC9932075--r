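# Confidence-based review simulation: accuracy after reviewing the first k
# clips of an ordering, random baselines, improvement over random (IOR) and
# the review-efficiency summary.

check_review_clips <- function(acc, sizes) {
  if (length(acc) == 0L)
    abort_invalid("need at least one clip")
  if (length(acc) != length(sizes))
    abort_invalid("`acc` and `sizes` differ in length")
  if (any(acc < 0 | acc > 1))
    abort_invalid("clip accuracies must lie in [0, 1]")
  if (any(sizes <= 0))
    abort_invalid("clip sizes must be positive")
}

#' Dataset accuracy after reviewing the first k clips of an ordering
#'
#' Reviewed clips are corrected to accuracy 1; unreviewed clips keep their
#' accuracy; the dataset score is the frame-weighted combination
#' `|D_rev|/|D| + acc(D_unrev) * |D_unrev|/|D|` (frame counts, not clip
#' counts).
#'
#' @param acc Per-clip accuracies.
#' @param sizes Per-clip frame counts.
#' @param ordering Permutation of clip indices giving the review order.
#' @param k Number of clips reviewed, `0 <= k <= n`.
#' @return The dataset accuracy after review.
#' @export
accuracy_after_review <- function(acc, sizes, ordering = seq_along(acc), k) {
  check_review_clips(acc, sizes)
  n <- length(acc)
  if (length(ordering) != n || !setequal(ordering, seq_len(n)))
    abort_invalid("`ordering` must be a permutation of 1..n")
  check_scalar_number(k, "k", lower = 0, upper = n)
  reviewed <- ordering[seq_len(k)]
  acc2 <- acc
  acc2[reviewed] <- 1
  sum(acc2 * sizes) / sum(sizes)
}

#' Review curve of one ordering
#'
#' @inheritParams accuracy_after_review
#' @param name Label for the ordering (e.g. "confidence", "optimal").
#' @return Object of class `review_curve`: `k = 0..n`, `acc_k`, `ordering`,
#'   `sizes`, `name`.
#' @export
review_curve <- function(acc, sizes, ordering = seq_along(acc),
                         name = "ordering") {
  check_review_clips(acc, sizes)
  n <- length(acc)
  acc_k <- vapply(0:n, function(k) accuracy_after_review(acc, sizes, ordering, k),
                  numeric(1))
  structure(
    list(k = 0:n, acc_k = acc_k, ordering = ordering, sizes = sizes,
         acc = acc, name = name),
    class = "review_curve"
  )
}

#' Ascending-confidence review ordering
#'
#' Clips are reviewed lowest confidence first; ties are broken by clip id
#' (or index) so the ordering is deterministic.
#'
#' @param conf Per-clip confidence scores.
#' @param ids Optional clip ids used for tie-breaking and reporting.
#' @return Integer permutation of `seq_along(conf)`.
#' @export
confidence_ordering <- function(conf, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(conf)
  order(conf, ids)
}

#' Optimal (ascending true accuracy) review ordering
#'
#' @param acc Per-clip true accuracies.
#' @param ids Optional clip ids for deterministic tie-breaking.
#' @return Integer permutation of `seq_along(acc)`.
#' @export
optimal_ordering <- function(acc, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(acc)
  order(acc, ids)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Expected review curve under random clip orderings
#'
#' The baseline "no information" curve: the mean of
#' [accuracy_after_review()] over orderings drawn uniformly at random. Below
#' 7 clips all `n!` orderings are enumerated exactly; otherwise a seeded
#' Monte-Carlo mean over `n_permutations` draws is used.
#'
#' @param acc,sizes Per-clip accuracies and frame counts.
#' @param n_permutations Number of Monte-Carlo orderings (default 100).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return A `review_curve` named "random"; also carries the per-k standard
#'   error (`se_k`, zero for exhaustive enumeration) and the number of
#'   orderings averaged.
#' @export
random_review_curve <- function(acc, sizes, n_permutations = 100, seed = 0L) {
  check_review_clips(acc, sizes)
  check_scalar_number(n_permutations, "n_permutations", lower = 1)
  n <- length(acc)
  perms <- if (n < 7L) {
    all_permutations(n)
  } else {
    with_substream(seed, "review_random",
                   replicate(n_permutations, sample.int(n), simplify = FALSE))
  }
  curves <- vapply(
    perms,
    function(p) vapply(0:n, function(k) accuracy_after_review(acc, sizes, p, k),
                       numeric(1)),
    numeric(n + 1L)
  )
  m <- length(perms)
  acc_k <- rowMeans(curves)
  se_k <- if (m > 1L) apply(curves, 1L, stats::sd) / sqrt(m) else rep(0, n + 1L)
  structure(
    list(k = 0:n, acc_k = acc_k, ordering = NULL, sizes = sizes, acc = acc,
         name = "random", se_k = se_k, n_orderings = m,
         exhaustive = n < 7L),
    class = "review_curve"
  )
}

#' Improvement over random of a review curve
#'
#' Pointwise `IOR_k = acc(D_k^method) - acc(D_k^random)` and its mean
#' `sum(IOR_k, k = 0..n) / n` (an (n+1)-term sum normalized by n).
#'
#' @param curve_method A `review_curve` for the ordering under evaluation.
#' @param curve_random The random-baseline `review_curve` on the same clips.
#' @return List with `IOR_k` (length n+1) and scalar `mean_IOR`.
#' @export
improvement_over_random <- function(curve_method, curve_random) {
  stopifnot(inherits(curve_method, "review_curve"),
            inherits(curve_random, "review_curve"))
  if (length(curve_method$k) != length(curve_random$k) ||
      any(curve_method$k != curve_random$k))
    abort_invalid("review curves are on different k grids")
  ior <- curve_method$acc_k - curve_random$acc_k
  n <- length(ior) - 1L
  list(IOR_k = ior, mean_IOR = sum(ior) / n)
}

#' Review efficiency of an ordering
#'
#' The mean improvement over random of the candidate ordering, relative to
#' that of the optimal (ascending true accuracy) ordering:
#' `mean_IOR_method / mean_IOR_opt`. Equals 1 when the candidate ordering
#' matches accuracy-sorted review, and 0 in expectation for an uninformative
#' (random) ordering; worse-than-random orderings are negative.
#'
#' @param mean_IOR_method Mean IOR of the candidate ordering.
#' @param mean_IOR_opt Mean IOR of the optimal ordering (> 0 for a defined
#'   ratio).
#' @return The efficiency ratio, or `NA` with attribute
#'   `undefined = TRUE` when `mean_IOR_opt <= 0` (all clips equally
#'   accurate, so no ordering can improve on random).
#' @export
review_efficiency <- function(mean_IOR_method, mean_IOR_opt) {
  if (!is.finite(mean_IOR_opt) || mean_IOR_opt <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  mean_IOR_method / mean_IOR_opt
}

#' Full review-efficiency evaluation of a confidence score
#'
#' Convenience wrapper: builds the confidence, optimal and random curves and
#' returns IOR series and the review-efficiency summary.
#'
#' @param conf Per-clip confidences.
#' @param acc Per-clip true accuracies.
#' @param sizes Per-clip frame counts.
#' @param n_permutations,seed Passed to [random_review_curve()].
#' @param ids Optional clip ids for tie-breaking.
#' @return Object of class `review_summary` with the three curves, `IOR`
#'   lists and `efficiency`.
#' @export
evaluate_review <- function(conf, acc, sizes, n_permutations = 100, seed = 0L,
                            ids = NULL) {
  curve_conf <- review_curve(acc, sizes, confidence_ordering(conf, ids),
                             name = "confidence")
  curve_opt <- review_curve(acc, sizes, optimal_ordering(acc, ids),
                            name = "optimal")
  curve_rand <- random_review_curve(acc, sizes, n_permutations, seed)
  ior_conf <- improvement_over_random(curve_conf, curve_rand)
  ior_opt <- improvement_over_random(curve_opt, curve_rand)
  structure(
    list(curve_conf = curve_conf, curve_opt = curve_opt,
         curve_rand = curve_rand, IOR_conf = ior_conf, IOR_opt = ior_opt,
         efficiency = review_efficiency(ior_conf$mean_IOR, ior_opt$mean_IOR)),
    class = "review_summary"
  )
}

#' @export
print.review_summary <- function(x, ...) {
  cat(sprintf(
    "<review_summary> %d clips: mean IOR conf = %.4f, opt = %.4f, efficiency = %.4f\n",
    length(x$curve_conf$acc), x$IOR_conf$mean_IOR, x$IOR_opt$mean_IOR,
    as.numeric(x$efficiency)))
  invisible(x)
}
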