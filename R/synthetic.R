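# Seeded synthetic generators. These emulate the structure of real
# behavior-video datasets -- mutually exclusive labels with Markov bout
# structure, behavior-dependent motion, class imbalance -- so that every
# pipeline stage is testable without external data. Feature-level fixtures
# bypass the CNN for fast unit tests; video-level fixtures exercise the
# full frames -> flow -> features path.

#' Specify a synthetic behavior process
#'
#' Each behavior has a motion kernel (scene velocity in px/frame plus
#' jitter), a self-transition probability `p_stay` governing bout length
#' (mean bout length is `1 / (1 - p_stay)` frames), and a class weight.
#' Off-diagonal transition mass is distributed proportionally to the other
#' classes' weights; class imbalance arises chiefly from unequal bout
#' lengths (per-behavior `p_stay`), mirroring how common behaviors dominate
#' real ethograms.
#'
#' @param behaviors A [behavior_set()] or character vector of behavior names.
#' @param p_stay Per-behavior self-transition probability in `[0, 1)`
#'   (recycled).
#' @param weights Class weights (recycled, normalized to sum 1) used for the
#'   initial state and to apportion switch targets; exact frame occupancy is
#'   given by [stationary_weights()].
#' @param velocity K x 2 matrix (or list) of per-behavior scene velocities in
#'   px/frame; defaults to speeds 0, 1, 2, ... in distinct directions.
#' @param jitter Per-behavior sd of frame-to-frame velocity noise (recycled).
#' @param fps Frame rate of generated video.
#' @param frame_size Height/width of generated frames (>= 64).
#' @return Object of class `synthetic_behavior_spec`.
#' @export
synthetic_behavior_spec <- function(behaviors, p_stay = 0.9, weights = 1,
                                    velocity = NULL, jitter = 0.1,
                                    fps = 10, frame_size = 64) {
  if (is.character(behaviors)) behaviors <- behavior_set(behaviors)
  stopifnot(inherits(behaviors, "behavior_set"))
  K <- behaviors$K
  p_stay <- rep_len(p_stay, K)
  if (any(p_stay < 0 | p_stay >= 1))
    abort_invalid("`p_stay` must lie in [0, 1)")
  weights <- rep_len(weights, K)
  if (any(weights <= 0))
    abort_invalid("`weights` must be positive")
  weights <- weights / sum(weights)
  if (is.null(velocity)) {
    ang <- 2 * pi * (seq_len(K) - 1) / K
    velocity <- cbind((seq_len(K) - 1) * cos(ang), (seq_len(K) - 1) * sin(ang))
  }
  velocity <- matrix(unlist(velocity), nrow = K, ncol = 2)
  check_scalar_number(fps, "fps", lower = 0, strict_lower = TRUE)
  if (frame_size < 64)
    abort_invalid("`frame_size` must be at least 64")
  structure(
    list(behaviors = behaviors, p_stay = p_stay, weights = weights,
         velocity = velocity, jitter = rep_len(jitter, K), fps = fps,
         frame_size = as.integer(frame_size)),
    class = "synthetic_behavior_spec"
  )
}

#' Transition matrix of a synthetic behavior spec
#'
#' Diagonal entries equal `p_stay` exactly (so bout lengths are geometric
#' with mean `1 / (1 - p_stay)`); off-diagonal mass goes to the other
#' classes in proportion to their weights. Class imbalance in the stationary
#' distribution therefore comes primarily from per-behavior `p_stay`
#' (behaviors with longer bouts occupy more frames); use
#' [stationary_weights()] for the exact occupancy.
#'
#' @param spec A [synthetic_behavior_spec()].
#' @return K x K row-stochastic matrix.
#' @export
transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_behavior_spec"))
  K <- spec$behaviors$K
  P <- matrix(0, K, K)
  for (k in seq_len(K)) {
    if (K == 1L) {
      P[k, k] <- 1
      next
    }
    w <- spec$weights
    w[k] <- 0
    P[k, ] <- (1 - spec$p_stay[k]) * w / sum(w)
    P[k, k] <- spec$p_stay[k]
  }
  P
}

#' Stationary distribution of the label process
#'
#' The exact long-run fraction of frames each behavior occupies under the
#' spec's transition matrix (left eigenvector of eigenvalue 1, normalized).
#'
#' @param spec A [synthetic_behavior_spec()].
#' @return Named numeric vector of length K summing to 1.
#' @export
stationary_weights <- function(spec) {
  P <- transition_matrix(spec)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, spec$behaviors$labels)
}

#' Sample a Markov label sequence
#'
#' First-order Markov chain over the behaviors of `spec`; the initial state is
#' drawn from the stationary weights.
#'
#' @param spec A [synthetic_behavior_spec()].
#' @param n_frames Sequence length (>= 1).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Character vector of behavior labels, length `n_frames`.
#' @export
generate_label_sequence <- function(spec, n_frames, seed = 0L) {
  stopifnot(inherits(spec, "synthetic_behavior_spec"))
  check_scalar_number(n_frames, "n_frames", lower = 1)
  P <- transition_matrix(spec)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    abort_invalid("transition matrix rows must be non-negative and sum to 1")
  K <- nrow(P)
  with_substream(seed, "labels", {
    states <- integer(n_frames)
    states[1L] <- sample.int(K, 1L, prob = spec$weights)
    if (n_frames > 1L) {
      u <- stats::runif(n_frames - 1L)
      cum <- t(apply(P, 1L, cumsum))
      for (t in 2:n_frames) {
        states[t] <- findInterval(u[t - 1L], cum[states[t - 1L], ],
                                  left.open = TRUE) + 1L
      }
    }
    spec$behaviors$labels[states]
  })
}

# Smooth periodic texture used as the synthetic scene; sampled at positions
# shifted by the accumulated scene motion so TV-L1 can recover the velocity.
synthetic_texture_fun <- function(seed, n_waves = 24) {
  with_substream(seed, "texture", {
    fx <- stats::runif(n_waves, 0.02, 0.25)
    fy <- stats::runif(n_waves, 0.02, 0.25)
    ph <- stats::runif(n_waves, 0, 2 * pi)
    am <- stats::runif(n_waves, 0.3, 1)
  })
  function(X, Y) {
    v <- 0
    for (i in seq_len(n_waves))
      v <- v + am[i] * sin(2 * pi * (fx[i] * X + fy[i] * Y) + ph[i])
    v <- v / sum(abs(am))
    (v + 1) / 2
  }
}

#' Render a synthetic behavior video
#'
#' Generates a label sequence from `spec`'s Markov process, then renders a
#' textured scene that translates with the active behavior's velocity kernel
#' (plus jitter) and carries a bright blob marking the "animal". Frames
#' where the active behavior has zero velocity are (nearly) static, so dense
#' optical flow on the output recovers the kernel velocities.
#'
#' @param spec A [synthetic_behavior_spec()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return List with `frames` (list of `frame_size x frame_size` grayscale
#'   matrices in `[0, 1]`), `labels`, `fps`, and the per-frame scene
#'   `velocities` actually applied (n x 2).
#' @export
generate_video <- function(spec, n_frames, seed = 0L) {
  stopifnot(inherits(spec, "synthetic_behavior_spec"))
  labels <- generate_label_sequence(spec, n_frames, seed)
  k_idx <- match(labels, spec$behaviors$labels)
  s <- spec$frame_size
  tex <- synthetic_texture_fun(seed)
  jit <- with_substream(seed, "video_jitter",
                        matrix(stats::rnorm(2 * n_frames), ncol = 2))
  vel <- spec$velocity[k_idx, , drop = FALSE] + jit * spec$jitter[k_idx]
  vel[1L, ] <- 0
  pos <- apply(vel, 2L, cumsum)
  Xg <- matrix(seq_len(s), s, s, byrow = TRUE)   # column (x) coordinate
  Yg <- matrix(seq_len(s), s, s)                 # row (y) coordinate
  frames <- vector("list", n_frames)
  blob_c <- s / 2
  for (t in seq_len(n_frames)) {
    img <- tex(Xg - pos[t, 1L], Yg - pos[t, 2L])
    d2 <- (Xg - blob_c - pos[t, 1L] %% 8)^2 +
      (Yg - blob_c - pos[t, 2L] %% 8)^2
    img <- pmin(img + 0.4 * exp(-d2 / (2 * (s / 12)^2)), 1)
    frames[[t]] <- img
  }
  list(frames = frames, labels = labels, fps = spec$fps, velocities = vel)
}

#' Specify a synthetic class-conditional feature process
#'
#' Class k has a mean vector at distance `delta` from every other class mean
#' (means are placed on scaled coordinate axes of the feature space) and
#' isotropic Gaussian noise of sd `sigma`, in `d` dimensions.
#'
#' @param K Number of classes (>= 2).
#' @param d Feature dimensionality (default 512).
#' @param delta Pairwise distance between class means (>= 0).
#' @param sigma Within-class standard deviation (> 0).
#' @return Object of class `synthetic_feature_spec` with the `means` matrix
#'   (K x d).
#' @export
synthetic_feature_spec <- function(K, d = 512, delta = 6, sigma = 1) {
  check_scalar_number(K, "K", lower = 2)
  check_scalar_number(delta, "delta", lower = 0)
  check_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  if (d < K)
    abort_invalid("need d >= K to place K equidistant class means")
  means <- matrix(0, K, d)
  for (k in seq_len(K)) means[k, k] <- delta / sqrt(2)
  structure(
    list(K = as.integer(K), d = as.integer(d), delta = delta, sigma = sigma,
         means = means),
    class = "synthetic_feature_spec"
  )
}

#' Sample class-conditional Gaussian features for a label sequence
#'
#' Frame j with label y_j gets `x_j ~ Normal(mean_{y_j}, sigma^2 I)`.
#'
#' @param spec A [synthetic_feature_spec()].
#' @param labels Label vector: integers in 1..K or characters matched against
#'   `behaviors`.
#' @param seed Integer seed.
#' @param behaviors Optional [behavior_set()] for character labels.
#' @return n x d feature matrix.
#' @export
generate_features <- function(spec, labels, seed = 0L, behaviors = NULL) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  idx <- resolve_label_index(labels, spec$K, behaviors)
  n <- length(idx)
  noise <- with_substream(seed, "features",
                          matrix(stats::rnorm(n * spec$d, sd = spec$sigma),
                                 n, spec$d))
  spec$means[idx, , drop = FALSE] + noise
}

#' Generate calibrated (or miscalibrated) logits for known labels
#'
#' For each frame a posterior vector is drawn with a peak probability `p_j`
#' (uniform around `base_accuracy`) on a class chosen *from that posterior*,
#' then the peak is swapped onto the true label exactly when the sampled
#' class equals it. The construction makes the emitted probabilities exactly
#' calibrated: `P(correct | posterior) = max posterior`, and argmax accuracy
#' converges to `base_accuracy`. Returned logits are
#' `log(posterior) * overconfidence_scale`, so a scale of 1 yields
#' calibrated logits (fitted temperature ~ 1) and a scale `s > 1`
#' overconfident ones (fitted temperature ~ s).
#'
#' @param labels True labels (integers 1..K or characters with `behaviors`).
#' @param K Number of classes.
#' @param base_accuracy Mean peak probability, in `(1/K, 1)`.
#' @param overconfidence_scale Multiplier `s > 0` applied to the
#'   log-posteriors.
#' @param seed Integer seed.
#' @param behaviors Optional [behavior_set()] for character labels.
#' @return List with `logits` (n x K), `pred` (argmax class indices) and
#'   `labels` (resolved true indices).
#' @export
generate_calibrated_logits <- function(labels, K, base_accuracy = 0.8,
                                       overconfidence_scale = 1, seed = 0L,
                                       behaviors = NULL) {
  check_scalar_number(K, "K", lower = 2)
  check_scalar_number(base_accuracy, "base_accuracy", lower = 1 / K, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(overconfidence_scale, "overconfidence_scale",
                      lower = 0, strict_lower = TRUE)
  idx <- resolve_label_index(labels, K, behaviors)
  n <- length(idx)
  half_width <- 0.8 * min(base_accuracy - 1 / K, 1 - base_accuracy)
  with_substream(seed, "calibrated_logits", {
    p_peak <- stats::runif(n, base_accuracy - half_width,
                           base_accuracy + half_width)
    peak_at <- sample.int(K, n, replace = TRUE)   # exchangeable peak position
    # sample the "true" class from each posterior, then swap coordinates so
    # that the sampled class sits at the known label: preserves calibration
    correct <- stats::runif(n) < p_peak
    other <- vapply(peak_at, function(pk) {
      j <- sample.int(K - 1L, 1L)
      if (j >= pk) j + 1L else j
    }, integer(1))
    sampled <- ifelse(correct, peak_at, other)
    post <- matrix((1 - p_peak) / (K - 1L), n, K)
    post[cbind(seq_len(n), peak_at)] <- p_peak
    # swap columns `sampled` and `idx` row-wise
    tmp <- post[cbind(seq_len(n), sampled)]
    post[cbind(seq_len(n), sampled)] <- post[cbind(seq_len(n), idx)]
    post[cbind(seq_len(n), idx)] <- tmp
    logits <- log(post) * overconfidence_scale
    list(logits = logits, pred = max.col(logits, ties.method = "first"),
         labels = idx)
  })
}
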