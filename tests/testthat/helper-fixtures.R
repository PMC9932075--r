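# Shared fixtures, generated in code. Nothing here touches the network or
# the filesystem outside tempdir().

# Smooth band-limited texture: enough structure for optical flow to lock on,
# evaluable at real-valued (sub-pixel shifted) coordinates.
smooth_texture <- function(size, seed = 42, shift_x = 0, shift_y = 0) {
  set.seed(seed)
  n_waves <- 20
  fx <- runif(n_waves, 0.02, 0.2)
  fy <- runif(n_waves, 0.02, 0.2)
  ph <- runif(n_waves, 0, 2 * pi)
  X <- matrix(seq_len(size), size, size, byrow = TRUE) - shift_x
  Y <- matrix(seq_len(size), size, size) - shift_y
  v <- 0
  for (i in seq_len(n_waves))
    v <- v + sin(2 * pi * (fx[i] * X + fy[i] * Y) + ph[i])
  (v / n_waves + 1) / 2
}

# Class-conditional Gaussian sequences with Markov labels, for classifier
# tests (a thin wrapper over the synthetic module).
markov_gaussian_clip <- function(n_frames, K = 3, d = 8, delta = 6,
                                 sigma = 1, p_stay = 0.9, seed = 1) {
  bset <- behavior_set(paste0("b", seq_len(K)))
  bspec <- synthetic_behavior_spec(bset, p_stay = p_stay)
  fspec <- synthetic_feature_spec(K, d = d, delta = delta, sigma = sigma)
  y <- generate_label_sequence(bspec, n_frames, seed = seed)
  idx <- match(y, bset$labels)
  list(x = generate_features(fspec, idx, seed = seed + 1000L), y = idx,
       labels = y, behaviors = bset)
}

clips_to_seqs <- function(clips, fps = 5, sequence_seconds = 15) {
  do.call(c, lapply(clips, function(cl)
    split_into_sequences(cl$x, cl$y, fps, sequence_seconds)))
}
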