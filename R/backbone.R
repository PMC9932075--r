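# Convolutional backbone for per-frame feature extraction. The architecture
# is the standard 18-layer residual network: 7x7/2 stem, 3x3 max-pool, four
# stages of two basic blocks (64/128/256/512 channels), global average
# pooling -- so every input frame yields a 512-dimensional feature vector.
# Weights are seeded He-initialized draws by default: feature extraction is
# a fixed (not trained) transform here, and a deterministic random backbone
# keeps the pipeline self-contained; externally trained weights can be
# plugged in through the same structure. Convolutions are computed with
# im2col + BLAS matrix products.

conv_init <- function(kh, kw, cin, cout, scale = 1) {
  w <- array(stats::rnorm(kh * kw * cin * cout,
                          sd = scale * sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

#' Seeded residual convolutional backbone
#'
#' @param seed Integer seed for the weight draws.
#' @param in_channels Channels expected by the first convolution (3 for RGB
#'   frames; see [make_flow_backbone()] for stacked-flow input).
#' @return Object of class `cnn_backbone` with `feature_dim = 512`.
#' @export
backbone_resnet18 <- function(seed = 0L, in_channels = 3L) {
  blocks <- list(c(64, 64, 1), c(64, 64, 1),
                 c(64, 128, 2), c(128, 128, 1),
                 c(128, 256, 2), c(256, 256, 1),
                 c(256, 512, 2), c(512, 512, 1))
  with_substream(seed, "backbone", {
    stem <- conv_init(7, 7, in_channels, 64)
    layers <- lapply(blocks, function(bl) {
      cin <- bl[1]; cout <- bl[2]; stride <- bl[3]
      blk <- list(
        type = "block",
        conv1 = conv_init(3, 3, cin, cout),
        # damp the residual branch so activations stay bounded through depth
        conv2 = conv_init(3, 3, cout, cout, scale = 0.25),
        stride = stride
      )
      if (stride != 1 || cin != cout)
        blk$proj <- conv_init(1, 1, cin, cout)
      blk
    })
    structure(
      list(stem = stem, blocks = layers, in_channels = as.integer(in_channels),
           feature_dim = 512L, seed = seed, id = sprintf("resnet18-rand-%d", seed)),
      class = "cnn_backbone"
    )
  })
}

#' @export
print.cnn_backbone <- function(x, ...) {
  cat(sprintf("<cnn_backbone> %s: %d input channels -> %d features\n",
              x$id, x$in_channels, x$feature_dim))
  invisible(x)
}

# im2col convolution: x [H, W, C], w [kh, kw, C, Cout].
conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cout <- dim(w)[4L]
  if (dim(w)[3L] != C)
    abort_invalid("convolution expects %d input channels, got %d",
                  dim(w)[3L], C)
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  oh <- (H + 2L * pad - kh) %/% stride + 1L
  ow <- (W + 2L * pad - kw) %/% stride + 1L
  rows <- seq.int(1L, by = stride, length.out = oh)
  cols <- seq.int(1L, by = stride, length.out = ow)
  col <- matrix(0, oh * ow, kh * kw * C)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      patch <- xp[rows + i - 1L, cols + j - 1L, , drop = FALSE]
      pos <- i + (j - 1L) * kh + (seq_len(C) - 1L) * kh * kw
      col[, pos] <- matrix(patch, oh * ow, C)
    }
  }
  wm <- matrix(w, kh * kw * C, cout)
  y <- col %*% wm
  y <- sweep(y, 2L, b, `+`)
  array(y, c(oh, ow, cout))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

maxpool_3x3_s2 <- function(x) {
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  pad <- 1L
  xp <- array(-Inf, c(H + 2L, W + 2L, C))
  xp[1L + seq_len(H), 1L + seq_len(W), ] <- x
  oh <- (H + 2L - 3L) %/% 2L + 1L
  ow <- (W + 2L - 3L) %/% 2L + 1L
  rows <- seq.int(1L, by = 2L, length.out = oh)
  cols <- seq.int(1L, by = 2L, length.out = ow)
  out <- array(-Inf, c(oh, ow, C))
  for (j in 0:2) for (i in 0:2)
    out <- pmax(out, xp[rows + i, cols + j, , drop = FALSE])
  out
}

block_forward <- function(x, blk) {
  h <- relu(conv2d(x, blk$conv1$w, blk$conv1$b, stride = blk$stride, pad = 1L))
  h <- conv2d(h, blk$conv2$w, blk$conv2$b, stride = 1L, pad = 1L)
  shortcut <- if (is.null(blk$proj)) x else
    conv2d(x, blk$proj$w, blk$proj$b, stride = blk$stride, pad = 0L)
  relu(h + shortcut)
}

backbone_first_conv <- function(backbone, x) {
  conv2d(x, backbone$stem$w, backbone$stem$b, stride = 2L, pad = 3L)
}

backbone_forward <- function(backbone, x) {
  if (length(dim(x)) != 3L)
    abort_invalid("backbone input must be an H x W x C array")
  h <- relu(backbone_first_conv(backbone, x))
  h <- maxpool_3x3_s2(h)
  for (blk in backbone$blocks) h <- block_forward(h, blk)
  colMeans(matrix(h, dim(h)[1L] * dim(h)[2L], dim(h)[3L]))   # global average pool
}

imagenet_mean <- c(0.485, 0.456, 0.406)
imagenet_sd <- c(0.229, 0.224, 0.225)

#' Resize and normalize frames for the backbone
#'
#' Every frame is bilinearly resized to `size x size`, expanded to three
#' channels if grayscale, scaled to `[0, 1]` if 8-bit, and standardized per
#' channel with the usual natural-image channel statistics.
#'
#' @param frames List of frames: `H x W` matrices or `H x W x 3` arrays.
#' @param size Output height/width in pixels (default 224).
#' @return List of `size x size x 3` arrays, one per input frame.
#' @export
preprocess_frames <- function(frames, size = 224L) {
  if (!is.list(frames) || length(frames) == 0L)
    abort_invalid("`frames` must be a non-empty list")
  check_scalar_number(size, "size", lower = 32)
  lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    if (!is.numeric(fr))
      abort_invalid("frame %d is not numeric image data", i)
    if (is.matrix(fr)) fr <- array(rep(fr, 3L), c(dim(fr), 3L))
    if (length(dim(fr)) != 3L || dim(fr)[3L] != 3L)
      abort_invalid("frame %d must be H x W or H x W x 3", i)
    if (max(fr) > 1.5) fr <- fr / 255
    out <- array(0, c(size, size, 3L))
    for (ch in 1:3)
      out[, , ch] <- (resize_matrix(fr[, , ch], size, size) -
                        imagenet_mean[ch]) / imagenet_sd[ch]
    out
  })
}

#' Extract per-frame backbone features
#'
#' Runs each frame (or flow stack) through the backbone and records the
#' global-average-pooling activations: one 512-vector per frame, rows in
#' input order. Inference is deterministic, so identical frames give
#' identical rows.
#'
#' @param frames List of preprocessed `H x W x C` arrays; `C` must match the
#'   backbone's `in_channels`.
#' @param backbone A `cnn_backbone`.
#' @param stream Stream tag stored on the result: `"spatial"` or
#'   `"temporal"`.
#' @param camera Camera id stored on the result.
#' @return `n x 512` matrix with attributes `stream`, `camera`, `backbone`.
#' @export
extract_stream_features <- function(frames, backbone,
                                    stream = c("spatial", "temporal"),
                                    camera = 1L) {
  stopifnot(inherits(backbone, "cnn_backbone"))
  stream <- match.arg(stream)
  if (!is.list(frames) || length(frames) == 0L)
    abort_invalid("`frames` must be a non-empty list")
  ch <- dim(frames[[1L]])[3L]
  if (is.na(ch) || ch != backbone$in_channels)
    abort_invalid("backbone expects %d input channels, frames have %s",
                  backbone$in_channels,
                  ifelse(is.na(ch), "none", as.character(ch)))
  feats <- t(vapply(frames, function(fr) backbone_forward(backbone, fr),
                    numeric(backbone$feature_dim)))
  structure(feats, stream = stream, camera = camera, backbone = backbone$id)
}

#' Stack flow images along channels for the temporal stream
#'
#' The stack for frame t concatenates the flow images at t-5 .. t+5 (for the
#' default stack size 11) along channels, giving `3 * stack_size = 33`
#' channels; near the clip boundary, missing neighbors are replaced by edge
#' replication of the first/last flow image.
#'
#' @param flow_images List (length n) of `H x W x 3` flow images for one
#'   clip, already preprocessed to the backbone input size.
#' @param stack_size Odd window length (default 11).
#' @return List of n `H x W x (3 * stack_size)` arrays.
#' @export
build_flow_stacks <- function(flow_images, stack_size = 11L) {
  if (!is.list(flow_images) || length(flow_images) == 0L)
    abort_invalid("`flow_images` must be a non-empty list")
  check_scalar_number(stack_size, "stack_size", lower = 1)
  if (stack_size %% 2L != 1L)
    abort_invalid("`stack_size` must be odd")
  n <- length(flow_images)
  half <- (stack_size - 1L) %/% 2L
  d <- dim(flow_images[[1L]])
  lapply(seq_len(n), function(t) {
    out <- array(0, c(d[1L], d[2L], 3L * stack_size))
    for (s in seq_len(stack_size)) {
      src <- min(max(t - half + s - 1L, 1L), n)   # edge replication
      out[, , (s - 1L) * 3L + 1:3] <- flow_images[[src]]
    }
    out
  })
}

#' Adapt a backbone to stacked-flow input
#'
#' Replicates the first convolution's kernel `stack_size` times along its
#' input-channel axis so the network accepts `3 * stack_size` channels
#' (33 for the default stack of 11); every other parameter is unchanged.
#'
#' @param backbone A `cnn_backbone` whose first convolution takes 3 channels.
#' @param stack_size Number of stacked flow images (default 11).
#' @return A new `cnn_backbone` with `in_channels = 3 * stack_size`.
#' @export
make_flow_backbone <- function(backbone, stack_size = 11L) {
  stopifnot(inherits(backbone, "cnn_backbone"))
  if (is.null(backbone$stem$w))
    abort_invalid("backbone has no identifiable first convolution")
  if (dim(backbone$stem$w)[3L] != 3L)
    abort_invalid("backbone's first convolution must take 3 channels")
  check_scalar_number(stack_size, "stack_size", lower = 1)
  fb <- backbone
  fb$stem$w <- backbone$stem$w[, , rep(1:3, times = stack_size), , drop = FALSE]
  fb$in_channels <- 3L * as.integer(stack_size)
  fb$id <- sprintf("%s-flow%d", backbone$id, stack_size)
  fb
}
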