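# Dense TV-L1 optical flow (total-variation regularizer, L1 data term)
# between consecutive grayscale frames, estimated with the classic
# duality-based scheme of Zach et al. on a coarse-to-fine pyramid, and its
# rendering as HSV "temporal frames" (hue = orientation, brightness =
# magnitude, Middlebury-style color wheel).

#' TV-L1 solver parameters
#'
#' Defaults follow the reference duality-based implementation: time step
#' `tau`, data-attachment weight `lambda`, tightness `theta`, `n_warps`
#' warps per pyramid level, `n_scales` pyramid levels with downsampling
#' factor `zoom`, and an inner fixed-point loop capped at `max_iter`
#' iterations or a mean-square update below `epsilon^2`.
#'
#' @param tau Dual ascent time step (default 0.25).
#' @param lambda Data term weight (default 0.15).
#' @param theta Coupling tightness (default 0.3).
#' @param n_warps Warps per scale (default 5).
#' @param n_scales Maximum pyramid levels (default 5; capped so the coarsest
#'   level is at least 16 px).
#' @param zoom Pyramid downsampling factor in (0, 1) (default 0.5).
#' @param max_iter Inner iterations per warp (default 50).
#' @param epsilon Stopping threshold on the flow update (default 0.01).
#' @return A named list of class `tvl1_params`.
#' @export
tvl1_params <- function(tau = 0.25, lambda = 0.15, theta = 0.3, n_warps = 5,
                        n_scales = 5, zoom = 0.5, max_iter = 50,
                        epsilon = 0.01) {
  check_scalar_number(tau, "tau", 0, strict_lower = TRUE)
  check_scalar_number(lambda, "lambda", 0, strict_lower = TRUE)
  check_scalar_number(theta, "theta", 0, strict_lower = TRUE)
  check_scalar_number(zoom, "zoom", 0, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  structure(list(tau = tau, lambda = lambda, theta = theta,
                 n_warps = n_warps, n_scales = n_scales, zoom = zoom,
                 max_iter = max_iter, epsilon = epsilon),
            class = "tvl1_params")
}

# Luma conversion for color inputs (H x W x 3 arrays).
as_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3L && dim(frame)[3L] == 3L)
    return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] +
             0.114 * frame[, , 3L])
  abort_invalid("frames must be H x W matrices or H x W x 3 arrays")
}

# Bilinear sampling of `img` at (X, Y) (columns, rows; 1-based), border clamp.
interp2 <- function(img, X, Y) {
  H <- nrow(img); W <- ncol(img)
  X <- pmin(pmax(X, 1), W)
  Y <- pmin(pmax(Y, 1), H)
  x0 <- pmin(floor(X), W - 1L)
  y0 <- pmin(floor(Y), H - 1L)
  dx <- X - x0
  dy <- Y - y0
  id <- function(r, c) (c - 1) * H + r
  v <- img[id(y0, x0)] * (1 - dx) * (1 - dy) +
    img[id(y0, x0 + 1)] * dx * (1 - dy) +
    img[id(y0 + 1, x0)] * (1 - dx) * dy +
    img[id(y0 + 1, x0 + 1)] * dx * dy
  matrix(v, nrow(X), ncol(X))
}

# Bilinear resize of a matrix to (h, w), with a light binomial pre-blur when
# shrinking (anti-aliasing).
resize_matrix <- function(img, h, w) {
  H <- nrow(img); W <- ncol(img)
  if (h == H && w == W) return(img)
  if (h < H || w < W) img <- blur3(img)
  X <- matrix(seq(1, W, length.out = w), h, w, byrow = TRUE)
  Y <- matrix(seq(1, H, length.out = h), h, w)
  interp2(img, X, Y)
}

blur3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  pad <- rbind(img[1L, , drop = FALSE], img, img[H, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, W, drop = FALSE])
  q <- (pad[1:H, ] + 2 * pad[2:(H + 1), ] + pad[3:(H + 2), ]) / 4
  (q[, 1:W] + 2 * q[, 2:(W + 1)] + q[, 3:(W + 2)]) / 4
}

central_gradient <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- (img[, c(2:W, W)] - img[, c(1, 1:(W - 1))]) / 2
  gy <- (img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]) / 2
  list(x = gx, y = gy)
}

forward_gradient <- function(u) {
  H <- nrow(u); W <- ncol(u)
  ux <- cbind(u[, 2:W, drop = FALSE] - u[, 1:(W - 1), drop = FALSE],
              numeric(H))
  uy <- rbind(u[2:H, , drop = FALSE] - u[1:(H - 1), , drop = FALSE],
              t(numeric(W)))
  list(x = ux, y = uy)
}

divergence <- function(px, py) {
  H <- nrow(px); W <- ncol(px)
  dx <- px
  dx[, 2:W] <- px[, 2:W, drop = FALSE] - px[, 1:(W - 1), drop = FALSE]
  dy <- py
  dy[2:H, ] <- py[2:H, , drop = FALSE] - py[1:(H - 1), , drop = FALSE]
  dx + dy
}

tvl1_one_scale <- function(I0, I1, u1, u2, p) {
  H <- nrow(I0); W <- ncol(I0)
  lt <- p$lambda * p$theta
  taut <- p$tau / p$theta
  g <- central_gradient(I1)
  Xb <- matrix(seq_len(W), H, W, byrow = TRUE)
  Yb <- matrix(seq_len(H), H, W)
  p11 <- p12 <- p21 <- p22 <- matrix(0, H, W)
  for (warp in seq_len(p$n_warps)) {
    I1w <- interp2(I1, Xb + u1, Yb + u2)
    I1wx <- interp2(g$x, Xb + u1, Yb + u2)
    I1wy <- interp2(g$y, Xb + u1, Yb + u2)
    grad <- I1wx^2 + I1wy^2
    rho_c <- I1w - I1wx * u1 - I1wy * u2 - I0
    for (it in seq_len(p$max_iter)) {
      rho <- rho_c + I1wx * u1 + I1wy * u2
      # pointwise thresholding step (proximal operator of the L1 data term)
      m1 <- rho < -lt * grad
      m2 <- rho > lt * grad
      m3 <- !m1 & !m2 & grad > 1e-12
      d1 <- lt * I1wx * (m1 - m2)
      d2 <- lt * I1wy * (m1 - m2)
      d1[m3] <- -(rho * I1wx / grad)[m3]
      d2[m3] <- -(rho * I1wy / grad)[m3]
      v1 <- u1 + d1
      v2 <- u2 + d2
      u1_new <- v1 + p$theta * divergence(p11, p12)
      u2_new <- v2 + p$theta * divergence(p21, p22)
      err <- mean((u1_new - u1)^2 + (u2_new - u2)^2)
      u1 <- u1_new
      u2 <- u2_new
      g1 <- forward_gradient(u1)
      g2 <- forward_gradient(u2)
      n1 <- 1 + taut * sqrt(g1$x^2 + g1$y^2)
      n2 <- 1 + taut * sqrt(g2$x^2 + g2$y^2)
      p11 <- (p11 + taut * g1$x) / n1
      p12 <- (p12 + taut * g1$y) / n1
      p21 <- (p21 + taut * g2$x) / n2
      p22 <- (p22 + taut * g2$y) / n2
      if (err < p$epsilon^2) break
    }
  }
  list(u1, u2)
}

#' Dense TV-L1 optical flow between two frames
#'
#' Estimates the per-pixel motion field from `frame_a` to `frame_b` by
#' minimizing a total-variation-regularized, L1-data-term energy on a
#' coarse-to-fine pyramid. Deterministic for fixed parameters.
#'
#' @param frame_a,frame_b Same-shape grayscale matrices (values in `[0, 1]`
#'   or `[0, 255]`) or H x W x 3 color arrays (converted to luma).
#' @param params A [tvl1_params()] list.
#' @return Object of class `flow_field`: matrices `dx`, `dy` in pixels/frame.
#' @examples
#' a <- matrix(runif(64 * 64), 64)
#' f <- compute_tvl1_flow(a, a)
#' max(abs(f$dx)) # static scene: ~0
#' @export
compute_tvl1_flow <- function(frame_a, frame_b, params = tvl1_params()) {
  I0 <- as_gray(frame_a)
  I1 <- as_gray(frame_b)
  if (!all(dim(I0) == dim(I1)))
    abort_invalid("frames have different shapes: %s vs %s",
                  paste(dim(I0), collapse = "x"),
                  paste(dim(I1), collapse = "x"))
  if (max(I0, I1) <= 1.5) {  # solver parameters assume 8-bit intensity range
    I0 <- I0 * 255
    I1 <- I1 * 255
  }
  H <- nrow(I0); W <- ncol(I0)
  n_scales <- max(1L, min(params$n_scales,
                          1L + floor(log(min(H, W) / 16) /
                                       log(1 / params$zoom))))
  hs <- round(H * params$zoom^((n_scales - 1):0))
  ws <- round(W * params$zoom^((n_scales - 1):0))
  u1 <- matrix(0, hs[1L], ws[1L])
  u2 <- matrix(0, hs[1L], ws[1L])
  for (s in seq_len(n_scales)) {
    I0s <- resize_matrix(I0, hs[s], ws[s])
    I1s <- resize_matrix(I1, hs[s], ws[s])
    if (s > 1L) {
      u1 <- resize_matrix(u1, hs[s], ws[s]) / params$zoom
      u2 <- resize_matrix(u2, hs[s], ws[s]) / params$zoom
    }
    uu <- tvl1_one_scale(I0s, I1s, u1, u2, params)
    u1 <- uu[[1L]]
    u2 <- uu[[2L]]
  }
  if (!all(is.finite(u1)) || !all(is.finite(u2)))
    abort_invalid("TV-L1 produced non-finite flow values")
  structure(list(dx = u1, dy = u2), class = "flow_field")
}

#' Flow magnitude
#'
#' @param flow A `flow_field`.
#' @return Matrix of per-pixel magnitudes.
#' @export
flow_magnitude <- function(flow) {
  sqrt(flow$dx^2 + flow$dy^2)
}

hsv_to_rgb_array <- function(h, s, v) {
  # vectorized HSV -> RGB, h in [0,1) cyclic, s, v in [0,1]
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
        ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
        ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
        ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, c(nrow(h), ncol(h), 3L))
  out[, , 1L] <- r
  out[, , 2L] <- g
  out[, , 3L] <- b
  out
}

#' Render a flow field as an 8-bit color image
#'
#' Hue encodes flow orientation (`angle / 2 pi` on a cyclic color wheel),
#' brightness encodes magnitude clipped at `max_magnitude`
#' (`min(|flow| / max_magnitude, 1)`), and saturation is fixed at maximum.
#' Zero-motion pixels are black. `max_magnitude` should be held fixed per
#' video (e.g. a high quantile of sampled magnitudes) so that brightness is
#' comparable across frames.
#'
#' @param flow A `flow_field`.
#' @param max_magnitude Positive normalization constant (pixels/frame).
#' @return H x W x 3 integer array with values in 0..255.
#' @export
flow_to_image <- function(flow, max_magnitude = 1) {
  check_scalar_number(max_magnitude, "max_magnitude", 0, strict_lower = TRUE)
  mag <- flow_magnitude(flow)
  hue <- (atan2(flow$dy, flow$dx) / (2 * pi)) %% 1
  val <- pmin(mag / max_magnitude, 1)
  rgb <- hsv_to_rgb_array(hue, matrix(1, nrow(mag), ncol(mag)), val)
  array(as.integer(round(rgb * 255)), dim = dim(rgb))
}

#' Per-video flow normalization constant
#'
#' @param flows List of `flow_field`s sampled from one video.
#' @param q Quantile of the pooled magnitudes (default 0.99).
#' @return A positive scalar suitable as `max_magnitude`.
#' @export
flow_norm_constant <- function(flows, q = 0.99) {
  mags <- unlist(lapply(flows, function(f) as.vector(flow_magnitude(f))))
  max(stats::quantile(mags, q), 1e-6)
}
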