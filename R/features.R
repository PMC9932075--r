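# Combining per-stream features and reducing their dimensionality with
# reconstruction independent component analysis (RICA). RICA learns a
# linear map W (d_in x d_out) minimizing, over standardized inputs x,
#
#   J(W) = mean_i [ lambda * || W W' x_i - x_i ||^2 + sum_j g(w_j' x_i) ]
#
# with g = log cosh: the first term preserves the ability to reconstruct
# the input from the projections, the second promotes independent
# (sparse) output features. The unconstrained smooth objective is
# minimized by L-BFGS from a seeded random initialization.

#' Concatenate per-stream, per-camera feature matrices
#'
#' Column-binds feature blocks in a fixed order (camera-major, spatial
#' before temporal within each camera), so one camera yields 1024 columns
#' and C cameras `512 * 2 * C`.
#'
#' @param matrices List of `n x d` feature matrices sharing the same row
#'   (frame) count, in the order to concatenate.
#' @return `n x sum(d)` matrix with attribute `stream = "concat"`.
#' @export
concat_features <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    abort_invalid("`matrices` must be a non-empty list of feature matrices")
  n <- nrow(matrices[[1L]])
  for (m in matrices)
    if (nrow(m) != n)
      abort_invalid("feature matrices have mismatched row counts (%d vs %d)",
                    n, nrow(m))
  out <- do.call(cbind, lapply(matrices, unclass))
  structure(out, stream = "concat",
            cameras = unique(unlist(lapply(matrices, attr, "camera"))))
}

rica_objective <- function(wvec, X, d_out, lambda) {
  d_in <- ncol(X)
  N <- nrow(X)
  W <- matrix(wvec, d_in, d_out)
  S <- X %*% W                      # N x d_out projections
  E <- S %*% t(W) - X               # reconstruction residual
  J <- (lambda / N) * sum(E * E) + sum(log(cosh(S))) / N
  attr(J, "S") <- S
  attr(J, "E") <- E
  J
}

rica_gradient <- function(wvec, X, d_out, lambda) {
  d_in <- ncol(X)
  N <- nrow(X)
  W <- matrix(wvec, d_in, d_out)
  S <- X %*% W
  E <- S %*% t(W) - X
  M <- crossprod(X, E)              # d_in x d_in
  g_rec <- (2 * lambda / N) * ((M + t(M)) %*% W)
  g_pen <- crossprod(X, tanh(S)) / N
  as.vector(g_rec + g_pen)
}

#' Fit a RICA dimensionality reduction
#'
#' Inputs are standardized (per-column mean 0, sd 1) before fitting; the
#' same standardization is applied by [apply_rica()]. The objective is
#' non-increasing from its value at the random initialization.
#'
#' @param X `N x d_in` training feature matrix, `N >= d_out`.
#' @param d_out Output dimensionality (default 512, `<= d_in`).
#' @param lambda Reconstruction penalty weight (default 1).
#' @param n_iter L-BFGS iteration cap (default 100).
#' @param seed Integer seed for the initialization.
#' @return Object of class `rica_transform`: `W`, standardization `center` /
#'   `scale`, `lambda`, objective values `J0` (initial) and `J` (final),
#'   `converged`.
#' @export
fit_rica <- function(X, d_out = 512L, lambda = 1, n_iter = 100L, seed = 0L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)))
    abort_invalid("`X` must be finite")
  d_in <- ncol(X)
  if (d_out > d_in)
    abort_invalid("d_out = %d exceeds input dimensionality %d", d_out, d_in)
  if (nrow(X) < d_out)
    abort_invalid("need at least d_out = %d training rows, got %d",
                  d_out, nrow(X))
  center <- colMeans(X)
  scale <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  w0 <- with_substream(seed, "rica_init",
                       stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)))
  J0 <- as.numeric(rica_objective(w0, Xs, d_out, lambda))
  opt <- stats::optim(
    w0, fn = function(w) as.numeric(rica_objective(w, Xs, d_out, lambda)),
    gr = function(w) rica_gradient(w, Xs, d_out, lambda),
    method = "L-BFGS-B",
    control = list(maxit = as.integer(n_iter))
  )
  if (!is.finite(opt$value))
    abort_invalid("RICA objective became non-finite")
  W <- matrix(if (opt$value <= J0) opt$par else w0, d_in, d_out)
  structure(
    list(W = W, center = center, scale = scale, lambda = lambda,
         d_in = d_in, d_out = as.integer(d_out),
         J0 = J0, J = min(opt$value, J0), converged = opt$convergence == 0,
         seed = seed),
    class = "rica_transform"
  )
}

#' @export
print.rica_transform <- function(x, ...) {
  cat(sprintf("<rica_transform> %d -> %d (lambda = %g, J %.4f -> %.4f)\n",
              x$d_in, x$d_out, x$lambda, x$J0, x$J))
  invisible(x)
}

#' Apply a fitted RICA transform
#'
#' Standardizes `X` with the training statistics and projects it:
#' `((X - center) / scale) %*% W`.
#'
#' @param transform A fitted `rica_transform`.
#' @param X `n x d_in` feature matrix.
#' @return `n x d_out` matrix with attribute `stream = "reduced"`.
#' @export
apply_rica <- function(transform, X) {
  stopifnot(inherits(transform, "rica_transform"))
  X <- as.matrix(X)
  if (ncol(X) != transform$d_in)
    abort_invalid("transform expects %d columns, got %d", transform$d_in,
                  ncol(X))
  Xs <- sweep(sweep(X, 2L, transform$center), 2L, transform$scale, `/`)
  structure(Xs %*% transform$W, stream = "reduced")
}
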