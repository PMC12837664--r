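## Shared neural building blocks: initialisers, dense layers, and 2-D
## convolution expressed as a fixed sparse gather (im2col) followed by a
## dense matrix product, so that the only differentiable pieces are plain
## matrix operations.
##
## Feature grids use the layout (P, C, L): P = h*w spatial sites (row index
## fastest, matching column-major storage of an h x w matrix), C channels,
## L centerline segments.

.rmat <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)

he_init <- function(n_out, n_in) .rmat(n_out, n_in, sqrt(2 / n_in))
glorot_init <- function(n_in, n_out) .rmat(n_in, n_out, sqrt(2 / (n_in + n_out)))

#' Dense layer: x %*% W + b
#' @param x n x d matrix (node or numeric); @param W d x m weights; @param b length-m bias.
#' @keywords internal
linear <- function(x, W, b) ad_add_rowvec(ad_matmul(x, W), b)

## Column-vector bias add for (rows = channels) matrices.
#' Add a per-row bias to a matrix
#' @param a n x m matrix; @param b length-n vector.
#' @export
ad_add_colvec <- function(a, b) {
  av <- ad_val(a); bv <- as.numeric(ad_val(b))
  ad_apply(list(a, b), av + bv,    # column-major recycling adds b down each column
           function(g) list(g, rowSums(g)))
}

#' Row-wise layer normalisation of a matrix with learnable affine
#' @param x n x d matrix; @param gamma,beta length-d parameters; @param eps guard.
#' @export
ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x); gav <- ad_val(gamma); bev <- ad_val(beta)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  sd <- sqrt(va + eps)
  xhat <- xc / sd
  y <- sweep(sweep(xhat, 2L, gav, "*"), 2L, bev, "+")
  ad_apply(list(x, gamma, beta), y, function(g) {
    dxhat <- sweep(g, 2L, gav, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    gx <- (dxhat - m1 - xhat * m2) / sd
    list(gx, colSums(g * xhat), colSums(g))
  })
}

#' Build an im2col gather plan for a 2-D convolution
#'
#' For an input stored as a (h*w*cin) x L column matrix (spatial index
#' fastest), the plan maps every entry of every k x k x cin patch of every
#' output position to its source row; out-of-image taps (zero padding)
#' gather nothing.
#'
#' @param h,w input spatial size; @param cin input channels;
#' @param k kernel size; @param stride stride; @param pad zero padding.
#' @return list(vidx, gidx, inv, inv_w, n_rows, n_in, h_out, w_out, kkc):
#'   patch rows `vidx` gather input rows `gidx`; `inv`/`inv_w` give the
#'   static inverse gather used by the backward pass.
#' @keywords internal
make_im2col <- function(h, w, cin, k, stride, pad) {
  h_out <- (h + 2 * pad - k) %/% stride + 1L
  w_out <- (w + 2 * pad - k) %/% stride + 1L
  kkc <- k * k * cin
  n_rows <- kkc * h_out * w_out
  idx <- integer(n_rows)
  ## patch-row order: entry (di, dj, c) fastest, then output position p'
  for (jo in seq_len(w_out)) for (io in seq_len(h_out)) {
    p_out <- io + (jo - 1L) * h_out
    base_row <- (p_out - 1L) * kkc
    for (c in seq_len(cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
      i <- (io - 1L) * stride - pad + di
      j <- (jo - 1L) * stride - pad + dj
      r <- base_row + (c - 1L) * k * k + (dj - 1L) * k + di
      idx[r] <- if (i >= 1L && i <= h && j >= 1L && j <= w)
        i + (j - 1L) * h + (c - 1L) * h * w else 0L
    }
  }
  vidx <- which(idx > 0L)
  gidx <- idx[vidx]
  n_in <- h * w * cin
  ## static inverse gather: for every input row, the patch rows referencing
  ## it (so the backward pass is a fixed set of adds, no sorting)
  refs <- split(vidx, gidx)
  max_ref <- max(lengths(refs))
  inv <- matrix(1L, n_in, max_ref)              # clamped index, weighted 0
  inv_w <- matrix(0, n_in, max_ref)
  for (r in seq_along(refs)) {
    ri <- as.integer(names(refs)[r])
    inv[ri, seq_along(refs[[r]])] <- refs[[r]]
    inv_w[ri, seq_along(refs[[r]])] <- 1
  }
  list(vidx = vidx, gidx = gidx, inv = inv, inv_w = inv_w,
       n_rows = n_rows, n_in = n_in,
       h_out = h_out, w_out = w_out, kkc = kkc)
}

## im2col gather as an autodiff op: row gather forward, static inverse
## gather (adds over at most k*k referencing patch rows) backward.
ad_im2col <- function(x, plan) {
  xv <- ad_val(x)
  L <- ncol(xv)
  G <- matrix(0, plan$n_rows, L)
  G[plan$vidx, ] <- xv[plan$gidx, , drop = FALSE]
  ad_apply(list(x), G, function(g) {
    gx <- g[plan$inv[, 1], , drop = FALSE] * plan$inv_w[, 1]
    for (j in seq_len(ncol(plan$inv))[-1])
      gx <- gx + g[plan$inv[, j], , drop = FALSE] * plan$inv_w[, j]
    list(gx)
  })
}

#' Apply a 2-D convolution to a (P, C, L) feature grid
#'
#' @param x grid (node or numeric) of dim (h*w, cin, L).
#' @param plan output of [make_im2col()] for matching geometry.
#' @param W cout x (k*k*cin) weights; @param b length-cout bias (or NULL).
#' @return grid of dim (h_out*w_out, cout, L).
#' @keywords internal
conv2d <- function(x, plan, W, b = NULL) {
  d <- dim(ad_val(x)); L <- d[3]
  cout <- nrow(ad_val(W))
  pout <- plan$h_out * plan$w_out
  x2 <- ad_reshape(x, c(d[1] * d[2], L))
  g <- ad_im2col(x2, plan)                          # (kkc*pout) x L
  g <- ad_reshape(g, c(plan$kkc, pout * L))
  y <- ad_matmul(W, g)                              # cout x (pout*L)
  if (!is.null(b)) y <- ad_add_colvec(y, b)
  ad_aperm(ad_reshape(y, c(cout, pout, L)), c(2, 1, 3))
}

#' Two-layer perceptron with ReLU hidden activation
#' @param x input matrix; @param p list(W1, b1, W2, b2).
#' @keywords internal
mlp2 <- function(x, p) linear(ad_relu(linear(x, p$W1, p$b1)), p$W2, p$b2)

mlp2_init <- function(d_in, d_hidden, d_out) {
  list(W1 = glorot_init(d_in, d_hidden), b1 = numeric(d_hidden),
       W2 = glorot_init(d_hidden, d_out), b2 = numeric(d_out))
}

## Wrap every numeric leaf of a nested list into ad_param nodes.
params_to_nodes <- function(x) {
  if (is.list(x)) lapply(x, params_to_nodes) else ad_param(x)
}

## Extract plain values back from a (possibly node-bearing) parameter tree.
params_to_values <- function(x) {
  if (is_node(x)) x$value
  else if (is.list(x)) lapply(x, params_to_values)
  else x
}
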