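## Topology-aware dual-stream encoding.
##
## Feature maps ("grids") are stored spatial-major as (P, C, L) arrays:
## P = h*w cross-sectional positions (column-major over the h x w section),
## C channels, L centerline segments. `fmap_from_lchw()`/`fmap_to_lchw()`
## convert to the (L, C, h, w) ordering used in the documentation.

.plan_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .plan_cache, inherits = FALSE))
    assign(key, builder(), envir = .plan_cache)
  get(key, envir = .plan_cache, inherits = FALSE)
}

im2col_cached <- function(h, w, cin, k, stride, pad) {
  cached(sprintf("im2col_%d_%d_%d_%d_%d_%d", h, w, cin, k, stride, pad),
         function() make_im2col(h, w, cin, k, stride, pad))
}

#' Convert a (L, C, h, w) array to the internal (h*w, C, L) grid layout
#' @param x array of dim (L, C, h, w).
#' @export
fmap_from_lchw <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(3, 4, 2, 1))        # (h, w, C, L)
  dim(y) <- c(d[3] * d[4], d[2], d[1])
  y
}

#' Convert an internal (h*w, C, L) grid back to (L, C, h, w)
#' @param x grid; @param h,w spatial extent with h*w == dim(x)[1].
#' @export
fmap_to_lchw <- function(x, h, w) {
  d <- dim(x)
  dim(x) <- c(h, w, d[2], d[3])
  aperm(x, c(4, 3, 1, 2))
}

#' Initialise a two-layer stride-2 convolutional stem (total stride 4)
#'
#' @param C output channels; @param cin input channels.
#' @return parameter list (W1, b1, W2, b2); the stem acts independently on
#'   every segment (no mixing along L).
#' @export
stem_init <- function(C, cin = 1L) {
  C1 <- max(4L, C %/% 2L)
  list(W1 = he_init(C1, 9L * cin), b1 = numeric(C1),
       W2 = he_init(C, 9L * C1), b2 = numeric(C))
}

## Apply the stem to a (P, cin, L) grid at input size h x w.
stem_apply <- function(grid, p, h, w, cin = 1L) {
  C1 <- length(ad_val(p$b1))
  pl1 <- im2col_cached(h, w, cin, 3L, 2L, 1L)
  x <- ad_relu(conv2d(grid, pl1, p$W1, p$b1))
  pl2 <- im2col_cached(pl1$h_out, pl1$w_out, C1, 3L, 2L, 1L)
  ad_relu(conv2d(x, pl2, p$W2, p$b2))
}

#' Encode the straightened (CPR) image stream
#'
#' Shallow per-segment CNN stem; spatial resolution is reduced by the total
#' stride 4 (h = H/4, w = W/4) while L is untouched.
#'
#' @param xmpr L x H x W intensity array.
#' @param params stem parameters from [stem_init()].
#' @return feature grid of dim (h*w, C, L).
#' @export
encode_mpr <- function(xmpr, params) {
  xv <- ad_val(xmpr)
  if (length(dim(xv)) != 3L) stop("xmpr must be a L x H x W array")
  if (!all(is.finite(xv))) stop("non-finite input")
  L <- dim(xv)[1]; H <- dim(xv)[2]; W <- dim(xv)[3]
  grid <- ad_reshape(ad_aperm(ad_reshape(xmpr, c(L, H * W)), c(2, 1)),
                     c(H * W, 1L, L))
  stem_apply(grid, params, H, W, 1L)
}

#' Initialise the volumetric-stream collapse + stem parameters
#' @param C output channels; @param D depth of the volumetric patches.
#' @export
collapse_init <- function(C, D) {
  list(depth_w = rep(1 / D, D), stem = stem_init(C, 1L))
}

#' Encode the volumetric stream via a depth-wise collapse convolution
#'
#' A learnable kernel over the through-plane depth collapses each
#' L x D x H x W patch stack to L x H x W, which then passes through a 2-D
#' stem of the same geometry as the CPR stream, guaranteeing spatial
#' alignment of the two feature grids.
#'
#' @param x3d L x D x H x W array.
#' @param params list from [collapse_init()].
#' @return feature grid of dim (h*w, C, L).
#' @export
collapse_3d <- function(x3d, params) {
  xv <- ad_val(x3d)
  if (length(dim(xv)) != 4L) stop("x3d must be a L x D x H x W array")
  if (!all(is.finite(xv))) stop("non-finite input")
  L <- dim(xv)[1]; D <- dim(xv)[2]; H <- dim(xv)[3]; W <- dim(xv)[4]
  xd <- matrix(aperm(xv, c(2, 1, 3, 4)), D, L * H * W)
  x2 <- ad_matmul(ad_reshape(params$depth_w, c(1L, D)), xd)   # 1 x (L*H*W)
  grid <- ad_reshape(ad_aperm(ad_reshape(x2, c(L, H * W)), c(2, 1)),
                     c(H * W, 1L, L))
  stem_apply(grid, params$stem, H, W, 1L)
}

#' Initialise the bidirectional vessel Mamba encoder
#' @param d_in flattened token width C*h*w; @param d_model latent scan width;
#' @param state_dim SSM state size.
#' @export
biv_init <- function(d_in, d_model, state_dim = 16) {
  list(W_proj = glorot_init(d_in, d_model), b_proj = numeric(d_model),
       fwd = ssm_params(d_model, state_dim),
       bwd = ssm_params(d_model, state_dim),
       W_down = glorot_init(d_model, d_in), b_down = numeric(d_in))
}

#' Bidirectional vessel Mamba over the centerline sequence
#'
#' Each segment's C x h x w grid is flattened to a token, projected to the
#' latent width, scanned by two independent selective SSMs (proximal-to-
#' distal and distal-to-proximal), merged by elementwise sum, projected back
#' and added residually, then reshaped to the grid layout.
#'
#' @param fmap feature grid (h*w, C, L) — or (h*w, C, n_branch*L) for a
#'   batch of branches stacked along the segment dimension.
#' @param params list from [biv_init()].
#' @param n_branch number of stacked branches (each scanned independently).
#' @return feature grid of the same shape.
#' @export
biv_mamba <- function(fmap, params, n_branch = 1L) {
  d <- dim(ad_val(fmap)); P <- d[1]; C <- d[2]; Lt <- d[3]
  if (Lt < 1L) stop("empty sequence")
  L <- Lt %/% n_branch
  stopifnot(L * n_branch == Lt)
  tok <- ad_aperm(ad_reshape(fmap, c(P * C, Lt)), c(2, 1))      # Lt x Din
  tp <- linear(tok, params$W_proj, params$b_proj)
  dm <- length(ad_val(params$b_proj))
  tp3 <- ad_reshape(tp, c(L, n_branch, dm))
  hf <- ad_selective_scan(tp3, params$fwd)
  hb <- ad_flip1(ad_selective_scan(ad_flip1(tp3), params$bwd))
  h2 <- ad_reshape(ad_add(hf, hb), c(Lt, dm))
  out <- ad_add(tok, linear(h2, params$W_down, params$b_down))
  ad_reshape(ad_aperm(out, c(2, 1)), c(P, C, Lt))
}

#' Initialise the centerline positional-embedding MLP
#' @param C embedding width; @param hidden hidden width.
#' @export
pe_init <- function(C, hidden = 32L) {
  list(W1 = glorot_init(3L, hidden), b1 = numeric(hidden),
       W2 = glorot_init(hidden, C), b2 = numeric(C))
}

#' Project centerline coordinates to per-segment positional embeddings
#'
#' @param ppos L x 3 normalised coordinates.
#' @param params list from [pe_init()].
#' @param P if given, broadcast to a (P, C, L) map that is constant over the
#'   spatial positions.
#' @return L x C matrix, or a (P, C, L) grid when `P` is supplied.
#' @export
positional_embed <- function(ppos, params, P = NULL) {
  pv <- ad_val(ppos)
  if (!all(is.finite(pv))) stop("non-finite coordinates")
  pe <- linear(ad_tanh(linear(ppos, params$W1, params$b1)), params$W2, params$b2)
  if (is.null(P)) return(pe)
  pev <- ad_val(pe)
  zero <- array(0, c(P, ncol(pev), nrow(pev)))
  ad_add_chan(zero, pe)
}

#' Pairwise Euclidean distance matrix of centerline points
#' @param ppos L x 3 coordinate matrix.
#' @return symmetric L x L matrix with zero diagonal.
#' @export
distance_matrix <- function(ppos) {
  m <- as.matrix(stats::dist(ppos))
  dimnames(m) <- NULL
  m
}

#' Initialise the spatial-aware cross-attention (SAM) parameters
#' @param C channel width; @param d_attn query/key width;
#' @param lambda_init initial topological penalty strength (>= 0).
#' @export
sam_init <- function(C, d_attn = C, lambda_init = 1.0) {
  list(W_q = glorot_init(C, d_attn), W_k = glorot_init(C, d_attn),
       W_v = glorot_init(C, C),
       lambda_raw = log(expm1(lambda_init)),     # softplus reparameterisation
       ln_g = rep(1, C), ln_b = numeric(C))
}

#' Distance-biased cross-attention fusing the two streams
#'
#' Per-segment tokens are obtained by spatial average pooling; the CPR
#' stream provides queries and the volumetric stream keys and values.
#' Attention scores are softmax_j(q_i k_j / sqrt(d) - lambda*log(1 + D_ij)),
#' with lambda = softplus(lambda_raw) >= 0. The attended values are
#' broadcast over (h, w), added residually to the query stream and
#' layer-normalised over channels.
#'
#' @param f_seq,f_vol aligned feature grids (h*w, C, L).
#' @param ddist L x L distance matrix from [distance_matrix()].
#' @param params list from [sam_init()].
#' @param mask optional additional additive penalty matrix (L x L); used to
#'   block attention across branches when several branches are stacked.
#' @return list(fused = grid, attn = L x L row-stochastic matrix,
#'   lambda = scalar).
#' @export
spatial_cross_attention <- function(f_seq, f_vol, ddist, params, mask = NULL) {
  ds <- dim(ad_val(f_seq)); dv <- dim(ad_val(f_vol))
  if (!all(ds == dv)) stop("shape mismatch between streams")
  q <- ad_matmul(ad_gap(f_seq), params$W_q)
  k <- ad_matmul(ad_gap(f_vol), params$W_k)
  v <- ad_matmul(ad_gap(f_vol), params$W_v)
  dm <- ncol(ad_val(q))
  lambda <- ad_softplus(params$lambda_raw)
  scores <- ad_mul(ad_matmul(q, ad_aperm(k, c(2, 1))), 1 / sqrt(dm))
  scores <- ad_sub(scores, ad_mul(lambda, log1p(ddist)))
  if (!is.null(mask)) scores <- ad_sub(scores, mask)
  A <- ad_softmax_rows(scores)
  tok <- ad_matmul(A, v)
  fused <- ad_layernorm_chan(ad_add_chan(f_seq, tok), params$ln_g, params$ln_b)
  list(fused = fused, attn = A, lambda = lambda)
}
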