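## Synergistic spectral-morphological decoupling.
##
## The plaque (texture) pathway summarises each channel's spatial power
## spectrum into K concentric-ring energies, models inter-channel structure
## with a Mamba block over the channel axis, and emits a sigmoid channel
## gate. The stenosis (geometry) pathway predicts per-pixel sampling offsets
## from the fused + texture features and resamples the fused map with a
## bilinear kernel, shifting the receptive field onto the lumen boundary.

## Spectral plan: explicit 2-D DFT matrix (so the fingerprint is a chain of
## plain matrix products, differentiable and exactly checkable against
## stats::fft) plus mean-pooling ring masks on the unshifted frequency grid.
spectral_plan <- function(h, w, K) {
  cached(sprintf("spec_%d_%d_%d", h, w, K), function() {
    Wh <- exp(-2i * pi * outer(0:(h - 1), 0:(h - 1)) / h)
    Ww <- exp(-2i * pi * outer(0:(w - 1), 0:(w - 1)) / w)
    W2 <- kronecker(Ww, Wh)            # acts on vec(img), row index fastest
    fy <- ifelse(0:(h - 1) <= h / 2, 0:(h - 1), 0:(h - 1) - h)
    fx <- ifelse(0:(w - 1) <= w / 2, 0:(w - 1), 0:(w - 1) - w)
    r <- sqrt(outer(fy^2, fx^2, "+"))
    rn <- as.vector(r) / max(r)
    ring <- pmin(floor(rn * K) + 1L, K)
    counts <- tabulate(ring, nbins = K)
    if (any(counts == 0L))
      stop("K larger than the number of available radius bins for this grid")
    M <- matrix(0, h * w, K)
    M[cbind(seq_len(h * w), ring)] <- 1 / counts[ring]
    list(Wr = Re(W2), Wi = Im(W2), M = M, ring = ring, counts = counts)
  })
}

#' Ring-pooled spectral fingerprint of a feature grid
#'
#' For every (segment, channel) slice the squared magnitude of the 2-D DFT
#' is partitioned into K equal-width concentric rings by normalised radial
#' frequency (ring 1 contains DC) and mean-pooled per ring, yielding a
#' rotation-insensitive texture signature.
#'
#' @param fmap feature grid (h*w, C, L) (node or numeric).
#' @param K number of rings; every ring must contain at least one frequency bin.
#' @param h,w spatial extent (default: square grid).
#' @return array (or node) of dim (L, C, K) with nonnegative entries.
#' @export
spectral_fingerprint <- function(fmap, K, h = NULL, w = NULL) {
  d <- dim(ad_val(fmap)); P <- d[1]; C <- d[2]; L <- d[3]
  if (is.null(h)) { h <- as.integer(round(sqrt(P))); w <- h }
  stopifnot(h * w == P, h >= 2, w >= 2)
  pl <- spectral_plan(h, w, K)
  x2 <- ad_reshape(fmap, c(P, C * L))
  re <- ad_matmul(pl$Wr, x2)
  im <- ad_matmul(pl$Wi, x2)
  pw <- ad_add(ad_mul(re, re), ad_mul(im, im))      # squared magnitudes
  e <- ad_matmul(t(pl$M), pw)                        # K x (C*L), mean per ring
  ad_aperm(ad_reshape(e, c(K, C, L)), c(3, 2, 1))    # L x C x K
}

#' Initialise the frequency-band Mamba gating head
#' @param K ring count; @param d_model latent width of the channel-axis scan;
#' @param state_dim SSM state size.
#' @export
fb_gate_init <- function(K, d_model = 64L, state_dim = 16L) {
  list(W_embed = glorot_init(K, d_model), b_embed = numeric(d_model),
       mamba = mamba_block_init(d_model, d_model, state_dim),
       W_p = glorot_init(d_model, 1L), b_p = 0)
}

#' Spectral channel gate from ring-energy sequences
#'
#' Ring energies are embedded from K to a latent width, the channel axis is
#' treated as the sequence of a Mamba block (batched over segments), and the
#' latent state is projected to one scalar per (segment, channel) followed
#' by a sigmoid.
#'
#' @param sfreq array (L, C, K) from [spectral_fingerprint()].
#' @param params list from [fb_gate_init()].
#' @return texture gate, an L x C matrix with entries strictly in (0, 1).
#' @export
fb_mamba_gate <- function(sfreq, params) {
  d <- dim(ad_val(sfreq)); L <- d[1]; C <- d[2]; K <- d[3]
  dm <- length(ad_val(params$b_embed))
  tok <- ad_aperm(sfreq, c(2, 1, 3))                     # (C, L, K)
  emb <- linear(ad_reshape(tok, c(C * L, K)), params$W_embed, params$b_embed)
  hfreq <- mamba_block(ad_reshape(emb, c(C, L, dm)), params$mamba)
  s <- ad_add(ad_matmul(ad_reshape(hfreq, c(C * L, dm)), params$W_p), params$b_p)
  ad_aperm(ad_reshape(ad_sigmoid(s), c(C, L)), c(2, 1))  # L x C
}

#' Apply a texture gate to a feature grid
#'
#' Elementwise product with the per-(segment, channel) gate broadcast over
#' the spatial positions; never increases feature magnitude for gates in (0, 1).
#' @param fmap grid (h*w, C, L); @param gate L x C matrix.
#' @export
apply_texture_gate <- function(fmap, gate) {
  d <- dim(ad_val(fmap)); g <- dim(ad_val(gate))
  if (d[2] != g[2] || d[3] != g[1]) stop("shape mismatch between map and gate")
  ad_mul_chan(fmap, gate)
}

#' Initialise the offset-prediction convolution
#' @param C channels of each input grid.
#' @export
offsets_init <- function(C) {
  list(W_fused = matrix(0, 2L, 9L * C), W_tex = matrix(0, 2L, 9L * C),
       b = numeric(2L))
}

#' Predict per-pixel sampling offsets from fused + texture features
#'
#' One 3x3 convolution over the channel-concatenated inputs (implemented as
#' the sum of two convolutions) yields 2 offset channels (dy, dx) per pixel,
#' in pixel units.
#'
#' @param ffused,ftex aligned feature grids (h*w, C, L).
#' @param params list from [offsets_init()].
#' @param h,w spatial extent (default square).
#' @return offset field of dim (h*w, 2, L).
#' @export
predict_offsets <- function(ffused, ftex, params, h = NULL, w = NULL) {
  d <- dim(ad_val(ffused))
  if (!all(d == dim(ad_val(ftex)))) stop("shape mismatch")
  P <- d[1]; C <- d[2]
  if (is.null(h)) { h <- as.integer(round(sqrt(P))); w <- h }
  pl <- im2col_cached(h, w, C, 3L, 1L, 1L)
  a <- conv2d(ffused, pl, params$W_fused)
  b <- conv2d(ftex, pl, params$W_tex, params$b)
  ad_add(a, b)
}

#' Deformable bilinear resampling of a feature grid
#'
#' For each integer pixel p the fractional location p' = p + dp is sampled
#' by the separable bilinear kernel max(0, 1-|qx-p'x|) * max(0, 1-|qy-p'y|)
#' over the four integer neighbours of p'; neighbours outside the grid
#' contribute zero. Differentiable in both the features and the offsets.
#'
#' @param fmap feature grid (h*w, C, L).
#' @param dp offset field (h*w, 2, L): dp[, 1, ] rows (dy), dp[, 2, ] columns (dx).
#' @param h,w spatial extent (default square).
#' @return resampled grid of the same shape as `fmap`.
#' @export
deformable_sample <- function(fmap, dp, h = NULL, w = NULL) {
  Fv <- ad_val(fmap); dv <- ad_val(dp)
  d <- dim(Fv); P <- d[1]; C <- d[2]; L <- d[3]
  if (!all(is.finite(dv))) stop("offsets must be finite")
  if (!all(dim(dv) == c(P, 2L, L))) stop("offset field must be (h*w, 2, L)")
  if (is.null(h)) { h <- as.integer(round(sqrt(P))); w <- h }
  stopifnot(h * w == P)
  ip <- ((seq_len(P) - 1L) %% h) + 1L
  jp <- ((seq_len(P) - 1L) %/% h) + 1L
  yy <- ip + matrix(dv[, 1L, ], P, L)
  xx <- jp + matrix(dv[, 2L, ], P, L)
  i0 <- floor(yy); fy <- yy - i0
  j0 <- floor(xx); fx <- xx - j0
  corners <- list(
    list(ii = i0,     jj = j0,     w = (1 - fy) * (1 - fx), dwy = -(1 - fx), dwx = -(1 - fy)),
    list(ii = i0 + 1, jj = j0,     w = fy * (1 - fx),       dwy = (1 - fx),  dwx = -fy),
    list(ii = i0,     jj = j0 + 1, w = (1 - fy) * fx,       dwy = -fx,       dwx = (1 - fy)),
    list(ii = i0 + 1, jj = j0 + 1, w = fy * fx,             dwy = fx,        dwx = fy))
  ## computation runs in (P, L, C) layout (no per-corner aperm); the index
  ## values address the flat (P, C, L) storage of the feature grid
  loff <- matrix((0:(L - 1)) * P * C, P, L, byrow = TRUE)
  coff_plc <- array(rep((0:(C - 1)) * P, each = P * L), c(P, L, C))
  gathered <- vector("list", 4L)
  wts <- vector("list", 4L)
  idxs <- vector("list", 4L)
  valids <- vector("list", 4L)
  out_plc <- array(0, c(P, L, C))
  for (k in 1:4) {
    cr <- corners[[k]]
    valid <- (cr$ii >= 1 & cr$ii <= h & cr$jj >= 1 & cr$jj <= w)
    q <- pmin(pmax(cr$ii, 1), h) + (pmin(pmax(cr$jj, 1), w) - 1) * h
    idx <- array(q + loff, c(P, L, C)) + coff_plc
    wv <- array(cr$w * valid, c(P, L, C))
    gk <- array(Fv[idx], c(P, L, C))
    out_plc <- out_plc + gk * wv
    gathered[[k]] <- gk; wts[[k]] <- wv; idxs[[k]] <- idx; valids[[k]] <- valid
  }
  out <- aperm(out_plc, c(1, 3, 2))
  ad_apply(list(fmap, dp), out, function(g) {
    gp <- aperm(g, c(1, 3, 2))                       # (P, L, C)
    gdy <- matrix(0, P, L); gdx <- matrix(0, P, L)
    n <- P * C * L
    vals <- numeric(4L * n); grps <- integer(4L * n)
    for (k in 1:4) {
      cr <- corners[[k]]
      span <- (k - 1L) * n + seq_len(n)
      vals[span] <- as.vector(gp * wts[[k]])
      grps[span] <- as.vector(idxs[[k]])
      sc <- matrix(.rowSums(matrix(gp * gathered[[k]], P * L, C), P * L, C), P, L)
      gdy <- gdy + sc * cr$dwy * valids[[k]]
      gdx <- gdx + sc * cr$dwx * valids[[k]]
    }
    ## single padded scatter-add: padding makes every target index present,
    ## aligning the rowsum result with 1..(P*C*L)
    rs <- rowsum(c(vals, numeric(n)), group = c(grps, seq_len(n)), reorder = TRUE)
    gdp <- array(0, c(P, 2L, L))
    gdp[, 1L, ] <- gdy; gdp[, 2L, ] <- gdx
    list(array(rs[, 1], c(P, C, L)), gdp)
  })
}

#' Initialise the diagnostic heads
#' @param C channel width; @param hidden hidden width of each MLP head.
#' @export
heads_init <- function(C, hidden = 32L) {
  list(st = mlp2_init(C, hidden, 4L),
       pl = mlp2_init(C, hidden, 4L),
       gl = mlp2_init(C, hidden, 4L))
}

#' Task-specific diagnostic projections
#'
#' Spatial global average pooling collapses the geometry and texture grids
#' to per-segment vectors; two MLP + softmax heads give the 4-class stenosis
#' (from geometry) and plaque (from texture) distributions, and an auxiliary
#' head on the segment-averaged fused features gives one branch-level
#' stenosis distribution.
#'
#' @param ftex,fgeo,ffused feature grids (h*w, C, L) with matching L (or
#'   n_branch*L for stacked branches).
#' @param params list from [heads_init()].
#' @param n_branch number of stacked branches; the auxiliary head emits one
#'   branch-level distribution per branch.
#' @return list(pst L x 4, ppl L x 4, pglobal length-4 (or n_branch x 4),
#'   plus the raw logits and the pooled vectors vtex, vgeo).
#' @export
diagnostic_heads <- function(ftex, fgeo, ffused, params, n_branch = 1L) {
  vtex <- ad_gap(ftex)
  vgeo <- ad_gap(fgeo)
  Lt <- nrow(ad_val(vtex)); L <- Lt %/% n_branch
  st_logits <- mlp2(vgeo, params$st)
  pl_logits <- mlp2(vtex, params$pl)
  pool <- kronecker(diag(n_branch), matrix(1 / L, 1L, L))
  gv <- ad_matmul(pool, ad_gap(ffused))
  gl_logits <- mlp2(gv, params$gl)
  pg <- ad_softmax_rows(gl_logits)
  if (n_branch == 1L) {
    pg <- ad_reshape(pg, 4L)
    if (!is_node(pg)) pg <- as.numeric(pg)
  }
  list(pst = ad_softmax_rows(st_logits),
       ppl = ad_softmax_rows(pl_logits),
       pglobal = pg,
       st_logits = st_logits, pl_logits = pl_logits, gl_logits = gl_logits,
       vtex = vtex, vgeo = vgeo)
}
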