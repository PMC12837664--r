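## Full network: dual-stream topology-aware encoding -> spectral/
## morphological decoupling -> diagnostic heads.

#' Default model dimensions
#'
#' @param C stem channels; @param d_model latent width of the centerline
#'   scans; @param d_freq latent width of the channel-axis spectral scan;
#' @param K spectral ring count; @param state_dim SSM state size;
#' @param d_attn query/key width of the fusion attention;
#' @param head_hidden hidden width of the diagnostic MLPs.
#' @export
model_config <- function(C = 32L, d_model = 128L, d_freq = 64L, K = 8L,
                         state_dim = 16L, d_attn = 32L, head_hidden = 32L) {
  list(C = as.integer(C), d_model = as.integer(d_model),
       d_freq = as.integer(d_freq), K = as.integer(K),
       state_dim = as.integer(state_dim), d_attn = as.integer(d_attn),
       head_hidden = as.integer(head_hidden))
}

#' Initialise all network parameters
#'
#' @param mcfg list from [model_config()].
#' @param H,W cross-section size; @param D volumetric depth.
#' @param seed RNG seed for the initial weights.
#' @return nested list of numeric parameter arrays (class `vessel_net`).
#' @export
vessel_net_init <- function(mcfg, H, W, D, seed = 1L) {
  h <- H %/% 4L; w <- W %/% 4L
  d_in <- mcfg$C * h * w
  p <- with_seed(seed, list(
    stem_mpr = stem_init(mcfg$C),
    vol = collapse_init(mcfg$C, D),
    biv_seq = biv_init(d_in, mcfg$d_model, mcfg$state_dim),
    biv_vol = biv_init(d_in, mcfg$d_model, mcfg$state_dim),
    pe = pe_init(mcfg$C),
    sam = sam_init(mcfg$C, mcfg$d_attn),
    fb = fb_gate_init(mcfg$K, mcfg$d_freq, mcfg$state_dim),
    off = offsets_init(mcfg$C),
    heads = heads_init(mcfg$C, mcfg$head_hidden),
    log_var1 = 0,                      # log sigma1^2 (task-loss uncertainty)
    log_var2 = 0                       # log sigma2^2 (regulariser uncertainty)
  ))
  structure(c(p, list(h = h, w = w, H = H, W = W, D = D)), class = "vessel_net")
}

## Stack B branches along the segment dimension (constant inputs).
stack_branches <- function(samples) {
  B <- length(samples)
  d <- dim(samples[[1]]$xmpr); L <- d[1]
  D <- dim(samples[[1]]$x3d)[2]
  xm <- array(0, c(B * L, d[2], d[3]))
  x3 <- array(0, c(B * L, D, d[2], d[3]))
  pp <- matrix(0, B * L, 3L)
  for (b in seq_len(B)) {
    idx <- (b - 1L) * L + seq_len(L)
    xm[idx, , ] <- samples[[b]]$xmpr
    x3[idx, , , ] <- samples[[b]]$x3d
    pp[idx, ] <- samples[[b]]$ppos
  }
  list(xmpr = xm, x3d = x3, ppos = pp, B = B, L = L)
}

#' Forward pass of the network on one or several branches
#'
#' Several branches are processed as one stacked graph: the centerline scans
#' batch over branches, the fusion attention uses a block mask so segments
#' never attend across branches, and the auxiliary head pools per branch.
#'
#' @param params parameter tree from [vessel_net_init()] (leaves may be
#'   `ad_node`s during training or plain arrays for inference).
#' @param samples a list of `vessel_sample`s from the same geometry.
#' @param mcfg model dimensions from [model_config()].
#' @param texture_guidance if FALSE the texture features entering the offset
#'   predictor are replaced by zeros (ablation probe); the texture branch
#'   itself is untouched.
#' @return list with pst, ppl ((B*L) x 4), pglobal (B x 4), vgeo, vtex, the
#'   intermediate feature grids, spectral sequence, channel gate and fusion
#'   attention.
#' @export
net_forward_multi <- function(params, samples, mcfg, texture_guidance = TRUE) {
  h <- params$h; w <- params$w
  st <- stack_branches(samples)
  B <- st$B; L <- st$L
  empr <- encode_mpr(st$xmpr, params$stem_mpr)
  evol <- collapse_3d(st$x3d, params$vol)
  hseq <- biv_mamba(empr, params$biv_seq, n_branch = B)
  hvol <- biv_mamba(evol, params$biv_vol, n_branch = B)
  pe <- positional_embed(st$ppos, params$pe)
  fseq <- ad_add_chan(hseq, pe)
  fvol <- ad_add_chan(hvol, pe)
  dd <- matrix(0, B * L, B * L)
  mask <- matrix(1e4, B * L, B * L)
  for (b in seq_len(B)) {
    idx <- (b - 1L) * L + seq_len(L)
    dd[idx, idx] <- distance_matrix(samples[[b]]$ppos)
    mask[idx, idx] <- 0
  }
  sam <- spatial_cross_attention(fseq, fvol, dd, params$sam,
                                 mask = if (B > 1L) mask else NULL)
  ffused <- sam$fused
  sfreq <- spectral_fingerprint(ffused, mcfg$K, h, w)
  gate <- fb_mamba_gate(sfreq, params$fb)
  ftex <- apply_texture_gate(ffused, gate)
  ftex_in <- if (texture_guidance) ftex else array(0, dim(ad_val(ftex)))
  offsets <- predict_offsets(ffused, ftex_in, params$off, h, w)
  fgeo <- deformable_sample(ffused, offsets, h, w)
  out <- diagnostic_heads(ftex, fgeo, ffused, params$heads, n_branch = B)
  c(out, list(ffused = ffused, ftex = ftex, fgeo = fgeo, offsets = offsets,
              sfreq = sfreq, gate = gate, attn = sam$attn, lambda = sam$lambda,
              n_branch = B, L = L))
}

#' @rdname net_forward_multi
#' @param sample a single `vessel_sample`.
#' @export
net_forward <- function(params, sample, mcfg, texture_guidance = TRUE) {
  net_forward_multi(params, list(sample), mcfg, texture_guidance)
}
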