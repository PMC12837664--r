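# Shared fixtures: tiny phantom/model configurations and independent
# reference implementations used as oracles.

tiny_phantom_cfg <- function(L = 8L, seed = 11L, noise = 0.02, ...) {
  phantom_config(L = L, H = 16L, W = 16L, D = 4L, base_radius = 5,
                 noise_sigma = noise, seed = seed, ...)
}

tiny_model_cfg <- function() {
  model_config(C = 8L, d_model = 24L, d_freq = 12L, K = 4L, state_dim = 6L,
               d_attn = 8L, head_hidden = 12L)
}

tiny_net <- function(H = 16L, W = 16L, D = 4L, seed = 2L) {
  vessel_net_init(tiny_model_cfg(), H, W, D, seed = seed)
}

# Independently coded naive per-step recurrence for the selective scan
# (double loop over channels and states; no code shared with the package).
naive_selective_scan <- function(u, p) {
  N <- nrow(u); Dm <- ncol(u); S <- ncol(p$A_log)
  A <- -exp(p$A_log)
  h <- matrix(0, Dm, S)
  Y <- matrix(0, N, Dm)
  for (t in seq_len(N)) {
    ut <- u[t, ]
    z <- as.vector(ut %*% p$W_dt) + p$b_dt
    delta <- log1p(exp(z))
    Bt <- as.vector(ut %*% p$W_B)
    Ct <- as.vector(ut %*% p$W_C)
    for (d in seq_len(Dm)) for (s in seq_len(S)) {
      h[d, s] <- exp(delta[d] * A[d, s]) * h[d, s] + delta[d] * ut[d] * Bt[s]
    }
    Y[t, ] <- as.vector(h %*% Ct) + p$D * ut
  }
  Y
}

# Brute-force bilinear resampling oracle: explicit loop over positions,
# channels and the four integer neighbours with the truncated kernel.
naive_deform <- function(fmap, dp, h, w) {
  d <- dim(fmap); P <- d[1]; C <- d[2]; L <- d[3]
  out <- array(0, d)
  for (l in seq_len(L)) for (p in seq_len(P)) {
    iy <- ((p - 1) %% h) + 1
    jx <- ((p - 1) %/% h) + 1
    py <- iy + dp[p, 1, l]
    px <- jx + dp[p, 2, l]
    for (qy in floor(py) + 0:1) for (qx in floor(px) + 0:1) {
      g <- max(0, 1 - abs(qx - px)) * max(0, 1 - abs(qy - py))
      if (g > 0 && qy >= 1 && qy <= h && qx >= 1 && qx <= w) {
        q <- qy + (qx - 1) * h
        for (cc in seq_len(C)) out[p, cc, l] <- out[p, cc, l] + g * fmap[q, cc, l]
      }
    }
  }
  out
}

# Term-by-term attention oracle for the distance-biased fusion.
naive_attention <- function(q, k, v, D, lambda) {
  L <- nrow(q); dm <- ncol(q)
  A <- matrix(0, L, L)
  for (i in seq_len(L)) {
    s <- numeric(L)
    for (j in seq_len(L))
      s[j] <- sum(q[i, ] * k[j, ]) / sqrt(dm) - lambda * log(1 + D[i, j])
    e <- exp(s - max(s))
    A[i, ] <- e / sum(e)
  }
  list(A = A, out = A %*% v)
}

# Ring energies computed independently via stats::fft on one spatial slice.
naive_ring_energy <- function(img, K) {
  h <- nrow(img); w <- ncol(img)
  pw <- Mod(stats::fft(img))^2
  fy <- ifelse(0:(h - 1) <= h / 2, 0:(h - 1), 0:(h - 1) - h)
  fx <- ifelse(0:(w - 1) <= w / 2, 0:(w - 1), 0:(w - 1) - w)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  rn <- r / max(r)
  ring <- pmin(floor(rn * K) + 1, K)
  vapply(seq_len(K), function(k) mean(pw[ring == k]), numeric(1))
}

# A fine-grained profile with every grade present.
mixed_profile <- function(L) {
  g <- integer(L)
  g[2:3] <- 1L; g[5] <- 2L; g[7] <- 3L
  p <- integer(L)
  p[g > 0] <- c(1L, 2L, 3L, 1L)[seq_len(sum(g > 0))]
  list(stenosis = g, plaque = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
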