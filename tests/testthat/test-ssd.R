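# Spectral-morphological decoupling: ring energies, channel gate,
# deformable sampling, diagnostic heads.

test_that("spectral fingerprint localises energy in the expected rings", {
  h <- 16; w <- 16; K <- 8
  # constant map: all energy in the DC ring
  f <- array(3, c(h * w, 2, 3))
  sf <- spectral_fingerprint(f, K, h, w)
  expect_identical(dim(sf), c(3L, 2L, 8L))
  expect_true(all(sf[, , 1] > 0))
  expect_equal(max(abs(sf[, , 2:K])), 0)

  # planted sinusoid: energy lands in the ring containing its radius
  fx <- 4
  img <- matrix(cos(2 * pi * fx * (0:(w - 1)) / w), h, w, byrow = TRUE)
  sfs <- spectral_fingerprint(array(img, c(h * w, 1, 1)), K, h, w)
  rmax <- sqrt(2) * 8
  expected_ring <- floor(fx / rmax * K) + 1
  expect_identical(which.max(sfs[1, 1, ]), as.integer(expected_ring))
  off_rings <- sfs[1, 1, -c(1, expected_ring)]    # tolerate DC leakage only
  expect_lt(max(off_rings) / sfs[1, 1, expected_ring], 1e-20)
})

test_that("ring energies match an independent stats::fft oracle", {
  set.seed(30)
  h <- 8; w <- 8; K <- 6
  img <- matrix(rnorm(h * w), h, w)
  sf <- spectral_fingerprint(array(img, c(h * w, 1, 1)), K, h, w)
  expect_equal(as.vector(sf[1, 1, ]), naive_ring_energy(img, K), tolerance = 1e-10)
})

test_that("spectra are invariant to 90-degree rotation on square grids", {
  set.seed(31)
  h <- 8
  img <- matrix(rnorm(h * h), h, h)
  rot <- t(img)[h:1, ]                            # 90-degree rotation
  s1 <- spectral_fingerprint(array(img, c(h * h, 1, 1)), 4, h, h)
  s2 <- spectral_fingerprint(array(rot, c(h * h, 1, 1)), 4, h, h)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("ring-energy bookkeeping accounts for the total spectral energy", {
  set.seed(32)
  h <- 8; K <- 4
  f <- array(rnorm(h * h * 3 * 4), c(h * h, 3, 4))
  sf <- spectral_fingerprint(f, K, h, h)
  counts <- stenoscan:::spectral_plan(h, h, K)$counts
  for (l in 1:4) for (cc in 1:3) {
    tot <- sum(Mod(stats::fft(matrix(f[, cc, l], h, h)))^2)
    expect_equal(sum(sf[l, cc, ] * counts), tot, tolerance = 1e-4)
  }
})

test_that("K exceeding the available radius bins is rejected", {
  expect_error(spectral_fingerprint(array(1, c(16, 1, 1)), 6, 4, 4), "radius bins")
})

test_that("the spectral gate lies in (0,1) and is channel-order sensitive", {
  set.seed(33)
  L <- 5; C <- 6; K <- 4
  sf <- array(abs(rnorm(L * C * K)), c(L, C, K))
  fp <- fb_gate_init(K, 8L, 4L)
  g <- fb_mamba_gate(sf, fp)
  expect_identical(dim(g), c(5L, 6L))
  expect_true(all(g > 0 & g < 1))
  # zero projection weight: constant sigmoid(b_p)
  fp0 <- fp; fp0$W_p[] <- 0; fp0$b_p <- 0.3
  g0 <- fb_mamba_gate(sf, fp0)
  expect_equal(max(abs(g0 - 1 / (1 + exp(-0.3)))), 0)
  # permuting the channel sequence changes the gate
  perm <- c(3, 1, 2, 6, 5, 4)
  gp <- fb_mamba_gate(sf[, perm, ], fp)
  expect_gt(max(abs(gp - g[, perm])), 1e-9)
})

test_that("texture gating scales features elementwise and never amplifies", {
  set.seed(34)
  f <- array(rnorm(8 * 3 * 4), c(8, 3, 4))
  gate_half <- matrix(0.5, 4, 3)
  expect_equal(apply_texture_gate(f, gate_half), 0.5 * f)
  # hand-multiplied 2x2 case
  f22 <- array(c(1, 2, 3, 4), c(2, 2, 1))
  g22 <- matrix(c(0.2, 0.9), 1, 2)
  expect_equal(apply_texture_gate(f22, g22),
               array(c(0.2, 0.4, 2.7, 3.6), c(2, 2, 1)))
  g1 <- matrix(runif(12), 4, 3)
  out1 <- apply_texture_gate(f, g1)
  expect_true(all(abs(out1) <= abs(f) + 1e-15))
  # gating monotonicity: a smaller gate never increases magnitude
  out2 <- apply_texture_gate(f, g1 * 0.5)
  expect_true(all(abs(out2) <= abs(out1) + 1e-15))
  expect_error(apply_texture_gate(f, matrix(1, 3, 4)), "mismatch")
})

test_that("offset prediction yields two finite channels, zero for zero weights", {
  set.seed(35)
  C <- 4
  f1 <- array(rnorm(16 * C * 3), c(16, C, 3))
  f2 <- array(rnorm(16 * C * 3), c(16, C, 3))
  op <- offsets_init(C)                            # zero-initialised conv
  off0 <- predict_offsets(f1, f2, op, 4, 4)
  expect_identical(dim(off0), c(16L, 2L, 3L))
  expect_equal(max(abs(off0)), 0)
  op$W_fused[] <- rnorm(length(op$W_fused), sd = 0.1)
  op$W_tex[] <- rnorm(length(op$W_tex), sd = 0.1)
  off <- predict_offsets(f1, f2, op, 4, 4)
  expect_true(all(is.finite(off)))
  expect_gt(max(abs(off)), 0)
})

test_that("deformable sampling: identity, unit shift, averaging, oracle", {
  set.seed(36)
  h <- 4; w <- 4; P <- h * w; C <- 3; L <- 2
  f <- array(rnorm(P * C * L), c(P, C, L))
  dp0 <- array(0, c(P, 2, L))
  expect_identical(deformable_sample(f, dp0, h, w), f)   # bit-exact identity

  # integer offset (dy=0, dx=1): value at the right neighbour, zero at the edge
  dp1 <- dp0; dp1[, 2, ] <- 1
  out1 <- deformable_sample(f, dp1, h, w)
  expect_equal(out1[1:(P - h), , ], f[(h + 1):P, , ])
  expect_equal(max(abs(out1[(P - h + 1):P, , ])), 0)     # out of bounds -> 0

  # fractional offset 0.5 averages the two vertical neighbours
  dpf <- dp0; dpf[1, 1, 1] <- 0.5
  outf <- deformable_sample(f, dpf, h, w)
  expect_equal(outf[1, , 1], (f[1, , 1] + f[2, , 1]) / 2)

  # offsets landing exactly on grid points reproduce grid values
  dpg <- dp0; dpg[2, 1, 1] <- 1; dpg[2, 2, 1] <- 1
  outg <- deformable_sample(f, dpg, h, w)
  expect_identical(outg[2, , 1], f[2 + 1 + h, , 1])

  # brute-force oracle on random instances
  for (i in 1:10) {
    fr <- array(rnorm(P * C * L), c(P, C, L))
    dpr <- array(runif(P * 2 * L, -1.5, 1.5), c(P, 2, L))
    expect_lt(max(abs(deformable_sample(fr, dpr, h, w) -
                      naive_deform(fr, dpr, h, w))), 1e-6)
  }
  expect_error(deformable_sample(f, dp0 + NA, h, w), "finite")
})

test_that("diagnostic heads emit row-stochastic distributions from pooled features", {
  set.seed(37)
  C <- 6; L <- 5
  hp <- heads_init(C, 8L)
  ft <- array(rnorm(16 * C * L), c(16, C, L))
  fg <- array(rnorm(16 * C * L), c(16, C, L))
  ff <- array(rnorm(16 * C * L), c(16, C, L))
  out <- diagnostic_heads(ft, fg, ff, hp)
  expect_equal(rowSums(out$pst), rep(1, L), tolerance = 1e-6)
  expect_equal(rowSums(out$ppl), rep(1, L), tolerance = 1e-6)
  expect_equal(sum(out$pglobal), 1, tolerance = 1e-6)
  # constant maps collapse to identical rows
  fc <- array(1.3, c(16, C, L))
  outc <- diagnostic_heads(fc, fc, fc, hp)
  expect_equal(outc$pst, matrix(outc$pst[1, ], L, 4, byrow = TRUE))
  # GAP equals the arithmetic mean on a hand 2x2 grid
  g22 <- array(c(1, 2, 3, 4), c(4, 1, 1))
  expect_equal(as.vector(ad_gap(g22)), 2.5)
})

test_that("texture guidance ablation changes geometry but not the texture branch", {
  set.seed(38)
  cfg <- tiny_phantom_cfg()
  pr <- mixed_profile(cfg$L)
  s <- generate_branch(cfg, pr$stenosis, pr$plaque)
  net <- tiny_net()
  # the offset conv is zero-initialised by convention; give it weight so the
  # guidance pathway actually carries signal
  net$off$W_fused[] <- rnorm(length(net$off$W_fused), sd = 0.05)
  net$off$W_tex[] <- rnorm(length(net$off$W_tex), sd = 0.05)
  mcfg <- tiny_model_cfg()
  full <- net_forward(net, s, mcfg, texture_guidance = TRUE)
  abl <- net_forward(net, s, mcfg, texture_guidance = FALSE)
  expect_identical(abl$ftex, full$ftex)            # texture path bit-identical
  expect_identical(abl$ppl, full$ppl)
  expect_gt(max(abs(ad_val(abl$fgeo) - ad_val(full$fgeo))), 0)
  expect_gt(max(abs(abl$offsets - full$offsets)), 0)
})
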