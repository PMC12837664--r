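# Synthetic vessel phantom: determinism, label logic, geometric and
# spectral separability, artifacts, dataset assembly.

test_that("fixed seed gives byte-identical branches and datasets", {
  cfg <- tiny_phantom_cfg()
  pr <- mixed_profile(cfg$L)
  s1 <- generate_branch(cfg, pr$stenosis, pr$plaque)
  s2 <- generate_branch(cfg, pr$stenosis, pr$plaque)
  expect_identical(s1, s2)
  d1 <- generate_dataset(cfg, 3, 2)
  d2 <- generate_dataset(cfg, 3, 2)
  expect_identical(d1$samples, d2$samples)
})

test_that("branch label is the maximum segment grade and profiles are validated", {
  cfg <- tiny_phantom_cfg()
  s <- generate_branch(cfg, c(0, 0, 3, 0, 0, 1, 0, 0), c(0, 0, 2, 0, 0, 1, 0, 0))
  expect_identical(s$branch_stenosis, 3L)
  s0 <- generate_branch(cfg, rep(0L, 8), rep(0L, 8))
  expect_identical(s0$branch_stenosis, 0L)
  expect_error(generate_branch(cfg, c(1, rep(0, 7)), rep(0L, 8)), "plaque")
  expect_error(generate_branch(cfg, rep(0L, 7), rep(0L, 7)), "length")
  expect_error(generate_branch(cfg, c(4, rep(0, 7)), c(1, rep(0, 7))), "0..3")
})

test_that("an all-normal branch follows pure taper", {
  cfg <- tiny_phantom_cfg(L = 12L, noise = 0)
  cfg$taper_rate <- 0.02
  cfg$stenosis_grade_bands$normal <- c(0, 0)    # no reduction at grade 0
  s <- generate_branch(cfg, rep(0L, 12), rep(0L, 12))
  d <- measure_lumen_diameter(s)
  expect_true(all(diff(d) < 0))                 # strictly tapering
  r_expect <- 2 * cfg$base_radius * (1 - cfg$taper_rate * (0:11))
  expect_lt(max(abs(d - r_expect) / r_expect), 0.15)
})

test_that("lumen diameters order strictly by stenosis grade", {
  cfg <- tiny_phantom_cfg(L = 16L, noise = 0.01)
  cfg$taper_rate <- 0
  g <- rep(0:3, each = 4)
  p <- ifelse(g > 0, 2L, 0L)
  s <- generate_branch(cfg, g, p)
  d <- measure_lumen_diameter(s)
  for (gr in 0:2)
    expect_gt(min(d[g == gr]), max(d[g == gr + 1]))
})

test_that("ppos lies in the unit cube with monotone arc length", {
  cfg <- tiny_phantom_cfg(L = 20L)
  s <- generate_branch(cfg, rep(0L, 20), rep(0L, 20))
  expect_true(all(s$ppos >= 0 & s$ppos <= 1))
  arc <- cumsum(c(0, sqrt(rowSums(diff(s$ppos)^2))))
  expect_true(all(diff(arc) > 0))
})

test_that("calcified and non-calcified walls separate in high-frequency rings", {
  cfg <- tiny_phantom_cfg(L = 32L, seed = 31L)
  cfg$taper_rate <- 0
  gc <- rep(2L, 32)
  sc <- generate_branch(cfg, gc, rep(1L, 32), seed = 5)   # calcified
  sn <- generate_branch(cfg, gc, rep(2L, 32), seed = 6)   # non-calcified
  K <- 8L
  ring_hi <- function(s) {
    grid <- array(aperm(s$xmpr, c(2, 3, 1)), c(16 * 16, 1, 32))
    sf <- spectral_fingerprint(grid, K, 16, 16)
    rowSums(matrix(sf[, 1, (K / 2 + 1):K], nrow = 32))    # upper half rings
  }
  ec <- ring_hi(sc); en <- ring_hi(sn)
  # margin beyond the noise-driven spread, over >= 50 segments in total
  expect_gt(mean(ec) - mean(en), 2 * sqrt(stats::var(ec) + stats::var(en)))
  expect_true(all(ec > max(en)))
})

test_that("generated datasets never violate the stenosis-implies-plaque logic", {
  ds <- generate_dataset(tiny_phantom_cfg(seed = 41L), 10, 0)
  for (s in ds$samples)
    expect_false(any(s$seg_stenosis > 0 & s$seg_plaque == 0))
})

test_that("dataset counts, granularity and class mix behave as specified", {
  cfg <- tiny_phantom_cfg(L = 6L, seed = 51L)
  ds <- generate_dataset(cfg, 200, 150)
  expect_identical(nrow(ds$manifest), 350L)
  fine <- vapply(ds$samples, function(s) s$granularity == "fine", logical(1))
  expect_identical(sum(fine), 200L)
  expect_true(all(vapply(ds$samples[!fine],
                         function(s) is.null(s$seg_stenosis), logical(1))))
  dsc <- generate_dataset(cfg, 0, 5)
  expect_true(all(vapply(dsc$samples, function(s) s$granularity == "coarse",
                         logical(1))))
  expect_error(generate_dataset(cfg, 0, 0), "empty")

  # two seeds: different label sequences, same class-mix marginals
  cfg2 <- tiny_phantom_cfg(L = 6L, seed = 52L)
  ds2 <- generate_dataset(cfg2, 200, 150)
  expect_false(identical(ds$manifest$branch_stenosis, ds2$manifest$branch_stenosis))
  tab <- rbind(tabulate(ds$manifest$branch_stenosis + 1, 4),
               tabulate(ds2$manifest$branch_stenosis + 1, 4))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-3)
})

test_that("blooming injection brightens lumen-adjacent calcified tissue only", {
  cfg <- tiny_phantom_cfg(L = 8L, noise = 0)
  g <- c(0, 1, 1, 0, 0, 1, 1, 0)   # mild grades keep a wide lumen to bloom into

  cfg$blooming_prob <- 0
  sc <- generate_branch(cfg, g, ifelse(g > 0, 1L, 0L))
  expect_identical(inject_blooming(sc, cfg), sc)         # prob 0: no-op

  cfg$blooming_prob <- 1
  sb <- inject_blooming(sc, cfg)
  expect_identical(sb$seg_stenosis, sc$seg_stenosis)     # labels untouched
  lum <- function(s, l) {
    img <- s$xmpr[l, , ]
    r <- sc$lumen_radius[l]      # generator-recorded true lumen radius
    H <- nrow(img)
    cy <- (H + 1) / 2
    dist <- sqrt(outer((1:H - cy)^2, (1:H - cy)^2, "+"))
    mean(img[dist > r - 2 & dist <= r])
  }
  for (l in which(g > 0)) expect_gt(lum(sb, l), lum(sc, l))

  sn <- generate_branch(cfg, g, ifelse(g > 0, 2L, 0L))   # non-calcified only
  expect_identical(inject_blooming(sn, cfg)$xmpr, sn$xmpr)
})

test_that("configuration validation rejects malformed bands and sizes", {
  expect_error(phantom_config(L = 0), "positive")
  expect_error(phantom_config(base_radius = 40), "base_radius")
  expect_error(phantom_config(stenosis_grade_bands = list(
    normal = c(0, 0.3), mild = c(0.25, 0.49),
    moderate = c(0.5, 0.69), severe = c(0.7, 0.9))), "disjoint")
})

test_that("datasets round-trip through disk and label tables are consistent", {
  ds <- generate_dataset(tiny_phantom_cfg(L = 6L, seed = 61L), 3, 2)
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$samples, ds$samples)
  lab <- dataset_labels(ds)
  expect_identical(sum(lab$granularity == "fine"), 3L * 6L)
  fine1 <- lab[lab$branch_id == ds$manifest$branch_id[1], ]
  expect_identical(fine1$stenosis, ds$samples[[1]]$seg_stenosis)
  expect_identical(max(fine1$stenosis), ds$samples[[1]]$branch_stenosis)
  unlink(dir, recursive = TRUE)
})
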