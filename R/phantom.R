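## Synthetic straightened-vessel phantom generator.
##
## Emulates the structure of a curved-planar-reformation (CPR) coronary
## dataset at desk scale: a bright tubular lumen whose diameter narrows with
## stenosis grade, an atherosclerotic wall annulus whose texture encodes the
## plaque class (calcified = bright high-spatial-frequency speckle,
## non-calcified = dim homogeneous thickening, mixed = both), a tortuous
## centerline that displaces the volumetric patches in-plane, and a
## dual-granularity label scheme (per-segment vs branch-maximum stenosis).

#' Phantom generator configuration
#'
#' Grade bands are fractional diameter reductions following CAD-RADS-like
#' conventions: normal 0-24%, mild 25-49%, moderate 50-69%, severe >= 70%.
#' Intensities are normalised grayscale in [0, 1].
#'
#' @param L segments per branch; @param H,W cross-section size (pixels);
#' @param D through-plane depth of the volumetric patches.
#' @param base_radius healthy lumen radius in pixels.
#' @param taper_rate physiological per-segment fractional narrowing.
#' @param stenosis_grade_bands named list grade -> c(min, max) diameter reduction.
#' @param plaque_texture_params per-class list(mean, amp, freq): intensity
#'   mean, oscillation amplitude and spatial frequency band (cycles/pixel).
#' @param tortuosity_amp,tortuosity_freq centerline sinusoid parameters.
#' @param noise_sigma additive Gaussian noise scale.
#' @param blooming_prob,blooming_gain calcium-blooming injector parameters.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(L = 32L, H = 32L, W = 32L, D = 8L,
                           base_radius = 10,
                           taper_rate = 0.004,
                           stenosis_grade_bands = list(
                             normal   = c(0.00, 0.20),
                             mild     = c(0.25, 0.49),
                             moderate = c(0.50, 0.69),
                             severe   = c(0.70, 0.92)),
                           plaque_texture_params = list(
                             calcified    = list(mean = 0.85, amp = 0.30, freq = c(0.30, 0.45)),
                             noncalcified = list(mean = 0.38, amp = 0.03, freq = c(0.02, 0.06)),
                             mixed        = list(mean = 0.62, amp = 0.25, freq = c(0.30, 0.45))),
                           tortuosity_amp = 0.15, tortuosity_freq = 1.5,
                           noise_sigma = 0.02,
                           blooming_prob = 0.0, blooming_gain = 0.35,
                           seed = 1L) {
  cfg <- list(L = as.integer(L), H = as.integer(H), W = as.integer(W),
              D = as.integer(D), base_radius = base_radius,
              taper_rate = taper_rate,
              stenosis_grade_bands = stenosis_grade_bands,
              plaque_texture_params = plaque_texture_params,
              tortuosity_amp = tortuosity_amp, tortuosity_freq = tortuosity_freq,
              noise_sigma = noise_sigma,
              blooming_prob = blooming_prob, blooming_gain = blooming_gain,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (any(c(L, H, W, D) <= 0)) stop("all sizes must be positive")
    if (base_radius <= 0 || base_radius > min(H, W) / 2)
      stop("base_radius must be positive and fit in the cross-section")
    b <- do.call(rbind, stenosis_grade_bands)
    if (any(b[, 1] > b[, 2])) stop("grade bands must have min <= max")
    if (any(b[-1, 1] <= b[-nrow(b), 2])) stop("grade bands must be disjoint and increasing")
  })
  invisible(cfg)
}

## Run expr with a private, restored RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Render one cross-section. `center` shifts the lumen (pixels, (dy, dx)).
## Returns an H x W matrix in [0,1] before noise.
render_section <- function(cfg, radius, plaque, wall_thickness, center = c(0, 0),
                           tex_draw) {
  H <- cfg$H; W <- cfg$W
  cy <- (H + 1) / 2 + center[1]; cx <- (W + 1) / 2 + center[2]
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  img <- matrix(0.15, H, W)                        # wall/background tissue
  lumen <- 1 / (1 + exp(-(radius - dist) / 0.6))   # anti-aliased disc
  if (plaque > 0) {
    ann <- dist > radius & dist <= radius + wall_thickness
    if (plaque == 1L) {
      tex <- tex_draw$mean + tex_draw$amp *
        cos(2 * pi * tex_draw$f1 * xx + tex_draw$ph1) *
        cos(2 * pi * tex_draw$f2 * yy + tex_draw$ph2)
      img[ann] <- tex[ann]
    } else if (plaque == 2L) {
      tex <- tex_draw$mean + tex_draw$amp *
        cos(2 * pi * tex_draw$f1 * xx + tex_draw$ph1)
      img[ann] <- tex[ann]
    } else {                                       # mixed: calcified half, soft half
      texc <- tex_draw$mean_c + tex_draw$amp_c *
        cos(2 * pi * tex_draw$f1 * xx + tex_draw$ph1) *
        cos(2 * pi * tex_draw$f2 * yy + tex_draw$ph2)
      texn <- tex_draw$mean_n + tex_draw$amp_n *
        cos(2 * pi * tex_draw$f3 * xx + tex_draw$ph3)
      upper <- yy < cy
      img[ann & upper] <- texc[ann & upper]
      img[ann & !upper] <- texn[ann & !upper]
    }
  }
  img <- img * (1 - lumen) + 0.9 * lumen
  pmin(pmax(img, 0), 1)
}

## Sample per-segment texture phases/frequencies for one segment.
draw_texture <- function(cfg, plaque) {
  tp <- cfg$plaque_texture_params
  if (plaque == 1L) {
    p <- tp$calcified
    list(mean = p$mean, amp = p$amp,
         f1 = stats::runif(1, p$freq[1], p$freq[2]),
         f2 = stats::runif(1, p$freq[1], p$freq[2]),
         ph1 = stats::runif(1, 0, 2 * pi), ph2 = stats::runif(1, 0, 2 * pi))
  } else if (plaque == 2L) {
    p <- tp$noncalcified
    list(mean = p$mean, amp = p$amp,
         f1 = stats::runif(1, p$freq[1], p$freq[2]),
         ph1 = stats::runif(1, 0, 2 * pi))
  } else if (plaque == 3L) {
    pc <- tp$calcified; pn <- tp$noncalcified
    list(mean_c = pc$mean, amp_c = pc$amp, mean_n = pn$mean, amp_n = pn$amp,
         f1 = stats::runif(1, pc$freq[1], pc$freq[2]),
         f2 = stats::runif(1, pc$freq[1], pc$freq[2]),
         f3 = stats::runif(1, pn$freq[1], pn$freq[2]),
         ph1 = stats::runif(1, 0, 2 * pi), ph2 = stats::runif(1, 0, 2 * pi),
         ph3 = stats::runif(1, 0, 2 * pi))
  } else NULL
}

## Tortuous centerline in [0,1]^3, arc-length parameterised.
make_centerline <- function(cfg) {
  L <- cfg$L
  t <- seq(0, 1, length.out = L)
  x <- cfg$tortuosity_amp * sin(2 * pi * cfg$tortuosity_freq * t)
  y <- 0.5 * cfg$tortuosity_amp * cos(2 * pi * cfg$tortuosity_freq * t)
  z <- t
  pts <- cbind(x, y, z)
  ## reparameterise by arc length so consecutive rows advance monotonically
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg)); s <- s / max(s)
  xs <- stats::approx(s, pts[, 1], xout = t)$y
  ys <- stats::approx(s, pts[, 2], xout = t)$y
  zs <- stats::approx(s, pts[, 3], xout = t)$y
  p <- cbind(xs, ys, zs)
  ## min-max normalise each axis into [0,1] (constant axes map to 0)
  apply(p, 2L, function(v) if (diff(range(v)) < 1e-12) rep(0, length(v))
        else (v - min(v)) / diff(range(v)))
}

#' Generate one synthetic vessel branch
#'
#' @param cfg a [phantom_config()].
#' @param grade_profile length-L stenosis grades in 0..3
#'   (0 normal, 1 mild, 2 moderate, 3 severe).
#' @param plaque_profile length-L plaque classes in 0..3
#'   (0 absent, 1 calcified, 2 non-calcified, 3 mixed); segments with
#'   stenosis > 0 must carry plaque > 0.
#' @param seed RNG seed for this branch (defaults to `cfg$seed`).
#' @return object of class `vessel_sample` with fields `xmpr` (L x H x W),
#'   `x3d` (L x D x H x W), `ppos` (L x 3), `seg_stenosis`, `seg_plaque`,
#'   `branch_stenosis`, `granularity`.
#' @export
generate_branch <- function(cfg, grade_profile, plaque_profile, seed = cfg$seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  L <- cfg$L
  if (length(grade_profile) != L || length(plaque_profile) != L)
    stop("profiles must have length L")
  if (!all(grade_profile %in% 0:3) || !all(plaque_profile %in% 0:3))
    stop("labels must lie in 0..3")
  if (any(grade_profile > 0 & plaque_profile == 0))
    stop("stenosis > 0 requires plaque > 0 (clinical logic)")
  bands <- do.call(rbind, cfg$stenosis_grade_bands)
  with_seed(seed, {
    xmpr <- array(0, c(L, cfg$H, cfg$W))
    x3d <- array(0, c(L, cfg$D, cfg$H, cfg$W))
    ppos <- make_centerline(cfg)
    amp_px <- cfg$tortuosity_amp * cfg$H / 4
    lumen_radius <- numeric(L)
    for (l in seq_len(L)) {
      g <- grade_profile[l]
      red <- stats::runif(1, bands[g + 1, 1], bands[g + 1, 2])
      r0 <- cfg$base_radius * (1 - cfg$taper_rate * (l - 1))
      r <- r0 * (1 - red)
      lumen_radius[l] <- r
      wall <- max(1.5, r0 - r + 1.5)
      tex <- draw_texture(cfg, plaque_profile[l])
      xmpr[l, , ] <- render_section(cfg, r, plaque_profile[l], wall,
                                    center = c(0, 0), tex_draw = tex)
      tl <- (l - 1) / max(1, L - 1)
      for (d in seq_len(cfg$D)) {
        td <- tl + (d - (cfg$D + 1) / 2) / max(1, L * cfg$D)
        cy <- amp_px * sin(2 * pi * cfg$tortuosity_freq * td)
        cx <- amp_px * cos(2 * pi * cfg$tortuosity_freq * td) * 0.5
        x3d[l, d, , ] <- render_section(cfg, r, plaque_profile[l], wall,
                                        center = c(cy, cx), tex_draw = tex)
      }
    }
    if (cfg$noise_sigma > 0) {
      xmpr <- pmin(pmax(xmpr + stats::rnorm(length(xmpr), sd = cfg$noise_sigma), 0), 1)
      x3d <- pmin(pmax(x3d + stats::rnorm(length(x3d), sd = cfg$noise_sigma), 0), 1)
    }
    structure(list(xmpr = xmpr, x3d = x3d, ppos = ppos,
                   seg_stenosis = as.integer(grade_profile),
                   seg_plaque = as.integer(plaque_profile),
                   branch_stenosis = as.integer(max(grade_profile)),
                   granularity = "fine",
                   lumen_radius = lumen_radius),
              class = "vessel_sample")
  })
}

#' @export
print.vessel_sample <- function(x, ...) {
  cat("<vessel_sample ", x$granularity, ", L=", dim(x$xmpr)[1],
      ", branch stenosis grade ", x$branch_stenosis, ">\n", sep = "")
  invisible(x)
}

## Estimate the lumen radius of a cross-section: largest radius at which at
## least 80% of pixels inside the disc are bright.
estimate_lumen_radius <- function(img) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  best <- 0
  for (r in seq(1, min(H, W) / 2 - 1, by = 0.5)) {
    inside <- dist <= r
    if (mean(img[inside] > 0.6) >= 0.8) best <- r else break
  }
  best
}

## 3 x 3 maximum filter.
maxfilter3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- matrix(-Inf, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- img
  out <- img
  for (di in 0:2) for (dj in 0:2) {
    out <- pmax(out, p[(1 + di):(H + di), (1 + dj):(W + dj)])
  }
  out
}

bloom_section <- function(img, gain, r, center = c(0, 0)) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2 + center[1]; cx <- (W + 1) / 2 + center[2]
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  bright <- img > 0.75 & dist > r + 0.5          # calcified wall signal
  if (!any(bright)) return(img)
  dil <- maxfilter3(img * bright)
  pmin(img + gain * dil * (!bright), 1)
}

#' Inject calcium-blooming artifacts into a vessel sample
#'
#' Dilates high-intensity (calcified/mixed) wall signal of affected segments
#' into adjacent pixels, including the lumen, without touching the labels.
#' Segments without bright wall voxels are unchanged, and with
#' `blooming_prob = 0` the sample is returned identically. Requires the
#' per-segment plaque labels and rendered lumen radii the generator attaches
#' (so only wall signal, never the lumen itself, is dilated); samples
#' lacking them are returned unchanged with a message.
#'
#' @param sample a `vessel_sample`.
#' @param cfg a [phantom_config()] providing `blooming_prob`, `blooming_gain`.
#' @param seed RNG seed for the per-segment Bernoulli gates.
#' @export
inject_blooming <- function(sample, cfg, seed = cfg$seed + 7L) {
  stopifnot(inherits(sample, "vessel_sample"))
  if (cfg$blooming_prob <= 0 || cfg$blooming_gain == 0) return(sample)
  if (is.null(sample$seg_plaque) || is.null(sample$lumen_radius)) {
    message("blooming skipped: segment plaque labels/geometry unavailable")
    return(sample)
  }
  L <- dim(sample$xmpr)[1]
  with_seed(seed, {
    gate <- stats::runif(L) < cfg$blooming_prob & sample$seg_plaque %in% c(1L, 3L)
    for (l in which(gate)) {
      r <- sample$lumen_radius[l]
      sample$xmpr[l, , ] <- bloom_section(sample$xmpr[l, , ], cfg$blooming_gain, r)
      for (d in seq_len(dim(sample$x3d)[2]))
        sample$x3d[l, d, , ] <- bloom_section(sample$x3d[l, d, , ],
                                              cfg$blooming_gain, r)
    }
    sample
  })
}

## Sample a segment-level grade profile whose maximum equals `gmax`.
sample_profile <- function(L, gmax) {
  grades <- integer(L)
  if (gmax > 0) {
    n_lesions <- sample(1:3, 1)
    centers <- sample(seq_len(L), n_lesions)
    peak <- sample(n_lesions, 1)
    for (i in seq_len(n_lesions)) {
      len <- sample(2:6, 1)        # focal to diffuse lesion extents
      idx <- pmax(1L, pmin(L, centers[i] + seq_len(len) - (len + 1L) %/% 2L))
      g <- if (i == peak) gmax else sample(seq_len(gmax), 1)
      grades[idx] <- pmax(grades[idx], g)
    }
  }
  plaques <- integer(L)
  plaques[grades > 0] <- sample(1:3, sum(grades > 0), replace = TRUE)
  list(stenosis = grades, plaque = plaques)
}

#' Generate a dual-granularity synthetic vessel dataset
#'
#' Coarse samples carry only the branch-maximum stenosis grade; fine samples
#' carry per-segment stenosis and plaque labels as well. One branch per
#' (synthetic) patient.
#'
#' @param cfg a [phantom_config()].
#' @param n_fine,n_coarse number of branches per annotation granularity.
#' @param class_mix length-4 probability vector over branch-maximum grades.
#' @return object of class `vessel_dataset`: list(samples, manifest) where
#'   `manifest` is a data.frame(branch_id, patient_id, granularity,
#'   branch_stenosis).
#' @export
generate_dataset <- function(cfg, n_fine, n_coarse,
                             class_mix = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(inherits(cfg, "phantom_config"), n_fine >= 0, n_coarse >= 0)
  n <- n_fine + n_coarse
  if (n == 0) stop("empty dataset request")
  class_mix <- class_mix / sum(class_mix)
  samples <- vector("list", n)
  man <- data.frame(branch_id = sprintf("br%04d", seq_len(n)),
                    patient_id = sprintf("pt%04d", seq_len(n)),
                    granularity = rep(c("fine", "coarse"), c(n_fine, n_coarse)),
                    branch_stenosis = NA_integer_,
                    stringsAsFactors = FALSE)
  with_seed(cfg$seed, {
    gmax <- sample(0:3, n, replace = TRUE, prob = class_mix)
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    for (i in seq_len(n)) {
      prof <- sample_profile(cfg$L, gmax[i])
      s <- generate_branch(cfg, prof$stenosis, prof$plaque, seed = seeds[i])
      if (cfg$blooming_prob > 0)
        s <- inject_blooming(s, cfg, seed = seeds[i] + 7L)
      if (i > n_fine) {
        s$seg_stenosis <- NULL
        s$seg_plaque <- NULL
        s$granularity <- "coarse"
      }
      samples[[i]] <- s
      man$branch_stenosis[i] <- s$branch_stenosis
    }
  })
  structure(list(samples = samples, manifest = man, cfg = cfg),
            class = "vessel_dataset")
}

#' @export
print.vessel_dataset <- function(x, ...) {
  cat("<vessel_dataset ", nrow(x$manifest), " branches (",
      sum(x$manifest$granularity == "fine"), " fine / ",
      sum(x$manifest$granularity == "coarse"), " coarse)>\n", sep = "")
  invisible(x)
}

#' Per-segment label table of a dataset
#'
#' @param ds a `vessel_dataset`.
#' @return data.frame(branch_id, segment_idx (0-based), stenosis, plaque,
#'   granularity); coarse branches contribute one row with NA segment fields.
#' @export
dataset_labels <- function(ds) {
  rows <- lapply(seq_along(ds$samples), function(i) {
    s <- ds$samples[[i]]
    id <- ds$manifest$branch_id[i]
    if (s$granularity == "fine") {
      data.frame(branch_id = id, segment_idx = seq_along(s$seg_stenosis) - 1L,
                 stenosis = s$seg_stenosis, plaque = s$seg_plaque,
                 branch_stenosis = s$branch_stenosis,
                 granularity = "fine", stringsAsFactors = FALSE)
    } else {
      data.frame(branch_id = id, segment_idx = NA_integer_,
                 stenosis = NA_integer_, plaque = NA_integer_,
                 branch_stenosis = s$branch_stenosis,
                 granularity = "coarse", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write a dataset to disk (arrays as RDS, labels as CSV, manifest as JSON)
#' @param ds a `vessel_dataset`; @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ds$samples, file.path(dir, "samples.rds"))
  utils::write.csv(dataset_labels(ds), file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"), dataframe = "rows")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir directory.
#' @export
read_dataset <- function(dir) {
  samples <- readRDS(file.path(dir, "samples.rds"))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  structure(list(samples = samples, manifest = manifest), class = "vessel_dataset")
}

#' Measure the effective lumen diameter of phantom cross-sections
#'
#' Area-equivalent diameter of the bright central disc, computed on the
#' anti-aliased rendering so that it varies continuously with the true
#' radius.
#' @param sample a `vessel_sample`.
#' @return length-L numeric vector of diameters in pixels.
#' @export
measure_lumen_diameter <- function(sample) {
  L <- dim(sample$xmpr)[1]
  vapply(seq_len(L), function(l) {
    img <- sample$xmpr[l, , ]
    r <- estimate_lumen_radius(img)
    H <- nrow(img); W <- ncol(img)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
    near <- dist <= r + 2
    ## soft area: rescale intensities between wall (0.15) and lumen (0.9)
    a <- sum(pmin(pmax((img[near] - 0.15) / 0.75, 0), 1))
    2 * sqrt(a / pi)
  }, numeric(1))
}
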