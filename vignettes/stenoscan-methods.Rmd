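---
title: "Coronary lesion assessment on straightened vessel sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary lesion assessment on straightened vessel sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Coronary CT angiography (CCTA) assessment asks two questions about every
segment of an artery: how narrowed is the lumen (stenosis grade: normal,
mild, moderate, severe), and what is the wall made of (plaque class: absent,
calcified, non-calcified, mixed). Clinically these are answered on
curved-planar-reformation (CPR) images — the artery "straightened" along its
centerline — together with small volumetric patches around each centerline
point. Two properties make the task awkward for conventional image
classifiers. First, severity is *relative*: whether a segment is narrowed
depends on the calibre of the vessel proximal and distal to it, so
long-range context along the centerline matters. Second, the two answers are
entangled in the pixels: bright calcium both signals plaque composition and,
through blooming artifacts, corrupts the apparent lumen geometry.

`stenoscan` implements a hierarchical network that addresses both, together
with the mixed-grained supervision needed in practice, where only a minority
of branches carry per-segment expert labels while the rest carry a single
branch-level maximum-stenosis grade from the clinical report.

# Architecture

Inputs per branch are a triplet: the CPR stack `xmpr` (L x H x W), sliding
volumetric patches `x3d` (L x D x H x W) and normalised centerline
coordinates `ppos` (L x 3). Feature maps are stored spatial-major as
(h*w, C, L) arrays.

## Topology-aware dual-stream encoding

Both image streams pass through shallow two-layer stride-2 convolutional
stems (total stride 4) that act independently per segment; the volumetric
stream is first collapsed over depth by a learnable depth kernel so the two
feature grids are spatially aligned. Each stream is then scanned along the
centerline by a **bidirectional selective state-space (Mamba-style)
encoder**: per segment, the C x h x w grid is flattened to a token,
projected to a latent width, and processed by two independent selective
scans — proximal-to-distal (following blood flow, accumulating the upstream
reference calibre) and distal-to-proximal (propagating the patent distal
calibre backwards) — whose outputs are summed, down-projected and added
residually. The scan is the diagonal-state selective recurrence

    delta_t = softplus(u_t W_dt + b_dt)
    h_t     = exp(delta_t A) * h_{t-1} + (delta_t u_t) B_t,   A = -exp(A_log)
    y_t     = <h_t, C_t> + D u_t

with input-dependent `B_t = u_t W_B`, `C_t = u_t W_C`. It is implemented as
an explicit per-step recurrence with a hand-derived
backpropagation-through-time rule; both directions are exact mirrors
(flip, scan, flip).

Centerline coordinates are embedded by a small MLP into one vector per
segment and broadcast over the spatial positions of both streams. Fusion
uses a **distance-biased cross-attention**: per-segment pooled tokens of the
CPR stream query the volumetric stream, and the pre-softmax scores are
penalised by `lambda * log(1 + D_ij)` where `D` is the Euclidean distance
matrix of the centerline points and `lambda = softplus(lambda_raw) >= 0` is
learnable. Segments that look alike but are anatomically far apart (e.g.
two calcifications at opposite ends of the artery) are thereby discouraged
from exchanging features. The attended values are broadcast back over
(h, w), added residually and layer-normalised over channels.

## Spectral-morphological decoupling

The fused features feed two task branches.

*Texture (plaque) branch.* For every (segment, channel) slice the squared
magnitude of the 2-D DFT is pooled into K concentric rings of normalised
radial frequency (ring 1 contains DC), giving a rotation-insensitive
spectral signature: calcified speckle concentrates energy in high-frequency
rings, homogeneous soft-plaque thickening in low ones. The ring vectors are
embedded and a Mamba block is run *across the channel axis* (channels as the
sequence, segments as the batch), after which a linear head plus sigmoid
yields one gate per (segment, channel). Multiplying the fused grid by this
gate gives the texture features; their spatially pooled vectors drive the
4-class plaque head.

We implement the DFT as an explicit (h*w) x (h*w) matrix so the whole
spectral path is a chain of matrix products — differentiable by
construction and exactly checkable against `stats::fft`, which the test
suite does. Ring pooling uses the mean of squared magnitudes per ring, so
ring energy times ring population recovers the total spectral energy
(a Parseval-style bookkeeping identity that is also tested).

*Geometry (stenosis) branch.* The fused and texture features jointly
predict per-pixel sampling offsets (a 3x3 convolution, zero-initialised),
which drive **deformable bilinear resampling** of the fused grid: each pixel
is replaced by the bilinear interpolation of the four integer neighbours of
its offset location, with the truncated kernel
`max(0, 1-|dx|) * max(0, 1-|dy|)` and zero contribution outside the grid.
This lets the receptive field slide onto the true lumen boundary even when
soft plaque blurs it; because the texture features act only as a *prior*
for the offsets, switching them off (`texture_guidance = FALSE`) changes
the geometry branch while leaving the texture branch bit-identical — a
decoupling probe asserted exactly in the tests. Spatially pooled geometry
vectors drive the 4-class stenosis head, and a parallel head on the pooled
fused features emits one auxiliary branch-level stenosis distribution.

The auxiliary head has 4 classes, matching the smooth-max aggregate it is
compared against in the consistency loss.

## Mixed-grained supervision

Fine-grained branches contribute the strong loss: mean cross-entropy of the
stenosis head plus `lambda_pl` times that of the plaque head
(`lambda_pl = 1` by default; no printed value exists for it).

Coarse branches contribute through **dynamic grade prototypes**: a 4 x C
bank of geometric feature centroids, initialised by K-means (K = 4,
`stats::kmeans`, clusters matched to grades greedily by label counts, grade
means as fallback for unsupported grades) on the pooled geometric embeddings
of the fine subset after a warm-up phase, then updated on every strong batch
by EMA `m_k <- mu m_k + (1 - mu) vbar_k` with `mu = 0.99`. Each segment of
a coarse branch is scored by cosine similarity to the prototypes; a
severity-aware mixture (weights proportional to `exp(max_k S_lk)`)
aggregates softmaxed similarity rows into one branch distribution whose
cross-entropy against the branch label is the weak loss, back-propagated
through the similarities into the encoder.

Two logical regularisers apply to all branches: a **mutual-exclusion loss**
penalising probability mass on "stenosis without plaque" (and, as written,
its converse; a `mutex_unidirectional` switch drops the converse term), and
a **hierarchical consistency loss**, the mean squared difference between the
LogSumExp smooth maximum (temperature `alpha = 10`) of the per-segment
stenosis distributions and the auxiliary branch-level head. The total is
uncertainty-weighted,

    L = L_task / (2 sigma1^2) + (L_mutex + L_cons) / (2 sigma2^2) + log(sigma1 sigma2),

with `L_task` switching between strong and weak per batch and
`log(sigma^2)` trained jointly with the network by Adam.

Batches are homogeneous in granularity (the mixing of fine and coarse
within one batch is unspecified in the clinical protocol we follow, and
homogeneous batches keep the task-loss switch exact). Several branches are
processed as one stacked graph: the scans batch natively, the fusion
attention receives a block mask so segments never attend across branches,
and per-branch pooling matrices keep the branch-level quantities separate;
batch-of-one and stacked forwards agree exactly and this equivalence is
tested.

# The phantom generator

The in-house CCTA cohort the architecture was designed for is not
distributable, so the package ships a generator of synthetic straightened
vessels that reproduces the *structure each component is designed to
detect*:

* a bright (0.9) anti-aliased lumen disc per cross-section with radius
  `base_radius * (1 - taper_rate (l-1)) * (1 - reduction)`, where the
  fractional diameter reduction is drawn from CAD-RADS-like grade bands
  (normal 0–20%, mild 25–49%, moderate 50–69%, severe 70–92%; the bands are
  deliberately disjoint so grades are geometrically realisable);
* a plaque annulus around the lumen with class-specific texture: calcified
  = bright high-spatial-frequency two-dimensional speckle, non-calcified =
  dim near-homogeneous thickening, mixed = one half of each. Frequencies
  and phases are randomised per segment within class-specific bands;
* a sinusoidal, arc-length-parameterised centerline whose in-plane
  displacement is applied to the volumetric patches (the CPR stack is, by
  construction, centred — exactly the distortion/rectification relationship
  the fusion attention exploits);
* additive Gaussian noise, intensity clipping to [0, 1], and an optional
  calcium-blooming injector that dilates bright wall signal of
  calcified/mixed segments into adjacent pixels (including the lumen)
  without touching labels;
* dual-granularity labels: fine branches carry per-segment stenosis and
  plaque labels, coarse branches only the branch-maximum stenosis grade.
  Lesions are contiguous runs of 2–6 segments, one to three per diseased
  branch — focal to diffuse extents typical of segmental reporting.

Defaults (`L = 32`, `H = W = 32`, `D = 8`, `base_radius = 10 px`,
`noise_sigma = 0.02`) are desk-scale choices; no crop sizes or intensity
calibration are published for the original cohort, and intensities are
normalised grayscale without HU calibration. Class conventions are fixed
throughout: stenosis 0–3 = normal/mild/moderate/severe; plaque 0–3 =
absent/calcified/non-calcified/mixed, with "absent" serving as the fourth
plaque class of the 4-class head for healthy segments. Segment indexing in
tables is 0-based.

What the phantom does *not* emulate: scanner- and vendor-specific noise
spectra, contrast-timing variability, motion artifacts, bifurcations and
branch-tree topology, eccentric or crescentic lumen shapes, and the
inter-observer ambiguity of adjacent grades. Passing the phantom
experiments therefore demonstrates that the implementation can learn the
intended geometric and spectral cues end-to-end — not clinical-grade
performance on real CCTA.

# Numerical and design choices

* **Autodiff.** No automatic-differentiation framework for R is part of the
  package's dependency set, so training runs on a small reverse-mode engine
  included in the package: operators carry vector-Jacobian closures, and a
  depth-first post-order traversal accumulates gradients. Every rule —
  including the hand-derived backward passes of the selective scan and of
  the bilinear deformable sampler — is verified against central finite
  differences in the test suite. The bilinear kernel has a derivative
  discontinuity exactly at integer offsets; the analytic backward uses the
  right-hand derivative there, which is immaterial after the first
  optimiser step.
* **Attention reading.** The distance bias indexes segments, so queries,
  keys and values are per-segment tokens obtained by spatial average
  pooling; the attended values are broadcast over (h, w) before the
  residual. Only this reading makes the L x L distance matrix dimensionally
  consistent. Single-head attention is used, as in the formulation.
* **Scan merge.** Forward and backward scan outputs are summed before the
  down-projection; `lambda` is initialised at 1.0 under its softplus
  reparameterisation.
* **Ring geometry.** Radius is normalised by the maximum representable
  radius; K equal-width annuli; a K that leaves an empty annulus on the
  given grid is rejected. Mean pooling (rather than sum) was chosen so ring
  values are comparable across ring populations; the bookkeeping identity
  above makes the convention auditable.
* **Out-of-bounds sampling.** Neighbours outside the grid contribute zero
  (the truncated kernel), with no coordinate clamping.
* **Zero-denominator metrics** report 0 with a warning.
* **Degenerate inputs.** Empty sequences are errors; zero-norm vectors in
  cosine similarities score 0 under an epsilon guard (1e-8); non-finite
  losses abort training with a diagnostic.
* **Splitting.** The held-out test set is drawn exclusively from
  fine-grained branches, stratified by branch grade; the development pool is
  divided into folds stratified by granularity and grade via round-robin
  over shuffled strata. One branch per synthetic patient, so patient-level
  and branch-level exclusivity coincide.

# Training protocol and problem sizes

The configuration defaults reproduce the reference protocol (Adam, learning
rate 1e-4, batch size 3, 800 epochs, `alpha = 10`, `mu = 0.99`, warm-up =
first 10% of epochs). The package's own experiments — the test suite and
`scripts/acceptance.R` — use desk-scale settings chosen once for CPU
training: 16 x 16 crops, L = 32 segments, C = 16 stem channels, scan width
48, state size 8, K = 4 rings on the 4 x 4 feature grid, Adam at 2.5e-3
with batches of 6 branches, 15–16 epochs on cohorts of 160–240 branches.
Under these conditions the network reaches held-out segment-level macro-F1
around 0.87–0.95 for stenosis grading and ~1.0 for plaque typing on easy
phantoms. On a 25% fine / 75% coarse cohort, enabling the weak-supervision
pathway improves the held-out accuracy of the auxiliary branch-level head
(the model's branch prediction) over strong-only training, median over
seeds — unsurprisingly, since under strong-only training that head receives
no gradient at all. The max-of-segments branch rule, by contrast, does
*not* benefit at these problem sizes (see limitations); both rules are
always reported.

# Known limitations

* The engine is CPU-bound and desk-scale; it is a faithful, testable
  implementation of the method, not a performance port.
* The selective scan uses the sequential recurrence, not a fused parallel
  kernel; complexity is linear in L but with interpreter constants.
* Prototypes are maintained for stenosis grades only; plaque classes have
  no bank.
* The blooming injector requires the generator's per-segment geometry
  (labels and rendered lumen radii); applied to a stripped coarse sample it
  is a no-op with a message.
* With very few fine branches the K-means initialisation can lack support
  for a grade; the fallback (grade mean, or zero with a message) keeps
  training going but weakens the weak-supervision signal.
* At desk-scale epoch budgets the weak branch-level pathway does not improve
  — and can degrade — per-segment grading and the max-of-segments branch
  rule. Two mechanisms are visible in experiments: the severity-aware
  aggregation weights (softmax of maximal cosine similarity) are nearly
  uniform while features are young, so the branch-level cross-entropy drags
  the majority-normal segments of a diseased branch toward the branch grade;
  and cosine similarity to the prototypes discards feature magnitude, which
  is where short-trained geometric features mainly encode lumen calibre.
  A third dynamic compounds them: the uncertainty weight `sigma1` is shared
  between the strong and the weak task loss, so once coarse batches arrive
  with their largely irreducible cross-entropy, `sigma1` grows and the
  strong segment-level supervision is down-weighted while features keep
  moving under the weak and logical gradients. All three effects are
  expected to fade over hundreds of epochs, which is the scale of the
  reference protocol but beyond a CPU test suite; the acceptance pipeline
  therefore uses a long strong warm-up, a short mixed phase and
  best-validation checkpointing. The benefit of the coarse labels shows up
  where they act directly: the auxiliary branch-level head.
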