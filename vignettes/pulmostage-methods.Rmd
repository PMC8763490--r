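---
title: "pulmostage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pulmostage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmostage)
```

# Scope

`pulmostage` implements a desk-scale pipeline for lung-nodule analysis on
CT-like scalar images: region-based active-contour segmentation, nodule
measurement, deterministic TNM staging, a from-scratch multilayer CNN stage
classifier, and a stratified cross-validation harness. A synthetic phantom
generator stands in for clinical data so that every stage is testable,
reproducible and fast. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions that were
genuinely open — including what the synthetic world does *not* establish
about performance on real scans.

# The segmentation model

## Energy

The segmenter evolves a level-set field $\varphi$ on the image grid; the
contour is the zero level set, and by package convention $\varphi < 0$
*inside* the object. The energy is the two-phase piecewise-constant
(Mumford–Shah / Chan–Vese) approximation

$$
E(I_1, I_2, \varphi) \;=\; \sum_x \big(f(x) - I_1\big)^2\, H_\varepsilon(-\varphi)
\;+\; \sum_x \big(f(x) - I_2\big)^2 \big(1 - H_\varepsilon(-\varphi)\big)
\;+\; \gamma \sum_x H_\varepsilon(-\varphi)
\;+\; \beta \sum_x \delta_\varepsilon(\varphi)\,\lvert\nabla \varphi\rvert ,
$$

with a smoothed step $H_\varepsilon(t) = \tfrac12\big(1 +
\tfrac{2}{\pi}\arctan(t/\varepsilon)\big)$ and its derivative
$\delta_\varepsilon$. The literature writes the inside weight as
$H(\varphi)$ and the outside weight as $H(-\varphi)$ under the opposite
sign convention; under ours these are `Hin` $= H_\varepsilon(-\varphi)$ and
$1 - {}$`Hin` — the two forms are identical because
$H_\varepsilon(-t) = 1 - H_\varepsilon(t)$. The arctan form has global
support: its derivative is nowhere zero, so the scattered seed squares of
the default initialization feel image forces everywhere.

$I_1$ and $I_2$ are the mean intensities inside and outside the contour.
With a finite `kernel_sigma`, both become spatially varying Gaussian-kernel
weighted means (a localized variant for inhomogeneous backgrounds); with
the default infinite kernel they are global averages and the model is the
classical two-phase one. `region_intensity_inside()` /
`region_intensity_outside()` expose exactly these weighted-mean
expressions and are verified against brute-force summation in the tests.

## Evolution and numerics

Descent is explicit Euler on the Dirac-gated variational derivative

$$
\varphi \leftarrow \varphi + s\,\delta_\varepsilon(\varphi)\Big[
(f - I_1)^2 - (f - I_2)^2 + \gamma + \beta\,\kappa \Big],
$$

with curvature $\kappa = \nabla\!\cdot\!\big(\nabla\varphi /
\lvert\nabla\varphi\rvert\big)$ by central differences (denominator floored
at `grad_floor`, and $\kappa$ clamped to $\pm 1$, the tightest curvature a
unit grid can represent — unclamped values are discretization noise from
flat regions and destabilize the explicit step). Several numerical choices
deserve explanation because they depart from a textbook implementation, in
each case for a measured reason:

* **Intensities refresh in the sharp limit.** $I_1, I_2$ are refreshed
  every iteration from the binary partition $\{\varphi < 0\}$ — the
  $\varepsilon \to 0$ limit of the weighted-mean expressions — rather than
  from the smoothed indicator. With the smoothed indicator, the global
  arctan tails of thousands of background pixels carry more total weight
  than a nodule a few pixels wide, so $I_1$ would never represent a small
  object: a 4-pixel nodule is annihilated within two iterations. The sharp
  refresh is what the common two-phase implementations use.
* **Normalized step with backtracking.** The raw update is rescaled so the
  largest per-pixel change equals `dt` (a uniform positive factor that
  preserves the descent direction), and a candidate step that *raises* the
  energy is rejected and retried from the last accepted state at half the
  step (recovering by a factor 1.2 on acceptance). The rescaling traverses
  the long, nearly flat early phase of the seed initialization in a few
  iterations; the backtracking makes the recorded energy trace
  non-increasing by construction and gives a principled settling point
  when no usable step remains.
* **Stopping.** Primary: relative energy change below `rel_tol` over a
  `window` of accepted iterations. Secondary: no net change of the binary
  mask over `mask_stable` accepted iterations (snapshot comparison, so a
  flickering boundary pixel does not defeat it). The secondary rule exists
  because the smoothed-Heaviside tails keep draining energy long after the
  segmentation itself has settled — a pure energy criterion stops very
  late.
* **Reinitialization.** Every `reinit_every` accepted iterations the field
  is rebuilt as the exact signed distance (Felzenszwalb–Huttenlocher
  transform) of the current mask. Reinitialization changes the energy of
  the smoothed functional, so the trace carries a `reinit` marker and the
  descent bookkeeping restarts there.
* **Intensity normalization.** `levelset_evolve()` affinely maps the slice
  to $[0,1]$ before evolving, so `gamma`, `beta_len` and `dt` are
  intensity-scale free. The exposed `levelset_energy()` works on raw
  values (its oracle tests depend on that); the energy *trace* refers to
  the normalized image.

## Initialization: seeds, a second start, and a noise filter

The default initialization tiles the grid with 55 seed squares and takes
the signed distance to their union. Scattered seeds make the evolution
independent of a user-placed contour, but they have a structural blind
spot: a uniform seed pattern samples a small object and its background at
the same rate, so $I_1 \approx I_2$ exactly and the data force vanishes —
an unstable equilibrium that large objects escape (their asymmetry grows)
and small ones do not. Two measures address this:

* **Two-start selection.** When no explicit `phi0` is given, a second
  evolution starts from an intensity-threshold seed (midpoint between the
  median and the maximum intensity) and the result with the lower *sharp*
  two-region energy (within-region sums of squares plus the
  boundary-length penalty) is kept. The sharp energy is used for the
  comparison because the smoothed functional's global tails penalize any
  small object relative to an empty segmentation.
* **Contrast-to-noise filter.** The two-region energy always profits from
  claiming the upper tail of pure noise, so some region appears even in
  nodule-free slices. Components whose mean contrast over the background
  median is below `min_cnr` (default 4) background MADs are dropped; a
  nodule at the modelled noise level ($\sigma = c/8$) sits at CNR 8, twice
  the cutoff, while noise-tail regions sit near 2. On noise-free images
  the MAD is zero and any positive-contrast component is kept, so faint
  (nonsolid) nodules survive in clean data; on noisy data the cutoff is a
  deliberate detection threshold and is configurable.

Default parameters: `gamma = 0` (no area bias; collapse of stray regions
is handled by the curvature term and the CNR filter — a positive `gamma`
is available and makes contours collapse on homogeneous images),
`beta_len = 0.05`, `epsilon = 1.5` grid units, `dt = 1`, `max_iter = 500`,
`rel_tol = 1e-5` over `window = 10`, `mask_stable = 25`,
`reinit_every = 20`. On 64×64 phantom slices the evolution typically
settles in 25–75 accepted iterations (15–40 ms).

The parametric snake energy (tension $\alpha\int \lvert C'\rvert^2$,
rigidity $\beta\int \lvert C''\rvert$, edge attraction $-\mu \int \lvert
\nabla f\rvert^2$) is provided as an auxiliary diagnostic with a simple
gradient-descent evolution; the level set is the production path. The
rigidity term is evaluated with $\lvert C''\rvert$ unsquared, as the model
this package implements states it, with `squared_rigidity = TRUE`
switching to the classical form.

# Measurement and staging

Nodule size is reported two ways: the 3D volume-equivalent diameter and
the maximal in-plane area-equivalent diameter. *Staging uses the in-plane
value*, because TNM size is a longest-dimension convention and a thin slab
truncates thick nodules in depth; the 3D value is reported alongside.

Roundness is $4\pi A / P^2$. The perimeter $P$ is measured as the length
of the 0.5-level contour of the Gaussian-smoothed mask (σ = 1 px,
marching-squares extraction), falling back to the raw mask contour for
structures thinner than the kernel. A naive pixel-edge count overestimates
$P$ for curved boundaries by up to 8%, which would cap disc roundness near
0.89; a 4-direction Crofton estimate fixes discs but *underestimates*
square perimeters enough to push square roundness to 0.89 (vs. the
continuum π/4 ≈ 0.785). The smoothed sub-pixel contour is the estimator
that gets both right (discs ≥ 0.99, squares ≈ 0.82, a 1×20 bar ≈ 0.14) and
decreases monotonically with ellipse eccentricity. For nodules only a few
pixels across the perimeter underestimate can push roundness a few percent
above 1 (e.g. 1.02–1.03 for a 12-pixel disc); values near or above 1
should simply be read as "disc-like".

Solidity typing compares mean in-mask contrast against a reference (full
solid) contrast: ≥ 75% solid, ≥ 40% semisolid, below that nonsolid, ties
going to the upper class. The generator realizes semisolid nodules as a
full-contrast core with a half-contrast rim over the outer 30% of the
radius (in-mask mean ≈ 74.5%), and nonsolid nodules at a uniform 35%
contrast. The nonsolid fraction sits deliberately *below* the 40%
threshold rather than on it: a realization exactly at the boundary would
be typed semisolid by the tie rule. When no reference contrast is given it
is estimated from the 99th percentile of in-mask contrast — appropriate
for solid-core nodules, but a uniformly faint nodule then normalizes to
itself and types as solid; pass the nominal tissue contrast where known.

Staging is a pure lookup. `tu_category()` maps size in cm to TU1a…TU4 with
*upper-inclusive* boundaries at 1, 2, 3, 4, 5 and 7 cm (exactly 3 cm is
TU1c). `stage_group()` maps (TU, LN, DM) to the stage grid, with any
distant metastasis overriding: DM1 → 4A, DM2 → 4B regardless of TU/LN; the
TU4 row reads 3A for both LN0 and LN1, as published. A TU0/DM0 descriptor
yields the `STAGE_NONE` sentinel rather than a stage. The full table has
11 labels; the documented coarse grouping (1A1/1A2/1A3 → 1A, 4A/4B → 4)
yields 8 — the classifier's class count is therefore a free configuration
parameter, and the benchmark uses 9 distinct fine labels (below).

# The classifier

Architecture: `n_blocks` (default 6) of [3×3 convolution, same padding →
ReLU → 2×2 max-pool, stride 2] → flatten → dropout (0.2) → fully connected
(4096) → ReLU → fully connected (`n_classes`) → softmax, trained with
momentum SGD (0.9) on the softmax cross-entropy, learning rate
`lr0 · 10^(−⌊epoch/10⌋)`, batch size 10, early stopping on validation loss
(patience 10, best weights restored), and global gradient-norm clipping
(`clip_norm = 5` on the mean-over-batch gradient). The clipping matters:
with sparse masked inputs, a single oversized early step — amplified by
momentum — can push every hidden unit into the dead half of the ReLU and
freeze training at the uniform prediction; three of ten benchmark folds
died this way before clipping was added. The depth axis of the (H × W ×
depth) input is treated as the channel axis of 2D convolutions — the
minimal consistent reading of a "depth"-described input; there is no 3D
convolution. Spatial size shrinks only through pooling, so H and W must be
divisible by $2^{n\_blocks}$ (256 → 4, 64 → 1 after six blocks).

Implementation notes: the numeric core is compiled (im2col + GEMM per
sample for the convolutions; the fully connected head is batched so its
large weight matrices stream through memory once per minibatch). All
randomness — He initialization, per-epoch shuffling, dropout masks — is
drawn from R's RNG under the configured seed, making training bit-for-bit
reproducible. The classifier head is initialized at zero so an untrained
network scores exactly the uniform distribution (initial loss
$\log n_{classes}$); hidden layers are He-initialized. The per-sample
im2col caches of one minibatch are held in memory, about 40 MB at
64×64×8 and batch 10 (about 3 GB at the full 256×256×8 — within an 8 GB
budget but the dominant memory consumer).

Unstated choices, fixed as: channel progression doubling from 8 to 256 for
the full-size input (`mcnn_config()`); momentum SGD rather than an
adaptive optimizer, so the stepped schedule is meaningful; the classifier
consumes the background-subtracted, max-normalized *masked image* (a
channel-stacking alternative would carry image + mask separately; the
masked image is the minimal reading of "send the segmented image to the
classifier"). Max-normalization makes nodule tissue sit near intensity 1
regardless of acquisition contrast, decoupling the size signal from the
contrast draw.

# The synthetic world

`generate_phantom()` renders one ellipsoidal nodule of stated diameter and
contrast into a uniform parenchyma background plus additive Gaussian
noise, centred in the slab (the clinical protocol this emulates centres a
region of interest on the nodule; a centre-jitter argument exists).
Intensity units are arbitrary and recorded as such — no Hounsfield
calibration is claimed. Diameters 4–20 mm and contrasts 20–65 cover the
published simulated-nodule characteristics; sampling is uniform within the
stated intervals.

The 9-class benchmark (`default_class_map()`) bins nodule diameter into
nine disjoint intervals aligned with the TU boundaries: seven bins under
LN0/DM0 reach stages 1A1–3A, and the two largest bins carry DM1 and DM2
metadata reaching 4A and 4B — nine distinct labels, all separable by size
alone, which is essential because LN/DM are metadata codes with no image
realization. Slabs are 64×64×8 at 2.5 mm spacing (a 16 cm field of view
holding the 12 cm upper bin), noise defaults to contrast/8 per item (the
stated noisy test condition), and thick nodules truncate in depth, which
is why staging uses the in-plane diameter.

What a green benchmark does *not* establish: phantoms have uniform
backgrounds — no vasculature, airways, pleural wall, or mediastinum (the
clinical preprocessing step that removes those structures has no stated
algorithm and is left as a hook); nodules are ellipsoids without
spiculation or juxtapleural attachment; LN/DM are labels, not images; and
the class structure is size-determined by construction. Accuracy here
measures the pipeline's mechanics — segmentation fidelity, measurement
calibration, training dynamics — not clinical discrimination. Published
accuracy figures on clinical collections are not reproducible from this
package and are not claimed.

For the cross-validation budget the benchmark configuration
(`mcnn_benchmark_config()`) halves the channel progression to 4–128: the
size-binning task needs far less capacity than either progression, and the
halving keeps a full 10-fold run (150 training epochs over 900 volumes)
inside a single-CPU time budget. The harness accounts 15 epochs per fold —
150 epochs overall at k = 10 — while a standalone training defaults to 30
epochs; both are configurable, reflecting the two stated epoch budgets.

# Evaluation conventions

`stratified_kfold()` deals each shuffled class round-robin, so per-class
counts across folds differ by at most one. `confusion_metrics()` reports
accuracy plus one-vs-rest sensitivity (= recall; both column names are
emitted), specificity, precision and FPR, macro-averaged by default
(micro via argument) and in percent; undefined ratios become `NA` with a
warning, never silent zeros. `auc()` is the rank (Mann–Whitney) form with
midrank ties, macro-averaged one-vs-rest for multiclass scores.
`cross_validate()` trains one model per fold from scratch and emits
per-fold rows plus their exact arithmetic mean; an optional per-fold
modality tag is bookkeeping only.

# Known limitations

* The level-set model is two-phase: one object class against one
  background class per slice. Multiple nodules end up as one mask with
  several components (the pipeline keeps the largest by default).
* 2D slices are segmented independently; the 3D mask is the slice stack.
  No 3D level-set regularization across slices.
* The CNR filter is a detection threshold: nodules below 4 background MADs
  of contrast in noisy data are deliberately rejected as
  indistinguishable from noise.
* The localized (finite `kernel_sigma`) intensity model uses the
  simplified per-pixel data term, not the doubly integrated localized
  energy; it is an option, not the default path.
* File I/O is text-based (ASCII PGM slices + JSON sidecars, CSV tables).
  The series reader implements the medical-series contract
  (per-slice files, spacing metadata, position-sorted assembly) but no
  binary medical formats.
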