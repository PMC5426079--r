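---
title: "Segmenting ultrasound tumors with moorgb: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting ultrasound tumors with moorgb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moorgb)
```

## The problem

B-mode ultrasound images of tumors are hard to segment automatically:
speckle (multiplicative interference texture), low signal-to-noise ratio,
smooth intensity inhomogeneity, and posterior acoustic shadowing all
confound purely region-based or purely edge-based methods.  `moorgb`
implements a compound approach: a graph-based region-merging segmenter
whose two control parameters are tuned *per image* by particle swarm
optimization (PSO) under an objective that mixes region statistics with
boundary-gradient information.

The only prior knowledge used is a rectangular region of interest — the
*tumor-centered image* (TCI) — chosen so the lesion is fully contained and
roughly centered.  That single assumption anchors everything downstream:
the candidate tumor is always the segmented region that owns the TCI's
central pixel.

## Pipeline

1. **Crop** the TCI from the frame (`crop_tci()`).
2. **Enhance**: bilateral filter (speckle reduction), global histogram
   equalization (contrast), pyramid mean shift (homogeneity), in that
   order (`preprocess_pipeline()`).
3. **Segment** with the MST region-merging predicate at a candidate
   `(k, alpha)` (`segment()`).
4. **Score** the candidate by the three-term objective
   (`evaluate_candidate()`).
5. **Optimize** `(k, alpha)` by PSO (`pso_optimize()`), normalization
   factors fixed once from the initial swarm.
6. **Refine** the winning reference region by morphological opening and
   closing; keep the central component; trace the contour
   (`postprocess_mask()`).
7. **Evaluate** against a truth mask, when one exists
   (`metrics_report()`).

`run_moorgb()` executes 1-7; everything is deterministic for a fixed
configuration seed.

## The merge predicate

Pixels are vertices; edges join 4-neighbours (8 by config) with weight
$|I_a - I_b|$.  Edges are visited in non-descending weight order and the
two regions joined by an edge are merged iff

$$\mathrm{Dif}(C_1, C_2) = |\mu(C_1) - \mu(C_2)| \;\le\;
  \min_i\big(\sigma(C_i) + \tau(C_i)\big), \qquad
  \tau(C) = \frac{k}{|C|}\Big(1 + \frac{\mu(C)/\sigma(C)}{\alpha}\Big).$$

Larger `k` raises the threshold (easier merging, fewer regions); larger
`alpha` lowers it.  Three conventions close gaps the formula leaves open:

* $\sigma = 0$ (singleton or uniform region) makes $\beta = \mu/\sigma$
  undefined; we set $\beta := 0$, so $\tau$ falls back to the size
  threshold $k/|C|$.  This keeps the internal tolerance finite, so strong
  edges between uniform seed regions are still respected.
* $\sigma$ is the population standard deviation — well defined (zero) for
  single pixels.
* The edge sort is stable with ties broken by construction order
  (row-major scan, right-edge before down-edge), making partitions
  bit-reproducible.  Region statistics are carried as running sums, so a
  merge is O(1); a brute-force reference implementation that recomputes
  every statistic from raw pixels verifies the incremental path
  edge-for-edge in the test suite.

The grouping of the $\tau$ formula is ambiguous in its typeset source; the
reading above is the one for which the stated monotonicities (τ grows with
`k`, shrinks with `alpha`) actually hold.

## The objective

With the reference region $C_{\mathrm{Ref}}$ (the region owning the
central pixel) and $P(C) = |C|/|\mathrm{TCI}|$:

* **Between-class variance** $V_B = \sum_i P(C_i)\,(\mu(C_i) -
  \mu(C_\mathrm{Ref}))^2$ over the regions 4-adjacent to the reference —
  maximize contrast with the surroundings (this term alone is the older
  single-objective variant, recovered exactly with weights `(1, 0, 0)`).
* **Within-class variance** $V_W = \arctan(\mathrm{var}(C_\mathrm{Ref})) /
  P(C_\mathrm{Ref})$ — minimize heterogeneity, with the area fraction in
  the denominator penalizing small reference regions so minimization does
  not collapse the region.  The arctan compresses the raw variance to the
  scale of the area fraction.  The typeset source is ambiguous between
  dividing and multiplying by $P$; dividing is the only form that
  penalizes small regions under minimization (and the only one that
  reproduces the published oversegmentation pattern of the
  weight-sensitivity experiment), so it is the default; the multiplier
  form is selectable (`p_form = "multiply"`) for sensitivity checks.
* **Average gradient** $G_A$: mean Sobel magnitude (3×3 kernel,
  $\sqrt{g_x^2+g_y^2}$, replicate padding) over the *inner 4-boundary* of
  the reference region (member pixels touching non-members; the image
  border counts as outside) — pull the contour to strong edges.

The combined fitness $F_O = a V_B/f_B - b V_W/f_W + c G_A/f_A$ (defaults
$a=0.3, b=0.3, c=0.4$) is maximized.  The normalization factors
$f_B, f_W, f_A$ are the swarm means of the raw terms over the *initial*
particle grid, computed once per image before the first iteration; a zero
mean (degenerate image) is replaced by 1 with a warning.

A consequence worth knowing: if the reference region is *exactly* uniform,
$V_W = 0$ regardless of its size.  On mean-shift-flattened 8-bit images,
exactly uniform plateaus exist, so the degenerate weighting `(0, 1, 0)`
can converge to a tiny plateau that morphology then erases (the pipeline
reports a degenerate-convergence error).  The balanced default weights are
not affected — $V_B$ and $G_A$ both punish such candidates — and
`weight_sweep()` records collapsed runs as segmenting nothing.

## The optimizer

Standard global-best PSO over the box $k \in [100, 4000]$,
$\alpha \in [0.001, 4]$: velocity
$v \leftarrow w v + c_1 r_1 (p_i - x) + c_2 r_2 (p_g - x)$, position
$x \leftarrow x + v$, with $c_1 = c_2 = 0.5$ and inertia decaying linearly
from 1.0 to 0.2 over `t_max = 200` generations.  The run stops early when
the global best is stationary for 4 consecutive generations (stationary =
movement below 1e-9 in box-normalized coordinates; exact equality is
fragile in floating point).

Choices the published description leaves open, fixed here:

* *Initialization* is a deterministic uniform grid at cell centers (20×10
  for 200 particles; the factor pair closest to a 2:1 ratio in general),
  which makes the normalization factors image-deterministic.  Seeded
  uniform-random placement is available by config, and is the automatic
  fallback for swarm sizes with no usable factorization.
* $r_1, r_2$ are drawn independently per particle, per dimension, per
  generation.
* Out-of-box positions are clamped to the boundary and the clamped
  component's velocity is zeroed, so particles do not stick to walls.
* Identical positions are evaluated once per image (a pure cache; the grid
  start makes duplicates common).
* The inertia formula is evaluated from the $w_{\min}$ end
  ($w = w_{\min} + (w_{\max}-w_{\min})(1 - t/T_{\max})$), algebraically
  identical but exact at both endpoints in floating point.

## Postprocessing

The reference-region mask is opened then closed with a fixed 5×5
"elliptical" structuring element — the 13-cell discrete disk
$\{(dx,dy): dx^2+dy^2 \le 4\}$ (note: some libraries ship a 17-cell
variant under the same name; the kernel here is fixed in code for
reproducibility).  Opening removes spicules, closing fills holes.  Because
morphology can split a mask, a guard keeps the component containing the
image center (or the largest one if the center went to background); this
guard is an extension beyond the published pipeline, on by default.  The
contour is traced by a clockwise radial-sweep walk of the outer boundary.

## Evaluation metrics

Volume fractions against a truth mask $A_m$ (segmentation $A_n$):
$\mathrm{TPVF} = |A_m \cap A_n|/|A_m|$,
$\mathrm{FPVF} = (|A_n| - |A_m \cap A_n|)/|A_m|$,
$\mathrm{FNVF} = 1 - \mathrm{TPVF}$, all in percent.  FNVF is computed as
the complement so the identity TPVF + FNVF = 100 is exact in floating
point.  FPVF is deliberately not capped at 100%.

The averaged radial error casts `n_rays = 180` rays from the truth
region's rounded centroid (fallback: nearest foreground pixel) and
compares, per ray, the outermost boundary crossings of the two masks,
normalized by the truth radius.  Crossings are localized sub-pixel:
the mask is sampled bilinearly at 0.25-px steps and the last downward
crossing of the 0.5 level is linearly interpolated.  On rasterized test
disks this recovers radii within half a pixel (the rasterization itself
extends a nominal radius-$r$ disk about half a pixel outward).  Rays with
zero truth radius are skipped with a warning.  Taking the *outermost*
crossing is a convention for non-star-shaped masks; the published
description implicitly assumes star-shaped tumors.

## The phantom generator

No clinical images ship with the package; `phantom_suite()` generates the
stated world the tests run in: a darker elliptical (or 5-lobed, echoing
lobulated malignant outlines) lesion centered in a brighter background,
with

* multiplicative mean-1 speckle, `1 + sigma * (Exp(1) - 1)` — an
  exponential (squared-Rayleigh) heavy tail, scale `sigma`;
* a single low-frequency sinusoidal inhomogeneity field (default
  amplitude 10 gray levels, seed-drawn orientation and phase);
* Gaussian blur (default sigma 1 px) as a crude point-spread stand-in;
* optionally a posterior shadow band below the lesion.

Difficulty presets fix contrast/speckle at 80/0.1 (easy, ellipses),
50/0.2 (medium, mild lobulation), 30/0.3 (hard, lobulated + shadow).
The default 128×128 frame with lesion semi-axes of 16-28 px approximates
the pixel scale of a clinical TCI.  That scale matters: global histogram
equalization maps the blurred lesion rim (a band of roughly fixed width,
~2 px) onto the dark plateau, so the apparent boundary sits at the outer
edge of the rim.  On a realistic lesion this is a small relative error; on
a tiny phantom it inflates the radial error substantially.  For the same
reason the preprocessing chain homogenizes the lesion *interior* while
stretching its rim — tests assert the variance reduction on the eroded
truth mask.

What a green phantom test does **not** establish: performance on clinical
speckle (fully developed speckle is spatially correlated; ours is i.i.d.),
on lesions that violate the centered-TCI assumption, or on shadowing
stronger than the rendered band.  The published clinical numbers are not
reproducible without the original dataset; the test suite instead checks
properties — oracle equivalence of the segmenter, monotonicity in `k`,
hand-computed objective values, PSO recovery of analytic optima, metric
identities, and end-to-end recovery on the easy suite (mean TPVF ≥ 80%,
mean ARE ≤ 15% with the swarm scaled to `n_p = 50`, `t_max = 60` for
runtime).

## Worked example

```{r example, eval = FALSE}
suite <- phantom_suite(1, "easy", seed = 1)
cfg <- pipeline_config(pso = swarm_config(n_p = 50, t_max = 60, seed = 1))
res <- run_moorgb(suite[[1]]$image, cfg = cfg, truth = suite[[1]]$truth)
res
res$metrics
```

## Known limitations

* The segmenter is quadratic-free and fast, but the PSO still runs
  thousands of segmentations per image; full published settings
  (200 × 200) take minutes per image in R.
* Exactly uniform reference regions zero out $V_W$ (see above); degenerate
  weightings can exploit this.
* Histogram equalization is global; a strongly bimodal TCI can collapse
  the lesion rim (documented above).  No CLAHE variant is provided.
* Image I/O is PGM/CSV only — no compiled image-format dependencies.
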