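---
title: "Likelihood-weighted root phenotyping: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-weighted root phenotyping: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootproxy)
```

## The problem

Seedlings grown in transparent agar-filled wells can be photographed from
the side in large numbers, but measuring root-system traits from those
images usually starts with a segmentation step: classify every pixel as
root or background, then measure the binary mask. Segmentation thresholds
are brittle — faint lateral roots sit near the background level, condensation
and reflections sit above it — and each threshold choice silently changes
every downstream number.

`rootproxy` takes a different route. No pixel is ever classified. Instead,
every pixel receives a *likelihood* of being root material, and every trait
is a likelihood-weighted statistic: a sum, a weighted mean, a weighted
argmax. Bright pixels well connected to the top of the well (where seeds
are sown) dominate each measurement; disconnected bright noise contributes
almost nothing. The resulting "proxy traits" carry arbitrary units, which
is acceptable because downstream use is comparative — correlating against
manual measurements, or discriminating treatment groups — so calibration
to millimetres is unnecessary.

## The likelihood model

Each well is processed independently. After grayscale conversion and a
fixed-range contrast stretch, the well's pixels become nodes of an
8-connected graph. An edge between neighbouring pixels $p, q$ with
normalised intensities $I(p), I(q) \in [0, 1]$ costs

$$ w(p,q) \;=\; 1 - \alpha\, I(p)\, I(q), $$

with $\alpha = 1$ for orthogonal neighbours and $\alpha = \sqrt 2$ for
diagonal neighbours (the longer centre-to-centre distance). Travel across
bright material is nearly free; travel across dark background costs about
one unit per step.

Source points are found by scanning each pixel row of the top strip of the
well (5% of well height by default) for local intensity maxima — positions
almost certainly containing plant material, since seeds are sown above this
line. A multi-source Dijkstra search then assigns every pixel the cheapest
path cost $d(x,y)$ from *any* source, and the likelihood is

$$ L(x,y) \;=\; \Big(1 - \frac{d(x,y)}{d_{\max}}\Big)^{n}, $$

clamped into $[0,1]$. Root-connected pixels are cheap to reach and score
near 1; isolated bright specks must be reached across dark background and
score low — this is the mechanism that suppresses noise without any
threshold.

### The normalising constant $d_{\max}$

Three conventions are implemented (`norm_max()`, `norm_mode` in the
pipeline):

* **`"well"`** (default) — the observed maximum path cost within the well.
  This makes $L$ span exactly $[0,1]$ per well and keeps the mass-weighted
  extremity traits anchored to the root: the far background corner is
  forced to likelihood 0, so a well's deepest *high-likelihood* pixel is on
  the root system.
* **`"empirical"`** — the per-well maxima averaged over the whole batch,
  computed in a first pass. This is the convention to use for population
  work: it puts every well's likelihoods on one shared scale, so masses
  and depths are comparable across wells. All population-level results in
  the tests use this mode.
* **`"theoretical"`** — $H + W$, an upper bound for an all-background well
  (any pixel is reachable within $H + W$ unit-cost steps). Deterministic
  without seeing any data, but very conservative: background likelihoods
  stay so high that the argmax-product depth saturates toward the well
  bottom. Provided for completeness and experimentation; not recommended
  as a default.

The choice matters because the depth trait is an argmax of
$L(x,y)\cdot y$: with a constant normaliser $D$ much larger than the
distances actually observed, a background pixel far below a short root can
outscore the root tip. With the per-well maximum (or a batch mean of
per-well maxima), background below the root decays to 0 and the argmax
stays on the root system. For a population, the batch-mean constant makes
proxy depth a monotone, near-linear function of true root depth — which is
what a correlation-based proxy needs.

### Negative diagonal weights

As written, $w = 1 - \sqrt2\, I(p) I(q)$ goes negative when
$I(p)I(q) > 1/\sqrt2$ — two saturated diagonal neighbours. Dijkstra requires
non-negative weights, so the default clamps at zero: travel through
saturated root material is free. The alternative reading
$w = \alpha\,(1 - I(p) I(q))$, non-negative by construction, is available
as `weight_mode = "scaled"`; on the synthetic fixtures the two differ only
marginally, because clamping triggers only inside bright root material
where costs are near zero anyway.

### Seed-detection details

Within each strip row, a *plateau* of equal maximal values contributes its
centre pixel (integer division for even plateaus); border pixels are
compared only against their one existing neighbour; a plateau spanning a
full row offers no contrast evidence and yields no seed. A minimum seed
intensity (default 0.2 after stretching) prevents empty wells from seeding
on noise; setting it to 0 restores the plain local-maximum rule. A well
with zero seeds is emitted as a flagged all-zero record — the batch never
stops.

The Dijkstra engine (compiled, binary-heap) orders priority-queue ties by
(distance, y, x), so identical inputs give bit-identical outputs on every
platform.

## The traits

All traits weight every pixel by $L$; none uses a mask.

| Trait | Definition |
|---|---|
| `centroid_x`, `centroid_y` | likelihood-weighted centre of mass |
| `mass`, `mass_norm` | $\sum L$; also divided by pixel count |
| `width_m`, `depth_m` | bounding box by mass-weighted extremities: right edge at $\arg\max_x L(x,y)\cdot x$, analogously (with mirrored coordinates) for the other three sides; `depth_m` is the bottom edge's $y$, the proxy for root length |
| `width_p95`, `depth_p95`, `depth_p99` | box enclosing 95% (99%) of total likelihood; depth is one-sided from the top (roots grow downward), width trims mass symmetrically |
| `mass_q0..q3` | mass in four stacked horizontal bands, top to bottom; remainder rows join the bottom band; always sums to `mass` |
| `orient_1..orient_10` | likelihood mass per structure-angle bracket, 0° (horizontal) to 90° (vertical), ten equal half-open brackets (last closed) |
| `qorient_q0_b1..q3_b4` | the same mass crossed with the four depth bands, four angle brackets each; sums to the orientation total |
| `leaf_area`, `leaf_hue` | top camera: count of pixels with HSV saturation strictly above 0.20, and their circular mean hue |

The structure angle is the *complement* of the Sobel gradient angle:
$\theta = 90° - \operatorname{atan2}(|G_y|, |G_x|)$. The raw gradient
points across a root, perpendicular to its axis, so a vertical root has a
horizontal gradient; the complement makes vertical roots read 90° and
horizontal laterals read 0°, matching the trait's intent (near-horizontal
mass is the lateral-root proxy). Pixels with zero gradient magnitude have
no orientation and are excluded from the brackets — without this, flat
background would dominate every histogram. The brackets weight by $L$
only, not by gradient magnitude.

Quantile boxes use cumulative sums with a $10^{-9}$ relative tolerance at
the boundary; argmax ties resolve to the first pixel in column-major
order. Both rules are arbitrary but deterministic.

## What the synthetic generator emulates

No captured image set ships with the package, so a generator
(`synthetic_root_spec()`, `generate_root_well()`, `generate_plate()`,
`generate_top_view()`, `generate_population()`) renders wells with known
ground truth:

* a primary root as a unit-step polyline descending from a top-strip start
  point, heading swaying sinusoidally within ±12° of vertical by default;
* laterals branching below 20% of the primary's length, at 40–60° from
  vertical, 40–90 px long — *absolute* lengths, since young laterals do not
  scale with primary length;
* strokes with a Gaussian cross-section (half-width 2 px) emulating
  out-of-focus agar imaging, or sharp binary strokes for exact-mask tests;
* root intensity 220 on background 30 (8-bit), Gaussian noise σ = 6, salt
  noise at density 5·10⁻⁴ and intensity 235;
* top-down rosettes as saturated discs on a white background.

The standard stretch bounds for this imagery are (48, 230): the low bound
sits at background + 3σ (30 + 18), so stretched background is exactly 0 —
flat, gradient-free, and cheap to distinguish — while root material maps
near saturation. This mirrors how bounds are chosen on a real rig: once,
from the known background and foreground levels, then applied to the whole
batch.

The population generator draws control wells with primary length
Normal(450, 80) px and Poisson(8) laterals, and growth-inhibited wells
with Normal(200, 50) px and Poisson(3) laterals — a root-inhibiting
treatment of realistic effect size for a water-deficit stress.

What the generator does **not** emulate: reflections and condensation on
the well walls, overlapping root systems from multiple plants per well,
agar texture, uneven illumination, and lens distortion. Tests passing on
synthetic wells therefore demonstrate the method's internal correctness
and its noise-suppression mechanism, not its accuracy on any particular
rig's imagery; on real images the stretch bounds and well grid must be
set per installation.

## Problem sizes and numerical checks

The test suite checks the shortest-path engine against an independent
igraph oracle on 200 random grids (10×10 to 20×20; agreement is at
floating-point accumulation level, < 10⁻¹²), conservation identities on
100 random likelihood fields (10⁻⁹ relative), depth recovery and exact
translation covariance on noise-free 120×340 straight-root wells, noise
suppression on 20 salted fixtures, proxy validity on 200 full-size
(290×710) wells with true lengths uniform on [100, 600] px, separability
on 100 + 100 control/inhibited wells, and the batch contract on 23
eight-well plates (184 rows, byte-identical reruns, corrupt files
quarantined). These sizes were chosen so the whole suite completes in a
few minutes on a laptop while leaving the population checks large enough
for stable correlation estimates.

## Known limitations

* Traits aggregate over a whole well; nothing assigns pixels to individual
  plants or reconstructs root topology.
* The likelihood floor of background pixels depends on the normalising
  mode; masses are comparable across wells only under a shared
  (`"empirical"`) constant.
* `depth_m` is biased upward for roots much shorter than the well (the
  argmax product trades likelihood against depth), but the bias is a
  near-linear function of true depth, so rank and correlation structure
  survive — the intended use.
* Well rectangles are configuration, not detection: a mis-specified grid
  silently measures the wrong region.
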