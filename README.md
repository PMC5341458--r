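# rootproxy

Threshold-free root phenotyping from multi-well plate images.

High-throughput seedling screens photograph transparent agar-filled wells
from the side, eight wells to a plate, thousands of plates to a screen.
Classical image analysis binarises each well — root vs background — and
measures the mask; the threshold is brittle exactly where it matters, on
faint lateral roots and noisy backgrounds. `rootproxy` never classifies a
pixel. It computes, for every pixel, a *likelihood* of root material, and
measures every trait as a likelihood-weighted statistic. The package is
aimed at phenotyping platforms and plant-biology labs that need unattended
batch measurement whose outputs correlate with, and discriminate like,
manual measurements — without per-image tuning.

## The method

Within a well, pixels form an 8-connected graph with edge weights

    w(p, q) = 1 − α · I(p) · I(q),   α = 1 (orthogonal), √2 (diagonal)

where `I ∈ [0, 1]` is normalised intensity after a fixed-range contrast
stretch. Seed points are per-row local intensity maxima in the top 5% of
the well (seeds are sown above that line). A multi-source Dijkstra search
gives every pixel its cheapest path cost `d(x, y)` from any seed, and

    L(x, y) = (1 − d(x, y) / d_max)^n,  clamped to [0, 1]

is the root likelihood: bright material connected to the top scores near 1,
isolated bright noise must be reached across dark background and scores
low. Traits are then likelihood-weighted sums and argmaxes: centroid, mass,
bounding-box depth/width (`depth_m` is the proxy for root length),
95%/99% quantile boxes, per-quadrant masses, Sobel-based orientation
histograms (near-horizontal mass is the lateral-root proxy), plus top-down
leaf area and circular mean hue. Units are arbitrary by design: downstream
use is correlation and discrimination, not millimetres.

## Worked example

Generate a synthetic well with known ground truth and analyse it:

```r
library(rootproxy)

spec <- synthetic_root_spec(length = 420, n_laterals = 6, seed = 42)
gw   <- generate_root_well(spec)                    # 290 x 710 well image
res  <- analyse_well(gw$image, bounds = stretch_bounds(48, 230))

dplyr::select(res$traits, depth_m, depth_p95, mass, centroid_y,
              mass_q3, orient_10)
#> # A tibble: 1 × 6
#>   depth_m depth_p95    mass centroid_y mass_q3 orient_10
#>     <dbl>     <dbl>   <dbl>      <dbl>   <dbl>     <dbl>
#> 1     421       582 133322.       278.  13229.     1714.

gw$truth$primary_length   # 420
nrow(res$seeds$points)    # 42 seed points in the top strip
```

The proxy depth (`depth_m = 421`) tracks the true primary length (420 px);
`orient_10` is the likelihood mass in the most-vertical orientation
bracket; `mass_q3` is the mass in the bottom quarter of the well.
`autoplot(res$lmap)` renders the likelihood heat map.

Batch processing runs from a YAML config (well rectangles, stretch bounds,
normalisation mode) and writes one CSV row per well:

```r
cfg <- read_run_config("run.yaml")
run_batch(cfg)
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/rootproxy.R run --config run.yaml
Rscript inst/cli/rootproxy.R fixtures --out demo_data --plates 3
```

CSV columns, in order: `image_id`, `well_index`, `empty_flag`,
`centroid_x`, `centroid_y`, `mass`, `mass_norm`, `width_m`, `depth_m`,
`width_p95`, `depth_p95`, `depth_p99`, `mass_q0..q3`, `orient_1..10`,
`qorient_q0_b1..q3_b4`, and (when a paired top image exists) `leaf_area`,
`leaf_hue`. Wells with no seed points are emitted as flagged zero rows;
unreadable images are logged and skipped — a batch never stops.

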