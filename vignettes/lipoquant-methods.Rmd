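---
title: "lipoquant: models, parameters and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lipoquant: models, parameters and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lipoquant` quantifies lipid droplets (LDs) and their associated proteins in
multi-channel 2D fluorescence images. This vignette documents the models the
package implements, the tunable parameters and their defaults, the
synthetic-data generator that backs the test suite, and the design choices
made where the underlying analysis conventions were genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## Image model and preprocessing

Images are named 2D intensity channels on one pixel grid
(`mc_image`), with a physical pixel size in µm (defaults follow common
spinning-disk confocal configurations: 0.107 µm at 60×, 0.065–0.066 µm at
100×). Intensities are kept in acquisition units — never rescaled to
[0, 1] — because every downstream statistic is a ratio, fraction or
correlation and is therefore invariant to the overall intensity scale
(property-tested in `test-acceptance.R`, criterion 7). Coordinates are
(row, col), 0-based, with pixel centers at integer positions; all distances
are Euclidean in pixel units.

**Background subtraction** (`subtract_background`) estimates the smooth
background as the grayscale opening of the channel with a flat disk (the
classical rolling-ball approximation; default radius 50 px, configurable —
the radius is an analysis choice, not a measured constant). Two numerical
points matter:

- On shot-noise-limited images a raw opening tracks local noise *minima*
  (an erosion is a running minimum), systematically under-subtracting the
  camera pedestal. Following standard Fiji practice the default pipeline
  therefore estimates the background on a 3×3-mean-smoothed copy and, for
  large balls, rolls the ball on a block-mean-shrunk image (factor 2 for
  radius > 15 px, 4 for radius > 31 px) with bilinear upscaling of the
  estimate. `presmooth = FALSE` gives the pure morphological opening (the
  exact contract the oracle tests check).
- The estimate is clamped to the pixel value before subtraction, so the
  output is always in `[0, input]`.

**Otsu thresholding** (`otsu_mask`) does an exhaustive search over a
256-bin histogram for the threshold maximizing between-class variance;
foreground is *strictly above* the threshold. A constant channel returns an
empty mask with a warning rather than an error: in batch runs, cells with
no signal must flow through and appear as missing values, not abort the
run. Whether the histogram is taken per cell (within the ROI) or per image
is configurable; the default is per-cell, since per-image thresholds are
dominated by the empty field around the cell.

**Mask operations** — union, difference, and Euclidean dilation. Dilation
uses the exact squared Euclidean distance transform rather than iterated
3×3 structuring elements, which distort large dilations into octagons; the
160 px dilation used by the peripheral mask is exactly circular here.

## LD detection

`detect_lds_log` implements scale-space blob detection: the
scale-normalized Laplacian-of-Gaussian response `-σ²∇²(G_σ * I)` is built
over a sigma grid, 3D local maxima (position × scale) above threshold
become detections, and `radius = √2·σ` — the extremum relation between a
2D blob's radius and its optimal LoG scale.

Defaults (`detection_config`): sigma 1.5–8 px over 10 linear steps
(radii ≈ 2–11 px), detection threshold 0.05 × channel maximum, overlap
pruning at 0.5 (intersection area over the smaller disk), greedy by
response with ties broken by larger radius then smaller (row, col) for
determinism. Each maximum is refined to sub-pixel position and sub-grid
scale by 1D quadratic interpolation of the response (offsets clamped to
half a grid step) — without refinement, centroid quantization alone costs
several percent of on-LD intensity in the enrichment statistic.

Derived masks:

- `blobs_to_mask` — union of filled disks (distance ≤ radius), overlaps
  counted once.
- `surface_donut_mask` — per blob, the annulus between `core_fraction·r`
  (default 0.6) and `r + e(r)` with `e(r) = clip(round(0.3·r), 2, 5)` px.
  The outward expansion of "2–5 px, proportional to the radius" has no
  canonical formula; the linear-with-clipping rule above is this package's
  declared default, exposed in the configuration, as is the core fraction.
- `count_local_maxima` — "Find maxima"-style spot counting by topographic
  prominence (height above the highest saddle to a larger peak, computed
  by descending-order union-find; the global maximum is measured against
  the image minimum). The prominence threshold is the user's.

**Mature-LD filter** (`filter_mature_lds`): in tissue fields a surface
decorator labels the droplet monolayer, so a genuine mature droplet has a
dye-bright, marker-dark core — the Pearson correlation of the two channels
over a small patch around the detection is negative — whereas non-specific
structures light up in both channels and correlate positively. The patch
halfwidth is `max(ceil(1.5·r), 3)` px (declared default; "a small patch"
has no canonical size). Blobs with degenerate (constant) patches are
dropped with a warning. The filter is idempotent.

## Per-cell statistics

- `enrichment_sum`: fraction of decorator intensity inside the detected
  radii, within the cell mask — in [0, 1], monotone in blob radii.
- `enrichment_mean`: mean intensity in a mask over mean intensity in the
  cell (> 1 = enriched). The two definitions coexist because both
  conventions are in active use (whole-droplet fraction vs surface-mask
  mean); they are separate functions rather than a flag so results are
  never silently mixed.
- `masked_pearson`: two-pass (mean-centered) Pearson over masked pixels.
  The single-pass formula is rejected deliberately: on bright 16-bit
  images `Σx² − n·x̄²` cancels catastrophically.
- `peripheral_mask`: cell minus nucleus dilated by 160 px (default),
  restricting colocalization to the cell periphery.
- `ld_area_fraction`: Otsu LD area over cell area.
- `ld_density_per_area`: `count / (H·W·pixel_size_um²)`. For the standard
  tissue quantification field — 2,048² px at 0.066 µm/px — the normalizing
  area is 18,270 µm² (acceptance criterion 1 recomputes this constant).

Pixels outside the cell mask are never imputed. Per-condition aggregation
is mean ± sample s.d. (n − 1); groups of one report `sd = NA`.

## Keima ratiometry

The reporter mask is the union of the per-channel Otsu masks of the 488 nm
and 561 nm excitation channels — the total area expressing the reporter
regardless of which excitation it currently favours. Over that mask the
package computes both the mean of per-pixel 561/488 ratios (`mean_ratio`,
the headline value, matching ratio-image construction) and the ratio of
sums (`total_ratio`). Pixels whose 488 intensity is at or below a
machine-scale floor (`eps = 1e-9`) are excluded and counted; no pseudocount
is added, because pseudocounts bias dim cells low. Ratios are computed on
background-subtracted channels by default (the raw camera pedestal enters
both numerator and denominator additively and drags the ratio toward 1;
this is a configuration flag, default on). Normalization divides every
cell's `mean_ratio` by the *control-group mean* — the natural reading of
normalizing "by a control sample" when several control cells exist — so
the control group averages 1 by construction. Cells suspected of cleaved,
diffusely cytosolic reporter are flagged (`keima_qc_cleaved`: reporter mask
covering > 85 % of the cell), never silently removed; exclusions appear in
the run log.

## Synthetic microscopy generator

`simulate_cell` renders one disk-shaped cell (default radius 80 px at
0.107 µm/px ≈ a 17 µm cell) containing a nucleus (28 px), with:

- **LDs**: disks with radii uniform in 3–8 px (≈ 0.3–0.9 µm, a plausible
  cultured-cell range chosen for testability — real LD size distributions
  vary widely and are not modelled), placed by rejection sampling inside
  the cell, outside the nucleus, pairwise ≥ 20 px apart; a bounded number
  of failed attempts raises a clean infeasible-packing error. The LD
  channel is a flat-top disk with a 1 px soft edge convolved with a
  Gaussian PSF (σ = 1 px default): LoG detection needs realistic edges,
  and a hard disk is not what a microscope produces.
- **Decorator channel**: painted with an *exact* intensity budget — the
  requested fraction of total intensity on the LDs (surface ring or filled
  disk), the remainder uniform over the cytoplasm. Before noise, the
  painted on-LD fraction equals the request to machine precision, which is
  what makes enrichment recovery a sharp test. The surface ring occupies
  `[r, r + 2]` px by default: a coat on the droplet monolayer sits at and
  just outside the dye-filled core, and this geometry is what produces the
  negative patch correlation that the mature-LD filter relies on (a ring
  starting at 0.6·r overlaps the bright core enough to flip the patch
  correlation positive; the inner edge is configurable down to 0.6 for
  rendering filled-ring hybrids). Non-specific spots are painted filled in
  both channels at the on-LD pixel density, from the off-LD budget.
- **Lysosome channel**: a configurable fraction of LDs co-painted plus
  free puncta, for colocalization tests.
- **Keima pair**: the cytoplasm carries the reporter; lysosomal puncta
  (disks of radius 3–6 px) cover a target fraction of reporter pixels at
  the acidic per-pixel 561/488 ratio (default 3.0), the rest at the
  neutral ratio (default 0.5). The recorded ground truth is the
  area-weighted mean over the *realized* mask, so disk-granularity in hit
  targets never contaminates the oracle.
- **Noise**: Poisson on (signal + background), then Gaussian read noise,
  clipped at 0. Defaults: background 20, read noise σ = 2 — with the
  default LD amplitude 200 this is SNR ≈ 40 under the definition
  `SNR = peak / sqrt(background + σ_read²)` (`snr_to_peak` inverts it).
  One RNG stream per scene is split deterministically into
  placement/intensity/noise sub-streams, so toggling noise never moves a
  blob.

What the generator does **not** emulate: realistic PSFs (Airy/defocus),
3D structure, illumination gradients, reticular organelle texture,
empirical LD size distributions, or photobleaching. A green test therefore
establishes that the *estimators* recover a stated ground truth under the
stated noise model — not that any biological effect size is reproduced.

## Numerical and degenerate-input choices

- Otsu on a constant channel → empty mask + warning (see above).
- Zero-denominator Keima pixels → excluded and counted (no pseudocount).
- Empty LD masks / zero total intensity → `NA` with warning, never 0.
- Dilation radius 0 → identity; empty mask in → empty mask out.
- Detection ties → response desc, radius desc, (row, col) asc.
- Background estimate clamped to the input before subtraction.
- Polygon ROIs are rasterized by even-odd scanline fill at pixel centers.

## Known limitations

- Fused droplets are not split (no watershed); the overlap pruner keeps
  the single strongest detection.
- The rolling-ball estimate is still biased low by a few counts on very
  noisy images; ratio statistics on dim cells inherit a corresponding
  small bias.
- The TIFF codec is deliberately minimal: uncompressed grayscale
  8/16/32-bit unsigned and 32/64-bit float, single- or multi-page. No
  compression, tiles, palettes or RGB.
- The pipeline treats the supplied ROI as the statistical unit and leaves
  any field-of-view-level aggregation to configuration.
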