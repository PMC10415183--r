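# lipoquant

Quantification of lipid droplets (LDs) and LD-associated proteins in
multi-channel 2D fluorescence microscopy, for cell biologists studying
neutral-lipid storage and lipophagy (the autophagic turnover of LDs).

LDs appear as bright disks in a neutral-lipid stain (e.g. BODIPY493/503);
LD-coat proteins decorate the droplet monolayer as surface rings;
pH-sensitive dual-excitation reporters (Keima fusions) report delivery of
droplets to acidic lysosomes. `lipoquant` turns these images into
per-cell numbers:

- **LD detection** — scale-space blob detection via the scale-normalized
  Laplacian of Gaussian. Maxima of `-σ²∇²(G_σ * I)` over position and scale
  give centroids and radii `r = √2·σ`, with sub-pixel quadratic refinement
  and overlap pruning.
- **Enrichment at LDs** — two conventions used in the field:
  `E_sum = Σ I(decorator) inside detected radii / Σ I(decorator) in cell`
  (a fraction in [0, 1]), and `E_mean = mean(I inside mask) / mean(I in
  cell)` over a surface "donut" mask (annulus `0.6r … r + e(r)` with
  `e(r) = clip(round(0.3r), 2, 5)` px).
- **Masked Pearson colocalization** — two-pass Pearson `r` over a pixel
  mask, in particular the cell-periphery mask: whole-cell mask minus the
  nucleus dilated by 160 px.
- **Keima lipophagy flux** — reporter mask = Otsu(ex488) ∪ Otsu(ex561);
  headline statistic is the mean of per-pixel 561/488 ratios, normalized to
  the control-group mean.
- **Morphometry** — Otsu LD-area fraction per cell; mature-LD density per
  physical area (`count / (H·W·px²)`; a 2,048² px field at 0.066 µm/px
  normalizes by 18,270 µm²), with a negative-correlation filter that keeps
  only droplets whose dye core anticorrelates with the surface marker.
- **Synthetic microscopy** — a generator that renders disk LDs, surface
  rings, lysosome fields, two-compartment Keima pairs and Poisson–Gaussian
  camera noise with exhaustive ground truth, so every stage above is tested
  against known truth without any raw images.

## Worked example

```r
library(lipoquant)

p  <- scene_params(n_lds = 10L, on_ld_intensity_fraction = 0.45,
                   decorator_mode = "surface_ring",
                   lyso_pixel_fraction = 0.3, seed = 42)
sc <- simulate_cell(p)

ld    <- subtract_background(get_channel(sc$image, "ld"), 50)
dec   <- subtract_background(get_channel(sc$image, "decorator"), 50)
blobs <- detect_lds_log(ld, sc$roi)
donut <- surface_donut_mask(blobs, dim(sc$image))
per   <- peripheral_mask(sc$roi, dilation_px = 30)
k488  <- subtract_background(get_channel(sc$image, "keima488"), 50)
k561  <- subtract_background(get_channel(sc$image, "keima561"), 50)
kr    <- keima_ratio(k488, k561, keima_reporter_mask(k488, k561))
```

prints (seed 42):

```
detected 10 LDs (truth: 10)
surface enrichment (mean ratio): 5.76
peripheral LAMP1/LD Pearson r: 0.488
Keima 561/488 mean ratio: 1.268 (generator truth: 1.258)
LD area fraction of cell: 0.0535
LD density: 0.0237 per um^2
```

Reading the numbers: all 10 simulated droplets were recovered; decorator
signal is 5.8-fold concentrated at droplet surfaces relative to the whole
cell; the lysosome channel partially colocalizes with LDs in the cell
periphery (r ≈ 0.49, half the droplets were co-painted); the Keima ratio
1.27 matches the generator's true compartment mix (30 % lysosomal pixels at
ratio 3.0, the rest cytosolic at 0.5 → 1.25); droplets cover 5.4 % of the
cell area.

## Batch runs

`run_pipeline("run.json")` (or the `exec/lipoquant` CLI: `simulate`, `run`,
`summarize`) processes a manifest CSV of images + ROI masks and writes
`per_cell_metrics.csv`, `keima_metrics.csv`, `blobs.csv`,
`condition_summary.csv` (mean ± s.d. per condition, n−1 convention), a run
log and the resolved config; every row carries the config hash. Reruns with
identical config and inputs are byte-identical.

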