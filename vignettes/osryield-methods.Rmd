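---
title: "Methods: flower mapping, yield estimation and canopy height in osryield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flower mapping, yield estimation and canopy height in osryield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osryield)
```

`osryield` turns a UAV multispectral orthomosaic of a flowering oilseed
rape (OSR) field into a seed-yield estimate and a canopy-height record.
This vignette is the package's own account of the science: the models and
their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices that make
the pipeline deterministic and testable.

## 1. The yellowness index

OSR petals absorb blue light (carotenoids) and reflect green, so the
normalized difference yellowness index

$$\mathrm{NDYI} = \frac{G - B}{G + B}$$

separates flowering canopy (positive values) from green vegetation and
bare soil (negative values). `compute_ndyi()` evaluates this per pixel at
64-bit precision and masks three kinds of pixel: any pixel where a source
band is nodata, pixels with $G + B = 0$ (the ratio is undefined), and
pixels whose index falls outside $[-1, 1]$ — possible only when a
calibrated reflectance product contains negative values, which the
package permits but reports. Out-of-range pixels are masked rather than
clamped so the `[-1, 1]` invariant of an index raster is real, not
cosmetic. For non-negative reflectances the index is automatically in
range, antisymmetric under band exchange, and invariant to a common
positive scaling of both bands; both properties are enforced by tests.

## 2. Iso-cluster classification

Thresholding NDYI directly at a hand-picked value is brittle: the
absolute index level shifts with calibration, illumination and site. The
pipeline instead clusters the index raster *first* and thresholds only the
**cluster means**. `isodata_classify()` implements an ISODATA-style
migrating-means classifier, deliberately deterministic:

- **Initialization** at the $(i - 0.5)/k$ quantiles of the valid values,
  $i = 1..k$, not at random seeds. Identical input and parameters give
  bit-identical output, which turns classifier tests into exact checks.
  The `seed` parameter is retained only for optional randomized restarts.
- **Assignment** of every pixel to the nearest centroid by Euclidean
  distance, ties broken toward the lowest centroid index.
- **Update** of each centroid to its member mean (an optional
  `sample_interval` stride subsamples the update for very large rasters;
  assignment always covers all pixels).
- **Empty clusters** are re-seeded at the pixel farthest from its current
  centroid.
- **Convergence** when fewer than `change_tolerance` (default 0.001) of
  pixels switch cluster, or after `max_iterations` (default 20).
- **After convergence**, clusters smaller than `min_cluster_size`
  (default 20 px) merge into the nearest-mean neighbour, and surviving
  clusters are relabelled in ascending mean order, so "cluster 1" is
  always the darkest regardless of iteration history.

Assignment and update steps both decrease the within-cluster sum of
squares, so the WSS trace recorded in the result is non-increasing — a
property test. On tiny one-dimensional instances the final partition is
checked against exhaustive enumeration of every possible assignment: it
attains the global optimum whenever the clusters are separated by more
than their internal spread, and stays within 5% of optimal otherwise.
If the data hold fewer distinct values than `k`, the classifier returns
fewer clusters and sets a degeneracy flag instead of failing.

The default `k = 5` reflects how flowering OSR fields actually decompose:
one soil cluster, one green-vegetation cluster, and three flower clusters
of varying yellowness. `assign_classes()` then maps cluster means to
semantic classes:

| cluster mean NDYI | class |
|---|---|
| $> 0.12$ | flower |
| $[-0.45, -0.15]$ | vegetation |
| $[-1, -0.45)$ | soil |
| $(-0.15, 0.12]$ | unclassified (default) |

Classification by cluster mean, not per-pixel value, is the point of the
design: whole clusters of varying flower brightness are grouped as
flowers, which a single per-pixel threshold cannot do. Interval boundary
ownership (closed at $-0.45$ and $-0.15$ on the vegetation side, open
elsewhere) is a declared convention — the field ranges are reported
without stating it. The gap $(-0.15, 0.12]$ defaults to `unclassified`
and is excluded from flower counts (conservative counting); a
`nearest`-range policy is available. Every pixel inherits its cluster's
class, and class pixel counts are exact tallies.

## 3. The pixel-fraction yield estimator

The estimator ties flower cover to yield:

$$\widehat{Y} \,(\mathrm{t/ha}) = \frac{F \cdot P}{A}, \qquad
F = \frac{\text{flower pixels}}{\text{total pixels}}, \qquad
P = F_{\text{area}} \cdot \kappa \cdot c_{\text{pod}} \ (\mathrm{t}),$$

with $F_{\text{area}} = \text{flower pixels} \times \text{res}^2$ the
classified flower area in m² (at the default 0.027 m ground sampling
distance each pixel covers $(0.027\,\mathrm{m})^2$), $A$ the zone area in
hectares, and $c_{\text{pod}} \in (0, 1]$ a flower-to-pod conversion
(default 1; 0.75 is the ground-truthed conversion fraction reported for
OSR and is available as a configuration value).

The heuristic step "approximate flower area to a seed mass" fixes no
units, and taking the conversion literally (m² read as tonnes) produces
physically absurd field-scale yields. The package therefore makes the
conversion explicit as $\kappa$, tonnes of seed per m² of classified
flower area, never hard-wires it, and fits it when ground truth exists:
`calibrate_kappa()` performs least squares through the origin of actual
yield on the $\kappa = 1$ prediction, $\hat\kappa = \sum x_i y_i / \sum
x_i^2$ with $x_i = F_i F_{\text{area},i} c_{\text{pod}} / A_i$. A single
(prediction, actual) pair reduces to the exact ratio. Note that because
$F_{\text{area}} \approx F \cdot A_{m^2}$, the estimate scales like
$F^2 \kappa \times 10^4$ and is invariant to the zone footprint size —
the estimator responds to flower *density*, quadratically.

Zonal application (`estimate_yield_zones()`) clips pixels to each zone by
the **pixel-centre rule**: grids are row-major with pixel $(1,1)$ at the
top-left map corner, a pixel covers the half-open square $[x, x +
\mathrm{res}) \times (y - \mathrm{res}, y]$, and a pixel belongs to a
zone iff its centre does. Under this rule a 10 m square window at
0.027 m/px owns exactly $370 \times 370$ pixel centres, a fact tested
against a brute-force point-in-polygon loop. Zones are square windows
(centre + side; the classic sampling design is 25 windows in each of four
yield-class areas) or arbitrary polygons (point-in-polygon via
`mgcv::in.out`, area by the shoelace formula). Masked pixels never enter
$F$ or the totals, so estimates are invariant to nodata padding — also a
test. Zones with no valid pixels are flagged and excluded from
statistics rather than contributing zeros.

## 4. Canopy height

`compute_chm()` is the exact per-pixel difference CHM = DSM − DTM; CHM +
DTM reconstructs the DSM bit-for-bit on valid pixels. Negative heights
(terrain-model overshoot) are **retained, not clamped** — clamping would
hide DTM errors — but their count is reported, and the summary layer
(`summarize_heights()`) excludes values below `mask_below` (default 0) so
artefacts do not drag down stage statistics. Quartiles use linear
interpolation between order statistics (`stats::quantile` type 7), pinned
so the summaries are exactly reproducible; they are verified against a
sort-based oracle. `stage_series()` orders summaries by the five OSR
stages — rosette, bolting, flowering, podding, ripening — and flags the
stage of maximum mean height. When a summary covers the whole field,
bare-soil pixels pull the mean below the canopy height; the median is the
more faithful canopy statistic, and stage comparisons should use a
consistent footprint.

## 5. Validation statistics

- `rmse()`: $\sqrt{\tfrac{1}{n}\sum (y_i - \hat y_i)^2}$, in t/ha for
  yields.
- `pearson_r2()`: product-moment correlation and its square. $R^2$ is
  reported from the correlation, not from a regression through the
  origin.
- `t_test_from_summary()`: two-sample t-test from (mean, sd, n) alone,
  for comparisons where only summary statistics exist — e.g. validating
  UAV-derived heights against 13 tape measurements of a wall bordering
  the field. A reported "mean ± spread" is read as mean and **standard
  deviation**; with 1.13 ± 0.13 m vs 1.18 ± 0.22 m (n = 13 each) this
  reading yields p ≈ 0.49 under both variants, the internal consistency
  check for the convention. Welch is the default (the spreads are
  visibly unequal); the pooled variant is available, and both are
  verified against a quadrature of the t density written from its
  formula. When both standard deviations are zero the statistic is
  undefined; equal means return p = 1 with a degeneracy flag.

## 6. The synthetic scene generator

No flight data are distributed with the package, so every downstream
stage is exercised on generated scenes with exact truth:

- **Class layout**: a Gaussian-smoothed random field
  (`patch_scale` = 8 px default) is rank-cut so the top
  $\mathrm{round}(f \cdot n)$ pixels are flower, the next block
  vegetation, the rest soil. Patches are spatially coherent — what an
  iso-cluster classifier actually faces — and realized fractions are
  exact up to whole-pixel rounding. The default vegetation fraction is
  half of the non-flower area.
- **Spectra**: per class and band, Gaussian reflectance with preset
  means/sds chosen once so the induced NDYI distributions land in the
  observed field ranges (≥ 99% of flower pixels above 0.12, vegetation
  within (−0.45, −0.15), soil within (−1, −0.45)). These are synthetic
  values, not physical spectra: real OSR fields show negative
  vegetation NDYI consistent with uncalibrated products, and matching
  the index ranges is what matters downstream. `sd_scale` widens all
  spreads and acts as a separability dial; recovery accuracy degrades
  monotonically with it (tested at 1, 5, 12).
- **Elevation**: DTM is a smooth random surface with ~0.5 m relief; DSM
  adds the stage height over canopy pixels plus Gaussian measurement
  noise (`noise_sd`, default 0.02 m) everywhere, so soil pixels have
  DSM ≈ DTM. Default stage heights 0.21 / 0.53 / 0.91 / 0.58 / 0.62 m
  (rosette → ripening) put the series on the scale UAV surveys report
  for OSR, peaking at flowering.
- **Yield points**: per zone, the noise-free yield is the estimator
  evaluated on *true* flower pixels with `kappa_true`, times
  $(1 + \varepsilon)$, $\varepsilon \sim N(0, \mathrm{CV})$ —
  multiplicative yield-monitor noise, default CV 0.05. `kappa_true`
  defaults to 0.0045 t/m², chosen once so a ~30%-flowered zone lands
  near 4 t/ha, the scale of combine yield maps (whose class means run
  roughly 3.4–4.6 t/ha).

All randomness flows from one seed per call through an RNG scope that
restores the caller's state; identical parameters and seed give
bit-identical scenes, and the seed is recorded in the truth object.

What the generator does **not** emulate: radiative transfer or canopy
BRDF, illumination gradients and shadows, mixed pixels at class
boundaries, spatially correlated sensor noise, georeferencing error, and
harvester artefacts (flow lag, edge passes). Passing tests therefore
demonstrate that the algorithms are implemented correctly and recover
known truth under field-plausible index distributions — not that the
pipeline is robust to every artefact of real orthomosaics.

## 7. Raster model and I/O

Rasters are matrix-backed objects: named bands (or a single value grid),
a logical nodata mask, metres-per-pixel resolution, a top-left map origin
and an opaque CRS tag (pass-through only; reprojection is out of scope —
a survey lives in one projected system). Values are stored as 64-bit
floats; nodata is a mask in memory and NaN on disk, avoiding sentinel
arithmetic. GeoTIFF I/O uses a compact codec written for this package
(classic little-endian TIFF, uncompressed 64-bit IEEE floats, one page
per band, band names/wavelengths/kind/CRS in an ImageDescription JSON
payload, pixel size in the ModelPixelScale tag) so that write-then-read
round trips are bit-exact — the property the format contract demands —
and an independent Python TIFF reader cross-checks the files in the test
suite. The reader also accepts 32-bit float and unsigned-integer
single-sample TIFFs from other tools, with positional default band names
blue, green, red, rededge, nir.

## 8. Problem sizes and determinism of the shipped checks

The test suite and `scripts/acceptance.R` run on scenes from 64² to 512²
pixels, 9–100 zones of 0.35–1 m side (windows scale with the synthetic
extent; the estimator is footprint-invariant, §3), and enumeration
oracles up to $3^{10}$ assignments — sizes chosen so the full suite
completes in well under a minute while the 512² acceptance scene still
exercises ~260k-pixel clustering. The CLI `demo` is byte-reproducible
per seed, tested by running it twice and comparing files.

## 9. Known limitations

- κ is field- and season-specific; a calibration from one date or field
  does not transfer, and the default exists only to give the synthetic
  workflow a realistic scale.
- The estimator's quadratic response to flower density is inherited from
  the pixel-fraction formulation; it is not a crop-growth model, and
  flowering-to-yield coupling can break under late-season stress.
- Classification is univariate on NDYI by default (the engine accepts
  multi-band input); clouds, specular soil or yellow weeds can land in
  the flower range.
- The wall-height t-test from summary statistics assumes near-normal
  heights and independent repeats; it checks bias, not spatial accuracy.
- GeoTIFF support is deliberately minimal: uncompressed single-sample
  pages, no tiling, no compression, CRS as an opaque tag.
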