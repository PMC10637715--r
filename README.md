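# osryield

UAV multispectral flower mapping and seed-yield estimation for oilseed
rape (*Brassica napus*).

Oilseed rape announces its eventual seed yield months before harvest: the
density of its yellow flowers in spring correlates with combine-measured
yield in August. `osryield` implements the image-analysis side of that
observation for drone surveys. Starting from an already-built multispectral
orthomosaic (blue/green/red/red-edge/NIR reflectance bands at centimetre
ground sampling distance), it

- computes the **normalized difference yellowness index**,
  `NDYI = (G − B) / (G + B)`, which is driven positive by the
  carotenoid-rich petals and stays negative over green canopy and soil;
- segments the NDYI raster with a deterministic **ISODATA (iso-cluster)**
  classifier — migrating means, quantile initialization, empty-cluster
  re-seeding, small-cluster merging — and groups the resulting clusters
  into *soil* / *vegetation* / *flower* by their cluster-mean NDYI
  (flower above 0.12, vegetation in [−0.45, −0.15], soil in [−1, −0.45));
- estimates seed yield per sampling zone with the **pixel-fraction
  estimator**

  ```
  estimated yield (t/ha) = F · P / A,
  F = flower pixels / total pixels,
  P = flower area (m²) · κ · flower-to-pod fraction   [tonnes],
  A = zone area (ha),
  ```

  where the area-to-mass coefficient κ (t per m² of classified flower
  area) is explicit and calibrated by least squares through the origin
  against yield-monitor ground truth;
- derives **canopy height models** (`CHM = DSM − DTM`) and per-stage
  height summaries across the five phenological stages (rosette, bolting,
  flowering, podding, ripening); and
- validates estimates with Pearson r/R², RMSE, and a two-sample t-test
  from summary statistics (the test used to check UAV heights against
  tape-measured wall heights: 1.13 ± 0.13 m vs 1.18 ± 0.22 m, n = 13
  each, gives p ≈ 0.49 — no detectable bias).

Because UAV campaigns are not repeatable on demand, the package ships a
**synthetic scene generator** with exact ground truth (patchy class
layout, class-conditional band spectra, stage-dependent canopy heights,
yield points coupled to true flower density), so the whole pipeline is
testable end-to-end. All tabular results are tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(osryield)

scene <- generate_scene(256, 256, flower_fraction = 0.30, seed = 42)
zones <- make_zone_grid(scene$truth, n = 25, side = 1)
pts   <- generate_yield_points(scene$truth, zones, noise_cv = 0.05, seed = 43)

res <- run_flower_yield_pipeline(scene$raster, zones,
                                 actual = dplyr::rename(pts, actual = yield))
glance(res$class_map)
#>    soil vegetation flower unclassified flower_fraction
#> 1 22937      22938  19661            0           0.300
glance(res)
#>   n_zones   kappa flower_pixels     n     r    r2  rmse slope intercept
#> 1      25 0.00452         19661    25 0.999 0.999 0.339  1.00   -0.0206
```

The classifier recovers the true 30% flower cover exactly
(19661 / 65536 = 0.300), the calibrated κ = 0.00452 sits within 1% of the
generator's 0.0045 t/m², and the zone estimates track the noisy "actual"
yields with R² = 0.999 and RMSE = 0.34 t/ha. Per-zone detail:

```r
head(tidy(res), 3)
#>   id            F flower_area_m2   A_ha estimated actual
#> 1 zone_001 0.221          0.220  0.0001     2.20   2.18
#> 2 zone_002 0.514          0.512  0.0001    11.9   10.9
#> 3 zone_003 0.0654         0.0671 0.0001     0.198  0.193
```

Canopy heights from a matched surface/terrain pair:

```r
el  <- generate_elevation(scene$truth, noise_sd = 0.05, seed = 44)
chm <- compute_chm(el$dsm, el$dtm)
summarize_heights(chm, "flowering")
#>   stage         n      min    q1 median  mean    q3   max
#> 1 flowering 54169 7.42e-07 0.826  0.893 0.724 0.934  1.15
```

The median (0.89 m) sits on the flowering canopy near the generated
0.91 m stage height; the mean is pulled down by bare-soil pixels, which is
why stage comparisons should use the same footprint throughout.

A command-line wrapper covers the same stages
(`inst/cli/osryield simulate|ndyi|classify|yield|chm|validate|demo`);
`demo --seed 42 --outdir out/` runs the full synthetic pipeline and is
byte-reproducible per seed.

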