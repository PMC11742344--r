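# phycoscan

Hyperspectral core scanning can detect sedimentary photopigments *in situ*,
without wet-chemical extraction. `phycoscan` implements the measurement
chain for the cyanobacterial pigment **phycocyanin (PC)**, which absorbs
near 620 nm, alongside the chlorins (chlorophyll *a* and derivatives,
~660–675 nm) whose much stronger absorption trough overlaps and can mask
the PC signal. It is aimed at paleolimnologists who scan lake-sediment
cores with VNIR (400–1000 nm) line-scan cameras and want reproducible,
scriptable pigment indices instead of point-and-click workflows.

## What it computes

Raw scans are scaled to 0–1 reflectance against a white (BaSO₄) and dark
(closed-aperture) reference, `R = (raw − dark)/(white − dark)`. Absorption
features are then measured per pixel with the **relative absorbance band
depth**:

```
RABD_min = ((X_right · R_left + X_left · R_right) / (X_right + X_left)) / R_min
```

where `R_left`, `R_right` are reflectances at the trough's endpoint bands,
`R_min` at the trough minimum, and `X_left`, `X_right` count bands from the
endpoints to the minimum. A flat spectrum gives exactly 1; deeper troughs
give larger values. The companion **RABA** integrates the relative
reflectance deficit below the endpoint chord. Default trough windows are
conservative and non-overlapping — PC (600, 620, 640) nm and chlorins
(650, 673, 700) nm — so RABD620 reflects PC only.

Around these operators the package provides:

- continuum removal by upper convex hull (for spectral QC and the
  trough-disappearance diagnostic);
- spiking-series normalisation (`RABD_spiked / RABD_unspiked`), OLS
  calibration models with R², slope p-values and tenfold cross-validated
  RMSEP;
- a chlorophyll-*a* interference analysis: RABD620 response to Chl *a* at
  fixed PC, the Chl *a*/PC vs RABD620/RABD675 masking curve, and the
  Chl *a* mass at which the PC trough vanishes;
- downcore RABD profiles at pixel (~80 µm) depth resolution;
- ENVI cube I/O and a deterministic end-to-end pipeline (`run_pipeline()`);
- a synthetic spiking-experiment generator with known ground truth
  (Gaussian absorbance troughs on matrix-specific backgrounds, Beer–Lambert
  spectrophotometer series) used to validate every stage.

## Worked example

Simulate an organic-sediment PC spiking experiment (cumulative 0/50/100/150
µg on one aliquot), compute the normalised RABD620 series and calibrate it:

```r
library(phycoscan)
specs <- default_matrix_specs(noise_sd = 0.01, seed = 7)
plan  <- spike_plan("PC", c(0, 50, 100, 150))
sim   <- simulate_spiking_cubes(specs$organic, plan, shape = c(8, 8))
tr    <- default_troughs()
ser   <- normalize_series(spike_series(sim$cubes, plan$masses, tr$RABD620))
ser
#>   step mass_ug index index_normalized
#> 1    0       0 1.008            1.000
#> 2    1      50 1.403            1.392
#> 3    2     100 2.009            1.994
#> 4    3     150 2.831            2.809
build_calibration_report(ser, seed = 7)$model
#> <calibration_model> y = 0.8942 + 0.01206 x | R2 = 0.9759, p = 0.0121, n = 4, RMSEP = 15.1% (4-fold CV)
```

The unspiked aliquot sits at RABD620 ≈ 1 (no trough); each 50 µg spike
deepens the 620 nm trough, and the normalised index regresses on mass with
R² ≈ 0.98. With only n = 4 steps the tenfold CV falls back to leave-one-out
(warning) and the RMSEP is accordingly pessimistic.

Interference: keep PC fixed at 150 µg and add Chl *a* in 5 µg steps:

```r
iser <- simulate_interference_series(specs$organic, pc_mass = 150, seed = 7)
iser[, c("chla_mass_ug", "rabd620", "rabd675", "mass_ratio", "index_ratio")]
#>   chla_mass_ug rabd620 rabd675 mass_ratio index_ratio
#> 1            0   2.971  0.9724    0.00000       3.055
#> 2            5   2.799  1.0781    0.03333       2.596
#> 3           10   2.877  1.2096    0.06667       2.378
#> 4           15   2.829  1.3491    0.10000       2.097
#> 5           20   2.867  1.4781    0.13333       1.940
attr(masking_curve(iser), "spearman_rho")
#> [1] -1
```

RABD675 climbs with every Chl *a* addition while the RABD620/RABD675 ratio
falls monotonically (Spearman ρ = −1): the growing chlorin trough
progressively masks the PC trough even though the PC load never changes.

`run_pipeline(default_pipeline_config(seed = 1))` chains all of the above —
three sediment matrices, calibration tables, interference report, downcore
profile — into a deterministic output directory.

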