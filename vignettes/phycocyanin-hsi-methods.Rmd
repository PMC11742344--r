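---
title: "Methods: hyperspectral phycocyanin indices, calibration and interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral phycocyanin indices, calibration and interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoscan)
```

## The measurement model

Cyanobacteria leave two spectral fingerprints in lake sediments: the blue
phycobiliprotein phycocyanin (PC), absorbing near 620 nm, and chlorophyll
*a* with its degradation products (chlorins), absorbing near 660–675 nm.
A VNIR line-scan camera (400–1000 nm) images a split core at roughly 80 µm
per pixel; after scaling each pixel between a dark reference (0, total
absorbance) and a BaSO₄ white reference (1, total reflectance), pigment
loads express themselves as absorption troughs in the 0–1 reflectance
spectrum.

`phycoscan` quantifies a trough with the relative absorbance band depth.
For a trough with endpoint bands $\ell$ and $r$ and minimum band $m$,

$$\mathrm{RABD} = \frac{(X_r R_\ell + X_\ell R_r)/(X_r + X_\ell)}{R_m},$$

where $X_\ell = m - \ell$ and $X_r = r - m$ are band counts. The numerator
is the straight-line continuum interpolated at the minimum band, so a flat
or linear spectrum yields exactly 1 and depth grows the value. The band
area variant, RABA, sums the relative deficit $(C_i - R_i)/C_i$ below the
endpoint chord $C$; the division by $C_i$ makes it invariant to rescaling
the spectrum, which is the natural choice given that the 0–1 scaling
already removes illumination level (the exact area formula is a package
design decision; several variants circulate in the literature).

Two methodological commitments matter:

- **Pixel-first statistics.** Indices are computed per pixel and then
  averaged over the region of interest. Because RABD is a ratio, this is
  *not* the same as evaluating the index on the ROI-mean spectrum on
  heterogeneous surfaces (a Jensen-type gap the test suite demonstrates);
  the per-pixel order matches how core-scanning workflows report sample
  statistics.
- **Conservative windows.** Default trough profiles are
  RABD620 = (600, 620, 640) nm, RABD675 = (650, 673, 700) nm,
  RABD660 = (650, 660, 690) nm (broader chlorin profile for downcore
  work), RABD845 = (800, 845, 880) nm (bacteriopheophytin *a*). The PC and
  chlorin windows share no band, so each index reads one pigment, at the
  price of underestimating absolute trough depth. All profiles are
  configurable; wavelengths snap to the nearest band centre with ties
  going to the lower band. RABD is evaluated on calibrated reflectance —
  the formula embeds its own local two-point continuum — while full convex
  hull continuum removal is reserved for spectral display and the
  trough-disappearance diagnostic.

Continuum removal divides the spectrum by its upper convex hull, computed
with a monotone-chain scan over (wavelength, reflectance) points; collinear
interior points are dropped, so equal-reflectance ties keep the earlier
band as the segment vertex. The hull is fitted over a configurable window
(default 550–850 nm) rather than the full camera range: the window
brackets all three pigment troughs while excluding the noisy edge bands,
and which window a given ENVI-based workflow uses is generally
undocumented, so both windowed and full-range hulls are supported.

## Calibration statistics

Spiking experiments add known pigment masses to sediment aliquots and
rescan after each step. The ROI-mean index per step is normalised by the
unspiked (step 0) value, removing baseline differences between sediment
matrices, and regressed on cumulative mass by ordinary least squares. The
slope p-value uses the t distribution with $n-2$ df, uncorrected — raw
p-values are what short calibration series support. RMSEP comes from
tenfold cross-validation: fold membership is a seeded random shuffle
applied to a canonically ordered copy of the points (sorted by x, then y),
which makes the estimate independent of input order while remaining fully
seed-reproducible. When $n$ is below the fold count — routine for 3–4-step
spiking series — the folds reduce to $n$, i.e. leave-one-out, with a
warning. RMSEP is reported as a percentage of the mean observed response by
default; range and maximum denominators are available because published
"RMSEP %" figures rarely state their normaliser.

Spectrophotometric reference concentrations use Beer–Lambert,
$A = \alpha L c$, with $\alpha = 88.15$ l g⁻¹ cm⁻¹ for chlorophyll *a* in
100 % acetone, and the classical two-wavelength phycocyanin equation
$\mathrm{PC} = (A_{620} - 0.474\,A_{652})/5.34$ mg ml⁻¹, whose
coefficients are exposed as arguments since several published variants
exist; a negative corrected numerator is floored at zero with a warning.

## The synthetic spiking generator

No public desk-scale raw cubes accompany the workflow, so validation runs
on a generator whose ground truth is known exactly. It emulates:

- **Matrix backgrounds.** Three sediment classes — wet organic gyttja,
  wet clastic silt/clay, dry homogenised CRM — as concave, monotone
  baselines interpolated linearly between knots. Linear interpolation is
  deliberate: a concave knot sequence then lies exactly on its own upper
  hull, so an unspiked background is trough-free by construction
  (continuum removal returns 1 to machine precision).
- **Pigment troughs.** Gaussian absorbance profiles
  $A_p(\lambda) = s_p\, m_p \exp(-(\lambda-c_p)^2/2\sigma_p^2)$ at
  $c = 620/673/845$ nm, mapped to reflectance by the transmittance
  convention $R = R_{bg}\,10^{-A}$ and clipped to (0, 1]. The Gaussian
  shape and the σ defaults (PC 12 nm, Chl *a* 10 nm, Bphe *a* 15 nm) are
  design choices consistent with published trough widths; no line shape is
  standardised for sediment spectra.
- **Sensitivities.** Per-matrix absorbance per µg: 0.004 (organic),
  0.002 (clastic), 0.006 (crm) for PC and 0.010 for Chl *a*. These encode
  the matrix effect — organic sediments give the most consistent response,
  clastic the weakest (pigment solution drains into pores) — and the
  roughly five-fold stronger light absorption of Chl *a* per unit mass.
  A `visibility` parameter (default 1) scales the optically effective
  fraction of the spiked mass, standing in for pore-water losses that no
  published value constrains.
- **Noise.** I.i.d. Gaussian reflectance noise per pixel and band
  (default sd 0.01), added after trough application; real sensor noise
  structure (striping, band correlation) is not modelled.
- **Spectrophotometer series.** Exact Beer–Lambert lines with optional
  Gaussian absorbance noise.

All randomness is driven by explicit seed arguments; identical
(spec, plan, seed) triples give bit-identical cubes, and the full pipeline
writes byte-identical CSVs when rerun with one seed.

What passing tests on this generator show — and do not show: they verify
the algebra, geometry and statistics of the measurement chain (index
formulas, hull construction, estimator behaviour, interference
directions), not radiometric fidelity to any particular sediment. Real
cores add surface roughness, moisture gradients, carbonate/organic
mixtures and pigment diagenesis that the generator does not attempt.

## The interference analysis and a turnover the generator reveals

Keeping PC fixed (150 µg) while spiking Chl *a* (0–20 µg in 5 µg steps)
reproduces, at zero noise, three qualitative findings: RABD675 rises
(close-to-linearly) with Chl *a*; RABD620 falls although PC never changes;
and the RABD620/RABD675 ratio declines monotonically with the Chl *a*/PC
mass ratio (Spearman ρ = −1), the masking relation. "Trough disappearance"
is operationalised as the loss of a local minimum of the continuum-removed
spectrum inside the PC window — no standard criterion exists.

A generator sweep over the Chl *a* trough width adds a caveat worth
stating: the interference is **not monotone in σ**. The RABD620 slope
magnitude and the masking strength grow while the chlorin trough overlaps
the PC window only partially (up to σ ≈ 25–30 nm at these windows) and
then *fade*, because a trough much wider than the window depresses the
trough centre and both shoulders almost equally, cancelling in the
band-depth ratio. Sign-based statements (negative slope, ρ = −1) are
robust; magnitude-based comparisons across widths are only meaningful
within the partial-overlap regime, and the tests are phrased accordingly.

## Numerical choices and degenerate inputs

- Calibrated reflectance outside [0, 1] (sensor noise) is clipped; the
  generator floors reflectance at 10⁻⁶ so ratio indices stay defined.
- A white reference equal to the dark reference in any band aborts
  calibration with a band-identifying error.
- Pixels with non-positive reflectance at the minimum band (dead pixels)
  are masked as `NA` in index maps and counted in a message; ROI means use
  finite values only and reject empty masks.
- The floating-minimum option (`float_min`) searches the deepest band
  strictly inside the trough window; the default keeps the fixed centre
  band, which is the conservative choice when troughs may shift.
- ENVI I/O supports data types 4/5 and all three interleaves; type 5
  (float64) round-trips R doubles bit-exactly. Errors are classed
  conditions (size mismatch with expected vs found byte counts, unknown
  interleave, missing wavelengths).
- Depth in downcore profiles is `(row − 1) × pixel size`, row 1 at the
  core top; a 100-row scan at 80 µm spans 0–7.92 mm.

## Problem sizes

The shipped defaults and test sizes are chosen as the smallest
configurations that exercise every code path meaningfully: 301-band
(2 nm) axes, 4×4 to 8×8 pixel aliquot cubes, 4-step PC and 5-step Chl *a*
spiking plans, 500-seed slope-recovery and 1000-seed type-I-error
simulations, and a 200-spectrum hull-oracle comparison. Scaling to full
scans (thousands of rows) is linear in pixels; `index_map()` is fully
vectorised over the spatial dimensions.

## Known limitations

- No spectral deconvolution of overlapping troughs; the conservative
  windows trade depth for specificity, and severe Chl *a* excess still
  masks PC (use the masking curve and the detectability threshold to judge
  when).
- No correction algorithm for the Chl *a* interference is provided, only
  its quantification.
- The generator's matrix effect is purely a sensitivity/background
  parameterisation; porosity and water content are not mechanistically
  modelled.
- No geometric calibration, mosaicking, or white-reference drift
  correction; one wavelength axis per cube.
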