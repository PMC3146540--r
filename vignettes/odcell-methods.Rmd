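---
title: "Methods: from optical density to cells, volumes and concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from optical density to cells, volumes and concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(odcell)
```

## The problem

Omics measurements on bacterial cultures are usually normalized to the
culture's optical density (OD600): so many moles of a metabolite or
protein per ml of culture per OD unit. Mathematical models need
intracellular molar concentrations or absolute copy numbers per cell.
Converting between the two requires knowing, for the growth condition at
hand, how many cells one ml·OD of culture contains (N, cells·ml⁻¹·OD⁻¹)
and how much total cell volume it carries (V_tot, µl·ml⁻¹·OD⁻¹). Both
quantities are condition dependent — which is exactly why a fixed
conversion factor applied across conditions is wrong.

This package ships a curated reference table of these quantities for
*E. coli* BW25113 (plus two MG1655 comparison rows) across 24 rows
covering complex medium, eight minimal-medium carbon sources (with and
without amino acid supplement), four stress conditions, four
glucose-limited chemostat dilution rates and two stationary-phase time
points, and implements the measurement chain that produced them so that
each stage can be validated on synthetic data with known ground truth.

## The three empirical relationships

1. **Cell volume grows with growth rate.** Mean cell length ranges from
   1.6 µm (stationary) to 3.9 µm (complex medium); width is condition
   independent at 1.26 ± 0.16 µm. Treating the cell as a cylinder of
   width w capped by two half-spheres, the single-cell volume is
   V = π·w²·(l − w/3)/4, giving 1.5–4.4 fl across conditions.
   `fit_volume_vs_mu()` fits V against log₁₀(µ) with a polynomial
   (degree 2 by default — the smallest degree that captures the visible
   curvature on a log axis; the degree is a parameter because the
   original functional form is not printed, so our fit is a
   re-derivation, not a reproduction).
2. **The OD-specific cell concentration falls with growth rate**, by a
   factor of four between the slowest and fastest growing conditions
   (23.0 vs 5.9 ×10⁸ cells·ml⁻¹·OD⁻¹).
3. **Their product is nearly constant:** V_tot = V × N ≈ 3.6 µl·ml⁻¹·OD⁻¹
   (mean 3.63 over the 24 rows, extremes 2.4–4.9, ratio ≈ 2). This is
   the workhorse constant for molar conversions:
   `conc [mol/L] = amount [mol·ml⁻¹·OD⁻¹] / (V_tot × 10⁻⁶)`.

`predict_cell_concentration()` combines (1) and (3) into the reciprocal
model N(µ) = V_tot·10⁹ / V(µ), so a user who knows only OD and growth
rate can estimate cells/ml.

### Known tensions in the reference values

Two printed values do not reproduce exactly from the other printed
values, and the package reports the recomputed numbers rather than the
printed ones:

- The complex-medium (LB) volume prints as 4.4 fl, but
  `capped_cylinder_volume(3.9, 1.26)` = 4.34 fl, which rounds to 4.3.
  The printed value was presumably computed from the unrounded mean
  length. All 24 rows agree within ±0.2 fl, consistent with
  input rounding.
- The reciprocal model with the global mean V_tot predicts the printed N
  within a factor 1.35 for 20 of the 22 growing conditions; the two
  amino-acid-supplemented rows (which have the lowest printed V_tot,
  2.4–2.5 µl) miss by factors up to 1.54. The model is a cross-condition
  approximation; per-condition table lookups are exact by construction
  and are preferred whenever the condition is known.

## Measurement chain

### Morphometry

`segment_and_measure()` thresholds a fluorescence image (Otsu's method on
a 256-bin histogram), labels 8-connected components, discards components
below a minimum area and those touching the border (their full length is
unmeasurable), and measures each object's length and width as the
extents along the principal axes of its pixel cloud (a Feret-style
measure; skeleton-based lengths would only matter at higher aspect
ratios than *E. coli* reaches). A blank, noise-only image yields no
objects — operationally, any image whose post-threshold foreground
fraction exceeds 35 % is treated as having no sparse objects to measure,
because a pure-noise histogram splits near its middle.

`summarize_population()` enforces the protocol floor of 200 cells per
condition (overridable with an explicit flag) and computes volumes under
two policies: the default `fixed_mean_width` uses w = 1.26 µm for every
cell, matching how the reference volumes were computed; `per_cell_width`
uses each cell's own width for sensitivity analysis. Under the fixed
policy, a measured length below 1.26 µm is clamped to the sphere limit
l = w so the formula's precondition holds — this only matters for
near-spherical stationary-phase cells.

Validation: on synthetic single-rod images the measured length is within
0.15 µm (≈1.6 px) of truth, the mean absolute length error over the
1.6–3.9 µm range is ~0.6 px, and fifteen simulated 7 µm beads are
recovered at 7.06 µm mean diameter — comfortably inside the ±0.2 µm
acceptance band and far inside the ±1.8 µm SD of the real bead control.
Width carries a systematic +0.1 µm pixelation/blur bias at this
resolution (the minor-axis extent of a tilted pixelated rod overshoots);
this is why volumes use the fixed-width policy by default and why the
width check in the acceptance suite uses the per-object budget rather
than a standard error.

### Bead-referenced counting

`absolute_concentration()` implements four steps: cells are counted in a
FL1×SSC gate, beads in an FSC×SSC gate (`gate_events()`, rectangular
gates in log₁₀ channel units — the original gates were drawn manually
and are not numerically specified); the analyzed volume follows from the
bead fraction seen, `analyzed = (bead_count / beads_total) × tube_volume`;
and concentration is cells over volume. `beads_total_in_tube` has no
default: it is the bead lot concentration times the 20 µl aliquot and is
lot specific. The 400/380 bead-aliquot dilution is corrected by default
(a ~5 % effect); whether the original analysis corrected it is not
stated, so a flag disables the correction for sensitivity analysis.
Poisson counting error is the only uncertainty modeled:
SE/value = √(1/cells + 1/beads).

### OD calibration

Plate-reader ODs are non-linear in true (spectrophotometer) OD.
`calibrate_od()` builds a monotone correction from paired samples
spanning 0.001–10 OD: a Hyman-filtered monotone cubic interpolant in
log–log space. Outside the calibrated device range the multiplicative
boundary correction is clamped, with a warning — extrapolating a
saturation curve is not defensible. The reference table itself is in
spectrophotometer OD; the correction exists for plate-reader workflows.

### Unit conversion and uncertainty

For an amount A in mol·ml⁻¹·OD⁻¹ (the unit tag is mandatory — untagged
numbers are refused rather than guessed):

- copies per cell = A · N_A / N,
- molar concentration = A / (V_tot × 10⁻⁶ L),

both exactly linear in A. When V_tot is taken as the product V × N
(`vtot_source = "product"`), the two outputs are mutually consistent:
copies / (V_cell[L]·N_A) = molarity. With the printed per-condition
V_tot (the default) they agree within the table's internal rounding
(≤ ~1.4 %). Molar concentrations refer to total cell volume; no
aqueous-accessible volume correction is attempted.

Uncertainty propagates from the table's ±SD on N and V, treated as
independent log-normals (nothing about their error distribution is
stated beyond ±SD; log-normals keep both quantities positive). A printed
"m ± s" is mapped to a log-normal with **median** m and log-scale SD
matching the CV — the symmetric-reporting convention. The alternative
(mean = m) inflates the mean of the reciprocal that enters the molar
conversion by exp(σ²) ≈ 15 % at the table's volume CVs, an artifact of
the parameterization rather than information in the data. Monte Carlo
(default 10,000 seeded samples) and first-order delta-method SDs agree
within ~8 % on glucose factors. Note the volume SD in the table is the
cell-to-cell spread, not the standard error of the condition mean, so
these SDs are deliberately conservative.

## The synthetic world

The generators emulate the statistical structure the analysis assumes,
with stated defaults:

- **Images**: 0.092 µm/pixel; rods as 2-D stadium projections of capped
  cylinders with lengths N(mean, SD) per condition and widths
  N(1.26, 0.16); beads as 7 µm disks; Gaussian PSF (σ = 0.1 µm, a
  diffraction-scale blur), constant background plus Gaussian read noise
  at high SNR (clean agarose-pad fluorescence imaging). Touching cells
  are not rendered by default: adjacency was resolved manually in the
  protocol, so the measurement pipeline is entitled to assume separated
  objects; `allow_touching = TRUE` exists for robustness experiments
  only. Every rendered image comes with the pre-blur label mask as a
  measurement oracle.
- **Event tables**: per-class counts Poisson in the analyzed volume
  (30 µl of a 400 µl tube by default — at the protocol's working
  concentration of ~10⁶ cells/ml this yields the ~30,000 cell events
  per sample the protocol targets); per-class log-normal FSC/SSC/FL1
  with ≥3 log-SD separation (real channel scales are instrument
  dependent and unpublished, so the scales are arbitrary but the
  separability is faithful to gatable real data); a debris class at
  10⁵/ml keeps gating honest.
- **Replicates**: day-to-day variability enters as multiplicative
  log-normal noise with 10 % CV on the true concentration, matching the
  protocol's reported upper bound.
- **OD pairs**: device OD = K·OD/(K + OD) with K = 2 (saturation at
  device reading ~2, typical of plate readers) plus 1 % multiplicative
  noise, over 0.001–10.

What a green test does *not* establish: robustness to touching or
overlapping cells, uneven illumination, autofluorescence, spillover or
doublets; FSC detection-limit truncation for tiny stationary cells
(described only qualitatively in the source material, so not modeled);
or correctness of the channel scales. These are documented limits of the
synthetic world, not of the arithmetic.

## Numerical and design choices

- Stationary cells (µ = 0) join the volume fit at a pseudo growth rate
  of 0.1 h⁻¹ (the plotting convention for log axes) but are excluded
  from the concentration model's domain; growth rate is undefined at
  stationarity. Extrapolation outside the observed µ range
  [0.12, 1.62] h⁻¹ is refused unless forced.
- The V_tot estimator is the unweighted mean across conditions; no
  replicate weights are available for most rows. Weighted alternatives
  can be computed from the exported table.
- `fit_volume_vs_mu()` accepts down to degree+1 points (exact
  interpolation, residual SD 0); a numerically non-monotone fit over the
  observed range warns rather than errors.
- Rounding to "table precision" uses half-away-from-zero at one decimal,
  matching how the printed values behave.
- Images are exchanged as uncompressed 16-bit little-endian grayscale
  TIFF via a minimal internal codec (no TIFF library dependency); config
  and model files are JSON.

## Limitations

The reference values are instrument- and strain-conditional: OD600 on a
different spectrophotometer, or a strain far from K-12, shifts N and
V_tot. Scatter-to-volume calibration (`calibrate_scatter_to_volume()`)
must be re-derived per instrument — scatter units are not portable.
Conversions are population averages; single-cell heterogeneity of copy
numbers is out of scope, as is dry-weight-based normalization.
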