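---
title: "Models and design choices behind the mammostroma pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the mammostroma pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammostroma)
```

`mammostroma` implements five quantification pipelines used to characterize
the breast tissue microenvironment — pericellular ECM quantification in
multiplexed images, Hertzian AFM stiffness estimation, structure-tensor
collagen coherency, fibroglandular-volume densitometry, and paired assay
statistics — together with seeded synthetic-data generators that carry
ground truth for each of them. This vignette records the models, the
parameters that matter, and the design decisions taken where the procedure
admitted more than one reasonable reading.

## Pericellular quantification in multiplexed images

### Model and procedure

A multiplexed acquisition is a channel stack (`H × W × C`, nonnegative
intensities) with a cell-segmentation label mask produced upstream
(segmentation itself is out of scope; masks are consumed). The chain is:

1. **Hot-pixel filtering.** A pixel whose value exceeds the maximum of its
   8 neighbours by more than a threshold (default 50, the convention for
   raw-count multiplexed data) is replaced by that neighbourhood maximum.
   The rule is idempotent, and the boundary is strict: a pixel exactly at
   `neighbour_max + threshold` is kept.
2. **Normalization.** Per channel, min–max scaling to `[0, 1]`; constant
   channels map to all zeros by convention. Synthetic scenes are generated
   directly on this normalized scale, so the demonstration pipeline applies
   the filter and masking to them without re-normalizing.
3. **Tissue/void masking.** The (normalized) tissue channels are summed,
   clipped at the 90th percentile — the small, very bright cell mode would
   otherwise dominate the between-class variance — and thresholded with
   Otsu's method, followed by morphological closing (disc brush, 5 px).
   Labelled-cell pixels are always tissue. An all-zero image is 100 % void,
   not an error.
4. **Cell classification.** Cells are gated epithelial on the
   E-cadherin-channel mean (threshold configurable; default the median over
   all cells). Marker-high cells are epithelial cells whose marker mean
   exceeds a threshold chosen by strategy: a fixed or analyst-supplied
   value, or a quantile of the epithelial marker means (default q = 0.8,
   i.e. top 20 %, since fixed-top-20 % selection is reported to behave
   equivalently to analyst thresholds for this readout). Marker-low cells
   are the equal number of lowest-expressing epithelial cells, so
   `|low| = |high|` holds on every image by construction. If more than half
   the epithelial cells sit above the threshold the matched classes would
   overlap, which is an error rather than a silent truncation.
5. **Pericellular means.** For each classified cell, a disc of radius
   `radius_um / pixel_size_um` (default 10 µm) is drawn around the centroid,
   membership by pixel-centre-to-centroid Euclidean distance. Pixels of
   *any* labelled cell — including the index cell — and void pixels are
   excluded; the mean of each ECM channel over the remainder is the
   pericellular intensity. Excluding the index cell reads "pericellular" as
   strictly extracellular; `include_index_cell = TRUE` restores the other
   reading. The disc is fixed rather than adaptively shrunk: masking
   preserves the stated radius and is deterministic.
6. **Validity gate.** Cells whose valid-pixel fraction falls below
   `min_valid_fraction` (default 0.1) keep `NA` means and are excluded from
   statistics. The gate exists because a near-empty disc would otherwise
   produce an unstable mean from a handful of pixels.

### Statistics

Class comparisons use one summary value per participant and condition
(participant-level means, not pooled cells, to avoid pseudoreplication),
fitted as a within-subject one-way ANOVA. With complete one-observation
blocks the classical repeated-measures F equals the condition F from the
additive two-way fit `value ~ condition + participant`, which is what
`compare_classes()` computes via `stats::aov()`; the equivalence is verified
in the tests against an explicitly coded sum-of-squares decomposition.
Pairwise follow-ups are paired t-tests with the Sidak adjustment
`p_adj = 1 − (1 − p)^m` over all `m` pairs.

## Hertzian AFM stiffness

The spherical-indenter Hertz model in the reduced-modulus convention,

$$F = \tfrac{4}{3}\, E_r \sqrt{R}\, \delta^{3/2},$$

relates force to indentation depth with no assumption on the Poisson ratio.
Defaults mirror a typical soft-tissue protocol: probe radius 2.5 µm (5 µm
colloidal sphere), 50 nm maximum indentation.

Fitting is two-stage and fully deterministic:

1. The whole curve is fitted by Levenberg–Marquardt least squares
   (`minpack.lm::nlsLM`) for three parameters: amplitude, contact offset and
   a constant force baseline. Using every sample avoids a subtle selection
   bias — choosing points by their own noisy force keeps upward-noise
   realizations near thresholds and drags the contact point negative — and
   lets any pre-contact segment pin the baseline. The problem is
   nondimensionalized (indentation by its span, force by the smoothed
   maximum) because the raw parameter scales differ by ~13 orders of
   magnitude and make the least-squares gradient numerically singular.
   Initialization comes from the linearized model: `F^{2/3}` is linear in
   `δ`. If the start lies exactly on the solution (noiseless curves), the
   model constructor's singular-gradient check fires; the fit is retried
   once from a fixed offset start.
2. The modulus is then re-estimated by linear least squares on the stated
   fitting boundary — samples whose baseline-corrected force lies in the
   inclusive 25–75 %-of-maximum window — with offset and baseline fixed.
   The window is located on a lightly smoothed (7-point running mean) force
   trace, again to keep per-sample noise out of the selection. `r²` is the
   coefficient of determination on that window; computing it on the window
   rather than the full curve matches the domain the modulus was estimated
   on.

Quality control is exactly two-stage and order-sensitive: first fits with
`r² < 0.95` are removed, then moduli outside `mean ± 2 SD` of the remaining
population. The outlier boundary is inclusive, so identical moduli (SD = 0)
all survive. The trim population is per sample by default (`by` argument),
since the per-region/per-sample/global choice is not dictated by the
procedure itself. Baseline/post comparisons use a pooled-variance two-sample
t-test by default, with Welch behind a flag.

Under the generator's study conditions (200 curves, signal-to-noise ≈ 20)
the median relative bias of the recovered modulus is well under 2 %, and the
relative RMSE across a 1–20 kPa grid is under 5 %. Note that at SNR ≈ 20 the
window `r²` of a *clean* curve is around 0.89: the `r² ≥ 0.95` gate assumes
the instrument noise regime of real acquisitions, which the demonstration
configuration emulates with a lower noise level (1.2 pN) so that the gate
separates corrupted from clean curves rather than discarding everything.

## Structure-tensor coherency

For a region of a grayscale image, gradients are taken by centred finite
differences after Gaussian pre-smoothing (default σ = 2 px, a local-window
scale comparable to common orientation-analysis tools; the region must be at
least 3 × 3 and border pixels without a defined centred difference are
excluded). The structure tensor averaged over the region gives

$$C = \frac{\lambda_{max} - \lambda_{min}}{\lambda_{max} + \lambda_{min}} \in [0, 1],$$

with `C = 0` declared for zero-gradient (constant) regions and the dominant
texture orientation taken perpendicular to the principal gradient
eigenvector, reported in degrees `[0, 180)` from the image row axis.
Coherency is exactly invariant to positive intensity rescaling and, to
discretization error, to rotation. Lobule averaging is hierarchical — mean
over regions within lobule, then over lobules (warning below three, the
stated minimum) — so that lobules with many regions do not dominate.

The fibre generator superposes sinusoidal gratings whose orientations are
drawn around the dominant angle with angular SD `dispersion` (radians);
dispersion 0 yields a strictly periodic, single-orientation pattern with
`C > 0.95`, pure noise (`amplitude = 0`) yields `C ≈ 0.02` on a 256² image.
Coherency decreases monotonically in dispersion, which is the property the
test suite checks rather than any particular calibration curve.

## Densitometry

`compute_fgv()` is a voxel count: fibroglandular voxels over fibroglandular
plus fat, background never entering the ratio. Counts are unweighted by
voxel size, matching pixel-count practice; anisotropic-voxel weighting would
be a straightforward extension but is deliberately not a hidden default.
Volpara grade classification is lower-inclusive exactly as printed
(`4.5`, `7.5`, `15.5` % boundaries); values outside `[0, 100]` are errors.

## Assay statistics

- **Wilcoxon signed-rank.** Zero differences are dropped (Wilcoxon's
  original rule, the common software default) rather than Pratt's method.
  With no ties among the absolute differences and `n ≤ 25`, the two-sided
  p-value is exact, computed from the signed-rank distribution
  (`stats::psignrank`, equivalent to full sign enumeration — the test suite
  verifies this equivalence by enumerating all `2^n` assignments for
  `n ≤ 8`). Otherwise a normal approximation with tie-corrected variance
  `n(n+1)(2n+1)/24 − Σ(t³−t)/48` is used, without continuity correction;
  this matches `stats::wilcox.test(correct = FALSE)` to 10 decimal places,
  which is the behaviour inherited by the common plotting front-ends.
- **Reporting arithmetic.** `category_fraction()` rounds half away from
  zero (1 decimal or integer), the convention that reproduces printed
  percentages such as 41.5 % (27/65), 90 % (1373/1519) and 96 % (1454/1519).
- **MFE and colonies.** Inclusive thresholds: spheres of diameter ≥ 50 µm,
  colonies of ≥ 50 cells. Both metrics are order-invariant in their inputs.

## What the generators emulate — and what they do not

The generators reproduce the *quantitative structure* the pipelines rely on:
known enrichment factors in closed-form geometry (disc-shaped cells, a
multiplicative annulus, minimum cell separation large enough that one cell's
measurement disc cannot touch another's enrichment zone), exact Hertz
forward curves with a controlled corrupted fraction (linear drift plus an
adhesion dip, amplitudes set so the corrupted curves genuinely fail the `r²`
gate), controllable texture anisotropy, exact voxel counts and paired tables
with known shifts. One root seed drives everything; identical specs produce
bit-identical output, and the scene/curve/assay sub-streams are derived
deterministically per object.

They do **not** emulate realistic tissue morphology, isotope spillover,
detector physics, scanner artefacts or cell-shape variability. Passing tests
therefore demonstrate the correctness of the computations and their
invariances, not robustness to every failure mode of real acquisitions —
analyst-facing parameters (thresholds, radii, QC gates) remain exposed
precisely because real data will exercise them differently.

## Problem sizes and runtime choices

The test and demonstration configurations are sized for quick, repeatable
runs: 256² scenes with 8 + 8 cells (20 seeds for the enrichment recovery),
200 Monte-Carlo force curves of 100 samples, 100 random QC instances, 20
noise images for the isotropic coherency limit, 500 enumeration checks of
the exact signed-rank p-value, and a demonstration pipeline (4 participants'
scenes, 3 AFM samples × 2 timepoints × 60 curves, 6 × 2 × 3 fibre images,
12 × 2 volumes, a 19-participant assay table) that completes in seconds and
is byte-stable across reruns. Larger inputs change none of the code paths —
all functions are vectorized or stream per object.

## Known limitations

- The pericellular disc uses the *rounded* centroid as its centre; at
  pixel sizes ≳ cell radius this quantization could matter, but at the 1 µm
  scale of the target data it is negligible (and translation invariance by
  whole pixels is exact, which the tests assert).
- The contact-point estimator assumes a monotone indentation ramp per
  curve; retraction segments and deep adhesion wells outside the modelled
  corruption modes are not handled.
- `compute_tissue_mask()` assumes void regions are (near) signal-free;
  autofluorescent or smeared backgrounds would need a different masking
  strategy, which is why the mask is an explicit, replaceable input to
  `pericellular_intensity()`.
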