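---
title: "Methods: 2-D lesion texture radiomics in livertex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2-D lesion texture radiomics in livertex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livertex)
```

# The pipeline and its assumptions

`livertex` analyses one grayscale slice per subject together with a binary
lesion mask. The working assumptions are:

* the mask is authoritative — the ROI is exactly the set of true mask
  pixels, with no dilation, erosion, or re-contouring, and nothing outside
  the mask may influence a feature value;
* the slice has already been chosen (e.g. the largest lesion cross-section);
  slice selection is not re-implemented;
* intensities are in arbitrary units that may drift between scanners and
  sessions, which is why every matrix feature consumes *relative* gray
  levels and the three histogram features retained (variance, skewness,
  excess kurtosis) are location-invariant.

The stages are: adaptive Wiener denoising → fixed-bin-number gray-level
discretization → texture matrices (co-occurrence, gray-gradient, run-length,
size-zone) and a Gabor bank → a 233-entry feature vector per subject →
test-retest reproducibility selection → pairwise Kruskal–Wallis screening
with per-feature ROC → four classifiers with cross-validation, a held-out
validation cohort, and bootstrap stability.

# Preprocessing

**Wiener filter.** A pixel-wise adaptive filter over `window × window`
neighborhoods (default 3 × 3; the window is the only tuning knob and the
default is the smallest symmetric neighborhood, appropriate for the fine
granularity of MR noise). Local means and variances use edge-truncated
windows; the noise power is the mean of the local variances — the standard
adaptive-Wiener convention. Where the local variance falls below the noise
estimate the filter returns the local mean. Filtering runs on the *whole
slice* before masking: the literature it follows filters full images, and
filtering a crop would make boundary pixels depend on the crop geometry.
(`wiener.enabled` turns the stage off.)

**Discretization.** In-mask intensities are resampled onto
`Range ∈ {16, 32, 64, 128}` levels with
`p(x) = floor(Range · (I − min) / (max − min + 1))`, min/max over the mask
only. The bracket is read as `floor` — the only reading that keeps `p`
integral. Stored levels are `p + 1`, spanning `1..Range`: several
run-length and size-zone statistics divide by the squared gray level, so a
level of 0 must never occur; the shift is order-preserving. A constant ROI
maps to level 1 everywhere. The default `Range = 32` balances histogram
occupancy against quantization loss for ROIs of a few hundred to a few
thousand pixels; all four values are selectable, which the
discretization-sensitivity analysis exploits. Note the `+ 1` in the
denominator (taken as given from the resampling convention this follows):
for continuous intensities whose span is not large relative to 1, it
compresses the occupied level range, so exact affine invariance holds for
shifts and only approximately (to one level, at floor boundaries) for
rescalings of wide-span images.

# Texture matrices and features

Directions are 0° = +column, 45° = up-right, 90° = up (−row), 135° =
up-left; diagonal steps are unit Chebyshev steps, so distance `d` at 45°
means an offset of `(−d, +d)`.

**GLCM (80 features).** Ordered in-mask pixel pairs at distance
`d ∈ {1,2,4,8}` along each of the four directions, symmetrized by adding
the transpose — equivalent to counting the four opposite directions as
well — and normalized. Ten statistics per matrix with these pinned
variants: Energy `Σp²`; Entropy `−Σ p ln p` (natural logs everywhere,
`0·ln 0 = 0`); Contrast `Σ(i−j)²p`; Correlation with the defined limit 0
when a marginal variance vanishes; Homogeneity `Σ p/(1+|i−j|)`; Sum
Variance as the variance of the `i+j` marginal; Cluster Shade and Cluster
Tendency as third/second central cross-moments; Inverse Difference Moment
`Σ p/(1+(i−j)²)`; Inverse Variance `Σ_{i≠j} p/(i−j)²`. Per distance, each
statistic is summarized by the mean and the *population* variance
(divisor 4) over the four directions; with transpose symmetrization an
8-direction reading would give identical values. A `(d, θ)` with no valid
pair yields the documented degenerate limits (Energy 1, Entropy 0,
Contrast 0, Correlation 0, Homogeneity 1, IDM 1, variances and the rest 0)
so cohort tables stay complete.

**GLGCM (15 features).** The per-pixel joint histogram of quantized gray
level and quantized gradient magnitude (the standard gray-gradient
co-occurrence reading; a direction-resolved variant would conflict with the
per-pixel definition). Gradients are 3 × 3 Sobel responses on the denoised,
unquantized intensities over the mask bounding box; out-of-mask pixels are
filled from their nearest in-mask neighbors by iterative 8-neighbor
propagation so the lesion boundary does not manufacture spurious gradients.
Gradient magnitudes are discretized by the same fixed-bin scheme to
`G = 16` levels — unstated upstream; 16 keeps the gradient axis
well-populated for small ROIs. Because the gradient axis is re-normalized
per image, gradient-level statistics are relative within a subject; tests
of "smoother image, smaller gradients" therefore live at the Sobel-operator
level, not the binned level.

**GLRLM (44 features).** Maximal same-level runs along each direction,
truncated at the mask boundary (a run never spans an out-of-mask pixel).
The eleven Galloway-style statistics (SRE, LRE, GLN, RLN, LGRE, HGRE,
SRLGE, SRHGE, LRLGE, LRHGE, and Run Percentage = runs per in-mask pixel)
are emitted separately per direction.

**ISZM (11 features).** Connected iso-level zones under 8-connectivity by
default (matching the 8-connexity used for co-occurrence pairs;
4-connectivity is available), counted by level and size, with the eleven
size-zone statistics including Zone Percentage = zones per in-mask pixel.

**Gabor bank (80 features).** 5 scales × 8 orientations. Center frequencies
are geometrically spaced from `f_high = 0.4` (scale 0) down to
`f_low = 0.05` cycles/pixel (scale 4) — the field's standard band for
texture work; orientations are `μπ/8`. Kernels are complex sinusoids under
an isotropic Gaussian envelope with `σ = 0.56/f` (one-octave bandwidth),
truncated at 3σ and DC-corrected to an exactly zero coefficient sum, so a
constant image gives zero response. Filtering uses the raw (denoised,
unquantized) intensities: quantization exists to make the *matrix* features
intensity-relative, and rounding would only add noise to a linear filter
bank. Responses are computed by FFT convolution of the bounding-box patch
with out-of-mask pixels replaced by the in-mask mean (`gabor.fill = "zero"`
is available) — mean fill avoids edge-response leakage from the dark
background; kernels larger than the ROI need no special casing because the
patch is padded with the same fill value. `S` is the in-mask mean of
|response|², `A` the mean of |response|.

The vocabulary totals 3 + 80 + 15 + 44 + 80 + 11 = 233 features, of which
3 + 80 + 15 + 44 = 142 describe local gray-level variation.

# Feature selection

Reproducibility is judged on test-retest replicate pairs: Lin's CCC with
population moments (two equal constant sequences → 0 with a warning, since
they carry no concordance information), and a dynamic-range statistic
`DR = 1 − mean|test−retest| / range(both replicates)`, clipped to [0, 1].
DR is the normalized mean absolute replicate difference from the
reproducibility literature; the name alone does not pin a formula, so the
definition is stated here and in the selection report. Thresholds default
to 0.9 for both. Redundancy pruning is greedy: candidates ranked by DR
(descending, ties by input order), a feature accepted iff its pairwise R²
with every already-accepted feature is `< 0.95`. "Close to 1" does not fix
a number; 0.95 removes near-duplicates (e.g. the same statistic at adjacent
distances) while keeping moderately correlated but distinct descriptors,
and the threshold is recorded in the report. Survivor counts are
data-dependent outputs, not targets. An empty survivor set is a legitimate
result.

# Screening, classifiers, stability

Screening applies the Kruskal–Wallis rank test (tie-corrected, chi-square
reference) per feature to each of the three pairwise class comparisons and
flags raw `p < 0.05` to match the study design; Benjamini–Hochberg adjusted
p-values are reported alongside for users who prefer FDR control.
Significant features get a ROC analysis: rank-formulation AUC, the
Youden-optimal cut-off (ties broken toward the lowest cut-off, evaluated at
midpoints between adjacent observed values), Hanley–McNeil standard error
and 95% CI; scores are oriented so AUC ≥ 0.5 with the direction recorded.

Each pairwise task uses the selected features significant for that pair,
capped at the `max_features = 12` smallest p-values — the study reduced the
feature vector before modelling, and a cap keeps logistic regression
well-posed at n ≈ 70–90 training subjects per task.

The four classifiers: KNN (k = 5, Euclidean, neighbor-vote fraction as
score), a one-hidden-layer backprop ANN (logistic activations, hidden-unit
count chosen from {3, 5, 10} by cross-validated AUC, weight decay 0.01 for
numerical stability, seeded initialization so refits are deterministic),
C-SVM with RBF kernel (cost × gamma over {0.1, 1, 10} × {0.01, 0.1, 1} by
cross-validated AUC; the decision value is mapped through a logistic link
so every model scores in (0, 1) and a single 0.5 threshold yields the
confusion matrix), and maximum-likelihood logistic regression (aliased
coefficients zeroed). Features are z-scored with statistics from the
training data only — inside every fold as well, so cross-validation is
leakage-free. Stratified 10-fold cross-validation on the training cohort
selects hyperparameters; the final model is refit on the full training
cohort and scored on the held-out validation cohort (accuracy, sensitivity,
specificity, Matthews correlation coefficient, AUC). Both the
cross-validated AUC and the validation AUC are reported, since either can
be meant by a "cross-validated performance" table.

Stability: `B = 100` bootstrap iterations (B is unstated upstream; 100
gives a ±0.1 σ-of-σ on the AUC spread at these cohort sizes), each a
stratified random half-split of the training cohort, training on one half
and AUC on the other; the result is the median ± sd of the B AUCs and
`RSD = σ/μ × 100`. Degenerate halves are skipped and counted, with ≥ 0.9 B
successes required.

# The synthetic phantom generator

The generator exists so the statistical machinery can be validated without
patient data. It emulates exactly the structure the analysis consumes:
256 × 256 slices with one elliptical lesion (semi-axes 8–30 px) on a darker
background (half the minimum class base intensity — rendered for visual
checking only; features never see it), three classes with distinct texture
parameters, cohort sizes 55/67/40 split 112/50 with stratification by
largest remainder, and 15 test-retest pairs sharing a noiseless texture
field with independent replicate noise. Per-class texture is
`base_intensity` plus a blurred Gaussian field (`blur_sigma`, scaled to
`intensity_sd`) for local correlation structure, a Voronoi blob field
(`blob_scale` mean cell diameter, i.i.d. cell offsets) for size-zone
structure, an optional linear ramp (`gradient_slope`) for gradient
structure, and i.i.d. noise (`noise_sd`). Every subject derives its own RNG
sub-stream from the master seed, so generation is deterministic and adding
subjects never perturbs earlier ones.

The default class parameters are *strongly separated* by construction
(e.g. in-ROI variability 8 vs 20 vs 30 intensity units, blob scale 0 vs 6
vs 3 px, a ramp only in one class); no quantitative inter-class effect size
is claimed by the upstream study, so these are free parameters fixed once
at values a reader would call clearly distinct. `separation = "none"` makes
the three classes identical for null checks. What the phantoms deliberately
do **not** model: MR acquisition physics (bias fields, partial volume, fat
signal, motion), irregular lesion shapes, background anatomy, or 3-D
structure. Passing tests therefore demonstrate that the pipeline recovers
planted texture differences and does not hallucinate absent ones — they do
not certify classification accuracy on clinical images.

# Discretization sensitivity

Recomputing the matrix features at 16 versus 128 gray levels probes which
families depend on the bin count. The per-feature change is summarized by
the *symmetric* relative difference `|a−b| / ((|a|+|b|)/2)` (0 when both
are 0; bounded by 2): several co-occurrence statistics grow polynomially
with the level count by construction (Contrast ∼ Range²), so an asymmetric
ratio would measure scale covariance rather than sensitivity, while the
symmetric form makes families of very different scales comparable. The
package's analysis contrasts the local families (GLCM + GLRLM) with the
low-intensity/large-zone size-zone statistics, whose dependence on zone
fragmentation makes them the bin-count-sensitive group; the test suite
checks the direction of the contrast with a paired test on 20 phantoms
rather than asserting any cohort-bound percentage.

# Numerical conventions and edge cases

* Entropies use natural logarithms; `0 · ln 0 = 0`.
* Degenerate matrices (constant ROI, zero-pair offsets) yield documented
  limit values rather than errors, so feature tables never hold NA.
* A zero-variance ROI returns skewness = kurtosis = 0 with a warning.
* The quantized-level container accepts any level count ≥ 2 so matrices can
  be built on hand-crafted level maps; the discretization itself only emits
  16/32/64/128.
* Youden ties break toward the lowest cut-off; redundancy ties keep input
  order; stratified folds recycle a shuffled 1..k sequence per class.
* Images are read as stored (PNG/TIFF rescaled to their integer bit range,
  NIfTI and CSV verbatim); cohorts are written as double-precision NIfTI
  plus PNG masks so write→read round trips are exact.

# Problem sizes used by the tests and the acceptance script

Unit tests run on 8–12 px level maps against brute-force enumerators and on
96–128 px phantoms for Monte-Carlo properties. The acceptance script runs
the full study-sized pipeline once (162 subjects, 15 retest pairs, four
classifiers, three tasks, B = 100), 20 null cohorts of 45 subjects at
128 × 128 for the chance-level check, 10⁴ label permutations for
Kruskal–Wallis calibration, and 20 phantoms for the discretization
contrast — sizes chosen so the whole script completes in a few minutes on a
single CPU while keeping Monte-Carlo error well inside the asserted bands.

# Known limitations

Single-slice 2-D analysis only (no 3-D matrices or inter-slice offsets);
no DICOM reader (convert to PNG/NIfTI first); no shape/morphology features;
no wrapper or embedded feature selection (LASSO, RFE); the GLGCM gradient
axis is per-image relative, so its statistics are not comparable across
images in absolute gradient units; the phantom generator's realism is
limited to the statistical structure listed above.
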