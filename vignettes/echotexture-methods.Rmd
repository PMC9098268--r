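---
title: "Methods: texture radiomics and classifier evaluation for echocardiographic ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture radiomics and classifier evaluation for echocardiographic ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`echotexture` implements a computer-aided detection chain for two-class
studies of myocardial texture in B-mode echocardiography: a 250-feature
texture battery per region of interest (ROI), univariate statistical gating,
Relief-F ranking, and a fixed-protocol evaluation of four classifiers. This
vignette records the model, every numerical convention the implementation
commits to, the design choices that were genuinely open, and what the
synthetic validation shows — and does not show — about clinical data.

## The analysis model

Each subject contributes two grayscale ROIs, one near end-diastole (the
"R" phase, from the ECG R wave) and one near end-systole ("T" phase). Each
ROI is reduced to a vector of 250 texture descriptors; each phase is
analysed as an independent samples-by-features table with a binary label
(patient = positive class). The scientific claim being tested downstream is
discriminability: whether texture distinguishes paced from healthy
myocardium, quantified by held-out sensitivity, specificity, accuracy and
AUC under a fixed classification protocol.

## Feature battery: conventions

The registry (`feature_registry()`) fixes 250 names in nine groups
(9 + 5 + 5 + 28 + 24 + 24 + 28 + 11 + 116). Conventions, in registry order:

* **Histogram (9).** Population (biased) moments; kurtosis is excess
  kurtosis (Gaussian → 0); percentiles use the nearest-rank method
  (`Perc50` of 1…100 is 50, not 50.5). Zero-variance images take skewness
  and kurtosis 0 by convention. The gradient group has its own `Variance`;
  to keep registry names unique the gradient moments carry a `Gr` prefix
  (`GrVariance` is "Variance of the gradient image").
* **Autoregressive model (5).** The causal four-neighbour AR(1) field
  f(x,y) = θ₁f(x−1,y) + θ₂f(x−1,y−1) + θ₃f(x,y−1) + θ₄f(x+1,y−1) + e, fitted
  by ordinary least squares on the mean-subtracted image over all interior
  pixels; `Sigma` is the RMS residual. Rank-deficient normal equations
  (constant image) yield all zeros.
* **Gradient (5).** Central differences without the 1/2 factor,
  magnitude √(Δx² + Δy²) on interior pixels; `GrNonZeros` is the percentage
  of interior pixels with non-zero magnitude.
* **Oriented-gradient histograms (28).** One cell covering the whole ROI
  (no block grid), signed orientation atan2(g_y, g_x) in [0°, 360°),
  magnitude-weighted votes, zero-magnitude pixels abstain, L1
  normalisation; an all-zero histogram (constant image) stays zero rather
  than being renormalised.
* **Gabor (24).** Complex kernels with isotropic Gaussian envelope
  σ = s ∈ {2, 4, 6, 8, 10, 12} px and carrier wavelength λ = 2s — one cycle
  per two envelope widths, the scale-invariant choice that makes "envelope
  size" the single scale parameter. Orientations 0° (H), 45° (Z), 90° (V),
  135° (N) follow the texture-analysis compass. The image mean is subtracted
  before filtering (suppressing the DC response), kernels are truncated at
  2σ so the largest filter remains usable on 64-px ROIs, and the feature is
  the mean response magnitude over the interior (the border of half the
  largest support is excluded for every filter, keeping the 24 features
  comparable). The attested envelope sizes are 4, 6 and 8; the arithmetic
  ladder {2,…,12} is the minimal six-element set containing them and is
  configurable (`gabor_sizes`).
* **Haar wavelet energies (24).** Eight dyadic levels × {LH, HL, HH};
  the feature is the mean squared detail coefficient. Eight levels ×
  three channels is the only reading consistent with the 24 names
  `HaarS1LH` … `HaarS8HH`. Levels that do not exist for a small image
  (a level needs a ≥ 2×2 approximation) are emitted as 0 and flagged via the
  `degenerate_levels` attribute, so the vector length is invariant.
* **Run-length matrix (28).** Runs of equal quantized gray level along
  H/Z/V/N; seven statistics per direction from the run-length matrix p(i,j)
  with C total runs and P pixels: ShrtREmph = Σp/j²/C, LngREmph = Σpj²/C,
  GLevNonUn = Σg²/C, RLNonUni = Σr²/C, Fraction = C/P, and the two
  C²-normalised non-uniformities.
* **Co-occurrence matrix (11).** One symmetric matrix at offset distance 1
  pooled over all four directions — the feature list has 11 entries, not
  4 × 11, so pooling rather than per-direction emission is implied — with
  Haralick statistics in log base 2 and 0·log 0 = 0. Degenerate correlation
  (zero marginal SD) is 0. Sum variance is centred on the sum average.
* **Local binary patterns (116).** Three codings: classic 4-neighbour LBP
  (`Oc4`), transition coding (`Tr4`, a bit per sign change between
  circularly consecutive neighbours), and center-symmetric LBP on circles of
  radius 1, 1, 2 with 4, 8, 12 neighbours (`Cs4`, `Cs8`, `Cs12`); off-grid
  circle samples are bilinearly interpolated. Ties (neighbour equal to
  reference) set the bit — "≥" semantics — because the coding must be
  deterministic on flat regions; this is documented rather than assumed.
  Histograms are L1-normalised.

Both matrix-based groups (GLRLM, GLCM) consume a quantized copy of the ROI:
64 gray levels over the mean ± 3 SD window (≈ 0.27 % of Gaussian pixels
clip), the convention of the texture-analysis lineage this battery follows;
all other groups use raw intensities. `quantize()` also offers the
full-nominal-range window, and falls back to it for constant images.

## Screening and Relief-F

* Normality: Lilliefors-corrected one-sample KS test per feature
  (`nortest::lillie.test`); zero-variance samples return p = 0 (degenerate).
  The normality p-values are reported but do not gate anything — the
  between-group test is the t-test regardless.
* Gate: classical equal-variance two-sample t-test, two-sided, significant
  at raw P < 0.05. No multiple-testing correction is applied — the protocol
  reports raw significance, and the downstream Relief-F ranking, not the
  gate, carries the selection burden. Degenerate conventions: zero pooled
  variance gives p = 1 (equal means) or p = 0 (perfect separation).
* Relief-F: two-class form, all m instances, k = 5 nearest hits/misses by
  Manhattan distance on range-normalised features, neighbour ties broken by
  lowest sample index (fully deterministic). Weights live in [−1, 1];
  constant features score exactly 0; scores are invariant to affine
  rescaling of any column. k = 5 and "use every instance" are the common
  defaults for cohorts of this size (≈ 100) and both are exposed
  (`k_neighbors`, `sample_count`).
* Ranking: the t-test gate is applied first and Relief-F ranks only
  significant features (gate-then-rank); ties break by registry order. If a
  cohort has fewer than ten significant features the list is returned short
  and flagged; if it has none (a realistic outcome under a global null) the
  protocol falls back to the ungated top-ten and flags the list — an
  evaluation must still be possible on null data, where this fallback is
  exactly as uninformative as intended.

## Evaluation protocol

* **Split.** Subject-level, drawing fixed per-class training counts
  (default 50 patients + 38 controls, leaving 14 + 8 for testing on the
  64/46 default cohort — the printed allocation, not naive 80 % rounding,
  which would give 51.2 patients). Both phases of a subject stay on one
  side; disjointness is asserted on every run.
* **Selection placement.** Screening and Relief-F see only the training
  partition. Running selection on the full table before the split — the
  workflow a point-and-click statistics package encourages — leaks the test
  subjects into the ranking: measured on null cohorts (no class effect) it
  inflates the mean best held-out accuracy from ≈ 60 % to ≈ 77 %. The
  leakage-free placement is the one under which the package's null
  calibration is meaningful, and is the deliberate departure this package
  makes from the legacy workflow.
* **Training metric.** Leave-one-out cross-validation; the n held-out
  predictions are pooled into one confusion matrix and scored once (a
  single training row per model implies pooled scoring). SVM z-scoring is
  refit inside every fold.
* **Classifiers.** Delegated to standard solvers with fixed
  hyperparameters: `rpart` decision tree (binary splits, minsplit 5, depth
  20, no cost-complexity pruning), `e1071` RBF SVM (C = 1, tolerance 0.10),
  `ranger` random forest (phase-specific: 29 trees/mtry 5/depth 8 for T;
  28/3/5 for R), and AdaBoost implemented here as discrete SAMME with
  depth-1 `rpart` stumps, 50 estimators, learning rate 0.1 (no installed R
  package provides AdaBoost classification; stumps are the conventional
  "tree" base learner). A "square regression loss" setting attested for the
  AdaBoost reference configuration is a toolbox quirk with no meaning for
  classification and is ignored. The protocol, not the solvers, is the
  package's contribution.
* **Sweep and report.** k = 1…10 top-ranked features, each classifier
  evaluated at every k (LOOCV-on-train and fit-train/score-test); the
  reported row per classifier is its best k by held-out accuracy (smallest
  k on ties). Choosing k on the test partition mirrors the source protocol
  ("increase until best performance") and is optimistic for the same reason
  it is there; the full sweep curve is always emitted so readers can see
  the k-dependence.
* **Metrics.** Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy,
  as percentages to two decimals; AUC by the Mann–Whitney statistic (ties
  count 1/2), which equals trapezoidal ROC integration. Single-class truth
  yields NA (flagged missing), never 0.

## The speckle simulator

No clinical images accompany the protocol this package operationalises, so
`generate_cohort()` provides a controlled stand-in: fully developed speckle,
the standard ultrasound texture model. Each image is

1. a smooth positive echogenicity map exp(0.5 · B/σ_B), B a Gaussian field
   smoothed at `bg_smoothness` (default 32 px) — slowly varying tissue
   brightness;
2. multiplied by the envelope |Z| of a correlated circular complex Gaussian
   field smoothed at `speckle_grain` (default 2 px), giving marginally
   Rayleigh amplitude (KS distance to a fitted Rayleigh < 0.05 on 10⁴
   pixels, verified in the tests);
3. for patients, plus an oriented sinusoidal band at `effect_orientation`
   (default 90°) with wavelength 2 · `effect_scale` (default 16 px) and
   random phase, amplitude 0.3 · `effect_size` · mean level;
4. optionally log-compressed (40 dB display range; off by default so the
   output retains Rayleigh statistics), min–max rescaled to [0, 255] and
   rounded.

The band amplitude constant 0.3 is a design calibration, not a free dial: a
matched orientation-selective filter integrates the band coherently over its
envelope while speckle averages away, so a band well below the speckle
amplitude still shifts the matched Gabor feature by several pooled SDs
(≈ 6 at `effect_size` 1 on 128-px ROIs) — whereas a band comparable to the
mean level (amplitude factor 1) dominates the raster, leaks into intensity
percentiles and saturated LBP codes through the per-image rescale, and the
Gabor features stop being the defining signature. At 0.3 the effect is
concentrated where the generator's contract puts it: oriented band energy.

Phases are independent realisations sharing the subject's class effect;
per-image seeds are derived from the cohort seed, subject index and phase,
so generation is bit-reproducible and order-independent. Defaults mirror the
motivating study: 64 cases, 46 controls, two frames each.

**What the simulator does not emulate**: anatomy (chambers, pacemaker
leads), attenuation, shadowing, scan-line geometry, depth-dependent
resolution, cine temporal correlation, or any physiologic difference between
the two cardiac phases. Passing the end-to-end tests therefore shows that
the pipeline recovers a planted oriented-texture difference at realistic
cohort sizes and stays at chance when none exists — it does not validate the
clinical claim that paced myocardium exhibits such a difference, which only
real images can test.

## Calibration checks and problem sizes

The test suite runs two protocol-level simulations, sized for a desk-scale
machine:

* a strong-effect run (`effect_size` 1, 90°, scale 8, 64/46 cohort,
  128-px ROIs): the matched feature `Gab8V` must appear in both phases'
  top-ten lists and at least one classifier must reach 90 % held-out
  accuracy;
* a null calibration (`effect_size` 0, 64-px ROIs, 20 seeds): for every
  classifier and phase, the mean best-k held-out accuracy must stay inside
  the 95 % binomial band around 50 % for a 22-subject test set
  (50 ± 20.9 points). The per-model mean is the calibrated statistic; the
  per-seed maximum over all classifiers and k is a maximum over ~80
  correlated binomial draws and exceeds a single-draw band by construction
  (it averages ≈ 65–70 % here even without leakage), which is why the
  best-k choice on test data should always be read together with the null
  curve.

Unit-level oracles pin the matrix and pattern groups to brute-force
enumerators (100 random small images each, 10⁻¹⁰ relative tolerance), the
Haar energies to hand-derived checkerboard closed forms, the AR estimator to
parameter recovery on a simulated field (±0.05), and the AUC to pair
enumeration and an independent ROC package.

## Known limitations

* Pure-R feature extraction: ≈ 0.1 s (64-px) to 0.7 s (256-px) per ROI —
  fine for cohorts of hundreds, slow for thousands.
* The t-test gate is applied to all features without multiplicity control;
  under a global null ≈ 5 % of features pass by construction. The null
  calibration shows what this implies for downstream accuracy.
* Best-k selection on the held-out partition is optimistic; with 22 test
  subjects one flipped prediction moves accuracy by 4.5 points. Sweep curves
  and the null band are the context for any single reported number.
* The Gabor envelope ladder and carrier wavelength, the Haar channel
  naming, and the LBP tie rule are fixed conventions documented above;
  alternative conventions would yield different absolute feature values
  (rankings are much less sensitive).
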