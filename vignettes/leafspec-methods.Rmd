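---
title: "Methods: hyperspectral classification of herbicide stress"
author: "leafspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral classification of herbicide stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspec)
```

## The problem

Quinclorac is an auxin-mimic herbicide used against barnyard grass in rice
paddies; at excess doses it is phytotoxic to the rice seedlings themselves,
and an exogenous salicylic-acid (SA) pre-treatment can partially rescue the
plants. The phenotyping question is whether a ground-based VNIR
(380–1030 nm) hyperspectral camera can tell the three conditions apart
non-destructively: untreated control (CK, label 1), quinclorac-stressed
(Q, label 2), and SA-rescued (S, label 3). Spectrally, stress raises
visible reflectance (pigment loss) and lowers near-infrared reflectance
(cell-structure damage), and the rescued group sits close to the stressed
group — so the discriminative signal is a few percent of reflectance, with
Q-vs-S the hard pair.

`leafspec` implements the full analysis pipeline for this problem:
reflectance calibration, pixel-spectra preprocessing, PCA score imaging and
feature extraction, soft-margin RBF support vector classification with grid
search, kappa/accuracy evaluation, and pixel-wise prediction maps. Because
no real image archive is distributed with the package, a synthetic scene
generator stands in for the camera; it is first-class, tested code, and the
end-to-end claims in the test suite are claims about this generator's
output, not about real rice.

## Reflectance calibration

Raw line-scan counts are converted to reflectance by the standard two-point
equation

$$I_c = \frac{I_{raw} - B}{W - B}$$

where $B$ is a dark frame (shutter closed) and $W$ a white-tile frame, each
a single scan line of `cols × bands` values broadcast down the image rows.
Elements where $|W - B| < 10^{-12}$ cannot be calibrated; they are set to 0
and counted in a calibration report rather than propagating `Inf` into the
downstream PCA. More than 1% degenerate elements raises a warning, or an
error in strict mode. ENVI-style I/O uses the smallest interoperable
dialect: an ASCII header with lowercase keys and a braced wavelength list
in nm, 32-bit float storage for reflectance and 16-bit unsigned for raw
counts, little-endian, BIL/BIP/BSQ interleaves.

## The synthetic scene generator

Each scene is a 64 × 64 × 512-band cube (380–1030 nm, uniformly spaced)
holding a few non-overlapping elongated elliptical "leaves" (major
semi-axis 10–14 px, minor 3.5–5 px) on a flat background of reflectance
0.03. The base leaf spectrum is a smooth idealised green-leaf curve: a
visible baseline of 0.08 with a green bump at 550 nm, multiplicative
pigment absorption dips at 450 and 680 nm (fractional depths 0.42 and
0.40), a logistic red edge centred at 715 nm (scale 18 nm), and a NIR
plateau of 0.50.

Treatments are additive offsets to that curve: on 434–700 nm, Q adds
+0.04 and S +0.03; on 750–953 nm, Q adds −0.05 and S −0.04 (CK adds
nothing). Offsets switch on and off through 15 nm raised-cosine ramps
placed *outside* the quoted intervals, so the full offset applies at every
band inside 434–700 and 750–953 nm and the group contrast over the quoted
window is exactly the nominal effect size. These effect sizes reproduce
the documented qualitative structure — CK below Q and S in the visible,
above them in the NIR, and |Q − S| band-wise much smaller than |CK − Q| —
and they are tunable parameters of `scene_params()`, not measured
constants.

Noise enters at three levels, all reproducible from one integer seed:

* per-pixel multiplicative slope (sd 0.05) and additive offset (sd 0.01)
  scatter, one draw per pixel applied across all bands — the usual
  first-order model of illumination/geometry scatter that makes smoothing
  and PCA meaningful;
* independent per-band Gaussian reflectance noise (sd 0.01);
* shot-like raw-domain noise (sd $0.2\sqrt{\text{counts}}$) after the
  reflectance scene is inverted through the calibration equation with
  synthetic dark (≈100 counts) and white (≈3000 counts) frames, so
  calibration sits on the main analysis path rather than only in unit
  tests.

What the generator does **not** emulate: radiative-transfer realism
(PROSPECT/SAIL-class leaf optics), within-leaf structural gradients,
specular highlights, canopy shadowing, or scene-level biological
replicate variance. The last point matters for interpreting the tests:
with pixel-level noise only, the per-scene *mean* spectra are nearly
noise-free, so the three classes separate cleanly at the sample level and
the end-to-end accuracies sit at 100% rather than the 80–100% range seen
on real plants. The pixel level keeps the realistic difficulty: roughly a
third of the pixels of a stressed scene are assigned to the neighbouring
treated class, so the prediction-map summaries retain the Q/S confusion
structure. Passing the end-to-end tests therefore demonstrates that the
pipeline machinery is correct and well-calibrated, not that real rice
would classify at 100%.

## Preprocessing

The fixed order is: calibrate → segment → extract pixel spectra → crop to
434–953 nm → wavelet denoise → 7-point moving average → per-sample mean
spectrum. Preprocessing is applied per pixel *before* averaging.

**Segmentation.** Plant pixels are `NDVI = (R800 − R680)/(R800 + R680)
> 0.4`, followed by removal of 4-connected components smaller than 20
pixels (isolated noise pixels clear the NDVI threshold surprisingly often
on a dark background; real workflows use interactive tools for this step,
so a simple reproducible index threshold is used here).

**Band window.** The crop keeps the contiguous band run that *covers*
[434, 953] nm — from the last band at or below 434 through the first band
at or above 953. On the uniform 512-band axis this retains exactly 410
bands; a plain `434 ≤ λ ≤ 953` filter would keep 408 and silently change
every downstream dimension (the ten-PC feature set is a 97.56% reduction
of 410, not of 408). When the limits coincide with band centres the two
rules agree.

**Wavelet denoising.** The denoiser is the orthogonal projection onto the
level-3 Daubechies-9 approximation space over the 410-band window: the
span of the 8-lattice translates of the cascade-refined scaling sequence,
truncated at the window edges, plus the constant vector, orthonormalised
by SVD with a 10⁻⁷ relative cutoff (a 66-dimensional space). This is
"keep the approximation, zero all details" formulated as a projection,
and the formulation is deliberate: a plain analysis–synthesis pass with
zeroed details is *not* idempotent on a finite window (repeated
application drifts at the 10⁻⁴ level near the boundaries), whereas a
projection is exactly idempotent, preserves constants to machine
precision, and treats the window edges by basis restriction instead of
extension artifacts. Empirically the two formulations share the same
smoothing bias (RMSE 9×10⁻⁴ against the noiseless truth after the full
chain) and the same noise-variance reduction (≈9×). The minimum input
length is the level-3 filter support (120 samples).

**Moving average.** Centred, window 7 bands, shrinking symmetrically at
the edges so every output value is a mean of observed bands centred on the
target band.

The test suite checks the chain end to end: on a completely noiseless
scene the recovered sample spectrum matches the generating treatment
spectrum with RMSE below 10⁻³ over the 410 retained bands. RMSE is the
right yardstick here: the smoothing bias of a 7-band moving average at the
cosine shift ramps is ≈3×10⁻³ at single bands by construction (bias ≈
f″·h²·(w²−1)/24), so a max-norm bound at 10⁻³ is not attainable by any
linear smoother with this window, while the band-averaged error is.

## PCA

PCA is mean-centred only (reflectance bands share units; no variance
scaling) and computed by SVD. Loading signs are fixed so each component's
largest-magnitude element is positive, making score images reproducible
across runs and BLAS implementations. Explained-variance fractions are
σ²-fractions of total variance. Score images place each plant pixel's
score at its image coordinate with `NA` background. For classification,
the first ten PC scores of the sample mean spectra are the feature set;
the PCA is fitted on the training split only, so no validation or test
information leaks into the feature definition.

On pooled preprocessed pixel spectra from one scene per group, the first
ten components carry ≈98.8% of total variance at the default noise level.
The budget is easy to state: the generator's structural variance
(treatment shifts plus pixel scatter) is essentially rank-four, and what
the ten components cannot absorb is the residual smoothed pixel noise —
about 1.2% of the total. Real canopy images concentrate far more
structural variance in the leading components, which is why published
values for this statistic reach 99.99%.

## Dataset splitting

Kennard–Stone selection starts from the two samples at maximal Euclidean
distance (lower indices win ties) and repeatedly adds the sample
maximising its minimum distance to the selected set — deterministic given
the data, so splits are reproducible without a seed. Two split modes are
provided: a 2:1 Kennard–Stone calibration/prediction split, and the
pipeline default, a per-class 4:1:1 train/validation/test split in which
each class's Kennard–Stone ranking is dealt round-robin through the
pattern (train ×4, validation, test). The dealing keeps every class's
validation and test counts within one of ⌊n/6⌋ for any class size.
Greedy farthest-point selection is not optimal for the minimum
pairwise-distance objective, so the suite checks its spread statistically
(above the 95th percentile of 1,000 random subsets) rather than against
every random draw.

## Support vector classification

The binary machine solves the soft-margin dual

$$\min_\alpha \tfrac12 \alpha^\top Q \alpha - e^\top \alpha,
\qquad Q_{ij} = y_i y_j K(x_i, x_j),
\qquad y^\top \alpha = 0,\; 0 \le \alpha_i \le C,$$

with the RBF kernel $K(u,v) = \exp(-\gamma\|u-v\|^2)$, by sequential
minimal optimisation with maximal-violating-pair working sets (compiled;
`src/smo.cpp`). The stopping rule is the KKT gap ≤ tol (default 10⁻³,
iteration cap 10⁴·n). The bias is the mean of $y_i - \sum_j \alpha_j y_j
K(x_j, x_i)$ over free support vectors, or the midpoint of the feasible
interval implied by the bound vectors when no multiplier is free.
Features are used unscaled: reflectance lies in [0, 1] and PC scores are
used as produced.

Multiclass problems use one-vs-one ensembles (three machines for three
classes; the first label of each pair is coded +1) with majority voting;
vote ties fall back to the largest summed |decision value| among the tied
labels, then the smallest label. Model selection scans the decade grid
$C, \gamma \in \{10^N : N = -8,\dots,8\}$ (17 × 17 = 289 cells), picks the
best validation accuracy, and breaks ties by higher training accuracy,
then smaller $C$, then smaller $\gamma$ — smaller values mean smoother,
less overfit-prone machines, so ties resolve toward the simpler model.

Correctness is established two ways: analytically (the two-point problem
has the closed-form solution $\alpha = 1/(1 - e^{-1})$, $b = 0$) and
against an independent dense-QP oracle — `kernlab::ipop` refined by an
exact KKT linear solve on the identified free set — which the SMO solution
matches to 10⁻⁶ in dual objective and 10⁻⁵ in decision values on random
fixtures up to n = 25.

## Evaluation and prediction maps

Confusion matrices are actual × predicted counts over the three labels;
accuracy is trace over total, and agreement is chance-corrected by
unweighted Cohen's kappa, $\kappa = (p_o - p_e)/(1 - p_e)$ with
$p_e = \sum_i r_i c_i / n^2$. The package ships the benchmark confusion
tables for the two rice cultivars (XS 134, ZJ 88) as a plain-text fixture
and recomputes both statistics from the raw counts; the recomputed
accuracies agree with every printed value at its printed precision, and
the recomputed kappas agree with the printed cells that are themselves
consistent with the unweighted definition (a handful of printed kappa
cells in the original tables are not reproducible from their own counts
under any standard weighting and are reported as computed).

Prediction maps push every plant pixel of a scene through the identical
preprocessing chain, project onto the ten-PC features, classify, and
report per-category pixel fractions (summing to one over plant pixels).
Scene-level summaries give mean ± sd fractions per true treatment. On the
synthetic study the majority pixel category matches the true treatment in
every scene at default noise.

## Pipeline and problem sizes

`run_pipeline()` chains all stages deterministically from one master seed
(scene seeds are derived, every random draw is local to its scene) and
writes all artifacts — manifest, sample-spectra CSV, split CSV,
grid-search CSVs, flat-text PCA/SVC model files, metrics CSVs, map
fractions — to an output directory. The standard study size used
throughout the tests and the acceptance script is 40 scenes per treatment
group (120 scenes of 64 × 64 × 512), the full 17 × 17 grid, and both
feature modes; this completes in about a minute on one CPU, with scene
generation dominating. The command-line front end
(`inst/cli/leafspec.R`) exposes the stages as subcommands over the same
functions.

## Known limitations

* The generator's low-rank noise model makes sample-level classification
  easy at default effect sizes; conclusions about real-world accuracy
  levels cannot be drawn from it, only about pipeline correctness.
* Segmentation is a fixed NDVI threshold; scenes with reflectance
  pathologies (specular background, dead leaves) would need a different
  index or threshold.
* The SVC has no probability calibration and no class weighting; kernels
  other than RBF are out of scope.
* Wavelength-interval ("optimal wavelength") selection is not
  implemented; the feature modes are the full 410-band window or ten PC
  scores.
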