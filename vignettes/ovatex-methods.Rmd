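---
title: "Texture-based classification of ovarian ultrasound images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based classification of ovarian ultrasound images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovatex)
```

## The problem

Discriminating benign from malignant ovarian masses on (contrast-enhanced)
ultrasound is a texture problem: malignant tissue tends to show more
high-frequency structure — bright spots, septa, irregular borders — on top of
the multiplicative speckle that dominates all ultrasound imagery. `ovatex`
implements a complete, testable version of the classical texture pipeline for
this task:

1. **wavelet shrinkage denoising** of the grayscale image,
2. **multiscale rotation-invariant uniform local binary patterns (LBP)** and
   **Laws' texture energies** as the feature vector,
3. a **binary logistic regression** classifier with confusion-matrix
   evaluation under stratified cross-validation.

Because no clinical image set is distributed with the package, a synthetic
two-class texture generator supplies the benchmark data; it is first-class,
tested code, not a fixture.

## Wavelet preprocessing

`dwt2_level()` is a separable orthonormal 2-D DWT (Haar by default; `db2` and
`db4` are available) with **symmetric half-sample boundary extension**. A
length-$n$ signal produces $\lfloor (n+L-1)/2 \rfloor$ coefficients per band
for a length-$L$ filter — $\lceil n/2 \rceil$ for Haar — and reconstruction is
exact for every supported size and wavelet (round-trip error below $10^{-12}$
in practice; the tests require $10^{-8}$). `wavelet_decompose()` iterates the
transform on the approximation band up to three levels, giving the usual
pyramid of one approximation plus three detail bands (horizontal / vertical /
diagonal) per level.

Numerical notes, chosen once and documented:

* **Wavelet default Haar.** With Haar and *even* image sides the transform is
  exactly orthonormal, so Parseval's identity holds to $10^{-9}$ relative and
  the energy-conservation tests are sharp. For odd sides the boundary
  extension keeps one redundant coefficient per band and strict Parseval no
  longer applies; reconstruction remains exact.
* **Detail-band sign.** The high-pass filter follows the quadrature-mirror
  convention $g_k = (-1)^k h_{L-1-k}$; detail bands are defined up to a global
  sign, which no downstream quantity (energy, thresholding, reconstruction)
  depends on.
* **Denoising** (`wavelet_denoise()`) soft-thresholds all detail coefficients
  and never touches the approximation band. The default *universal* threshold
  (VisuShrink) is $t = \hat\sigma\sqrt{2\ln N}$ with
  $\hat\sigma = \mathrm{median}(|F_1|)/0.6745$ estimated from the finest
  diagonal band — the standard robust MAD estimate, which assumes the finest
  diagonal band is noise-dominated. At `manual_t = 0` denoising is the
  identity, and retained detail energy is monotone non-increasing in the
  threshold.
* The classifier consumes the **denoised image** (one level by default); the
  3-level decomposition is exposed for inspection but its bands are not
  themselves features.

## LBP features

For each pixel, `D` neighbors on a circle of radius `r` are compared against
the center; the sign pattern is the binary code. Conventions:

* Neighbor $p$ sits at angle $2\pi p/D$ counterclockwise from the +column
  axis; off-grid positions are bilinearly interpolated, and positions within
  $10^{-9}$ of a grid node are read directly.
* Ties threshold as $\ge$ (a neighbor equal to the center contributes a 1).
* `orig` mode packs bits with binomial weights $\sum_p b_p 2^p$ (the raw
  bit-sum without weights would collapse onto the rotation-invariant code and
  could not produce the $2^D$-valued labels the code image is defined over).
* `riu2` mode — the mode the classifier uses — maps uniform patterns (at most
  two circular 0/1 transitions) to their 1-bit count and all non-uniform
  patterns to the single code $D+1$. For $D = 8$ this yields exactly 58
  uniform patterns and 10 distinct codes, which the tests verify by
  exhaustive enumeration; the code is invariant under every cyclic rotation
  of the neighbor bits and under gray-level shifts.

A code image (`lbp_image()`, computed over the interior where the full circle
fits) is summarized by its normalized histogram, and each scale contributes
two descriptors: energy $\sum_i h_i^2$ and Shannon entropy
$-\sum_i h_i \log_2 h_i$ (base 2; $0\log 0 := 0$). The default scales
$(D, r) \in \{(8,1), (16,2), (24,3)\}$ give six LBP features; the set is
configurable, and the vectorized implementation is tested against a naive
per-pixel oracle for every supported scale.

## Laws' texture energies

The nine $3\times3$ masks are outer products of the level $L3 = (1,2,1)$,
edge/border $B3 = (-1,0,1)$ and spot/dot $D3 = (-1,2,-1)$ vectors; all but
$L3L3$ have zero sum. Per zero-sum mask the image is cross-correlated
(symmetric padding, same-shape output), **balanced** by elementwise division
with the $L3L3$ response (local luminance) to remove contrast dependence, and
aggregated by a $7\times7$ moving-window sum of **absolute** values — the
texture-energy map — whose mean is the feature. Eight features result.

Choices worth stating:

* The window aggregates absolute values: balanced responses of zero-mean
  masks are signed and would cancel to nearly zero under a plain sum,
  carrying no energy information. The absolute-value sum is the standard
  nonlinear Laws energy statistic.
* Masks are applied as written (cross-correlation). Flipped convolution would
  only change signs of the antisymmetric masks, which the absolute-value
  window removes.
* The balancing divisor is floored at `epsilon = 1e-8` in magnitude (sign
  preserved) so zeros in the $L3L3$ map stay finite. Away from that floor the
  eight features are exactly invariant to positive rescaling of the image,
  tested at factors 0.5, 2 and 10.
* Symmetric mask pairs such as $L3B3$/$B3L3$ are kept separate (eight
  descriptors, not five pooled ones); they respond to orthogonal orientations,
  which the stripe-image test demonstrates.

## The logistic classifier

The model is standard binary logistic regression: with features $M_1..M_k$,

$$\log\frac{\pi}{1-\pi} = \alpha + \sum_{j=1}^k \beta_j z_j, \qquad
\pi = \frac{1}{1 + e^{-a}},$$

where $z_j$ are the z-scored features. Since the model family itself fixes
no estimation procedure, fitting maximizes the Bernoulli log-likelihood by
**Newton–Raphson with step-halving** (the penalized log-likelihood is
guaranteed non-decreasing across iterations), converging when the largest
parameter change drops below $10^{-8}$. Details:

* **Standardization** uses training-fold means/SDs only, making coefficients
  scale-free and the parameter-recovery tests well-posed; the parameters are
  stored in the model so prediction is self-contained.
* A small **ridge penalty** $\lambda\|\beta\|^2/2$ (default $\lambda =
  10^{-6}$, intercept unpenalized) keeps the Hessian well-conditioned when
  the synthetic classes are linearly separable; with $\lambda = 0$ and
  separable data the fit is flagged non-converged with a warning suggesting a
  positive penalty.
* The two algebraic forms of the inverse logit agree to $10^{-12}$ over
  $a \in [-30, 30]$, the implementation is stable for $|a|$ up to several
  hundred, and $P(1) + P(0) = 1$ to machine precision.
* Classification uses $\pi \ge$ threshold (default 0.5): the tie goes to the
  malignant class, the safer clinical direction.
* Metrics with zero denominators (e.g. precision when nothing is predicted
  positive) are reported as 0 with an `undefined` flag and a warning rather
  than an error, so pooled cross-validation never aborts.
* Evaluation is **stratified k-fold cross-validation** (default 5 folds,
  fold sizes within a class differing by at most 1, deterministic under the
  seed), with confusion counts pooled over held-out folds.

## The synthetic generator

`generate_texture_image()` targets the statistical contrasts the features
measure rather than the physics of contrast-enhanced acquisition:

* **Benign-like (class 0):** a uniform random field blurred with a Gaussian
  of scale `benign_smoothness` (default 2.5 px), rescaled to $[0.25, 0.75]$,
  then multiplied by $(1 + s\,N(0,1))$ speckle with $s = 0.3$ — the standard
  multiplicative model for ultrasound speckle.
* **Malignant-like (class 1):** the same field plus sparse bright spots
  (3×3 dot profiles seeded at a fraction 0.02 of pixels) and 4 thin linear
  segments, raising high-frequency spot/edge energy; speckle is applied after
  the additions so lesion structure is itself speckled.
* Defaults — 100 images per class at 128×128 in $[0,1]$ — are the package's
  reference study conditions. Image (class, index) is generated under the
  derived seed `seed + index`, so images are reproducible bit-for-bit and
  independent of how many are generated; with spot density 0 and edge count
  0, class 1 degenerates to class 0 exactly, which pins down the generator's
  RNG discipline in a test.
* `inject_noise()` provides Gaussian, salt-and-pepper and speckle corruption
  for denoising studies; all outputs are clipped to $[0,1]$ (clipping can be
  disabled to study the raw noise).

What the generator does *not* emulate: contrast-bubble perfusion dynamics,
attenuation and shadowing, depth-dependent resolution, scanner post-
processing, or anatomical structure. Passing the benchmark therefore shows
that the pipeline separates speckle-plus-lesion texture statistics as
designed — not that it reaches any particular accuracy on clinical images.

## Benchmark and problem sizes

The reference benchmark (`run_pipeline()` with all defaults) generates the
200-image dataset, denoises, extracts the 14 features and pools 5-fold CV
confusion counts; the acceptance checks require pooled accuracy $\ge 0.90$,
and the default conditions reach 1.00 with a wide margin (lowering the
spot density and edge count moves the classes together, and the margin
shrinks accordingly). Unit tests run the
same stages at reduced sizes — 16×16 oracle comparisons, 64×64 Monte-Carlo
checks, 20–50 images — sizes chosen to make the statistical assertions sharp
while keeping the suite quick to iterate on.

## Clinical table statistics

The package ships the accompanying 137-case cohort tables verbatim as CSV
fixtures. The comparison functions are deliberately conventional: Pearson
chi-square (no continuity correction) for r×c counts, Fisher's exact test
for sparse 2×2 collapses, and Welch's t from summary statistics (mean, SD,
n) for the tumor-diameter comparison — the sources name no test, so the
field-standard defaults are used and stated. `validate_clinical_tables()`
cross-checks every internal sum and *flags* rather than repairs the known
source inconsistencies: the pregnancy-outcome miscarriage count (38)
disagrees with the abortion group size (32); the recomputed GA-of-detection
chi-square p-value (0.011) disagrees with the printed 0.026; and a printed
p-value of "0" is reported as "< 0.001", not an exact value.

## Known limitations

* The DWT supports levels 1–3 and the haar/db2/db4 family; no stationary
  (undecimated) transform, and no BayesShrink/SureShrink threshold rules.
* LBP is the plain circular operator (no CLBP/LTP variants); `orig`-mode
  histograms for $D > 16$ are memory-heavy and riu2 is the intended mode.
* Laws masks are the 3×3 family only.
* The classifier is strictly binary with a single linear predictor; no
  multinomial extension, regularization paths or calibration.
* The synthetic benchmark bounds what can be claimed about clinical
  performance (see above).
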