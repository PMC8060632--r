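---
title: "From canopy images to nitrogen status: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From canopy images to nitrogen status: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnni)
```

## The problem

During the early growth of winter wheat (tillering to first node, Feekes 3
to Feekes 6), canopy cover (CC) — the fraction of ground covered by the
vertical projection of the canopy — can be measured cheaply from a nadir
RGB photograph. This package implements the full chain from such images to
a diagnosis of crop nitrogen status:

1. **Segmentation.** Each pixel's green minus red intensity (G−R) is
   computed; pixels with G−R above a threshold are canopy, the rest
   background, and CC is the canopy-pixel fraction.
2. **Allometry.** Growth indices — shoot dry matter (SDM, t/ha), leaf area
   index (LAI), shoot N accumulation (SNA, kg N/ha), shoot N concentration
   (SNC, % of dry matter) — are related to CC by power laws
   \(Y = a\,\mathrm{CC}^{b}\).
3. **Poolability.** A coincidence-of-regressions F test asks whether
   per-cultivar or per-N-rate lines (in log–log space) can be merged into
   one.
4. **Nitrogen status.** The Nitrogen Nutrition Index is
   \(\mathrm{NNI} = \mathrm{SNC}/N_c\) with the critical dilution curve
   \(N_c = A\,\mathrm{SDM}^{B}\) (defaults \(A = 4.15\), \(B = -0.38\) for
   winter wheat). NNI is estimated from CC either directly
   (\(\mathrm{NNI} = a\,\mathrm{CC}^b\) fitted on NNI observations) or
   indirectly, by composing the stage's SNC and SDM power laws with the
   critical curve in closed form.

## Segmentation model and its choices

The G−R index is a signed integer in \([-255, 255]\); no clamping is
applied. The default threshold is **0**: a pixel is canopy when green
strictly exceeds red. Zero is the natural sign boundary of the index, and
the strict inequality puts boundary pixels in the background. An `auto`
mode selects the threshold by Otsu's criterion on the 511-bin G−R
histogram (maximizing between-class variance, ties broken toward the lower
threshold, deterministic); it exists because lighting or soil colour can
shift the optimal cut away from 0 in real photographs. A constant map has
no bimodality to exploit and raises an error rather than returning an
arbitrary cut.

Alpha channels are dropped (fixtures and camera JPEGs are opaque); no
colour-profile or white-balance handling is attempted — those belong to
acquisition, not analysis. CC is a pure pixel ratio, so no resolution
configuration is needed; a block-averaged copy of a scene changes CC by
well under 0.02 as long as canopy boundaries are a small fraction of the
image, which holds for realistic leaf-blob sizes.

## The allometric estimator

`fit_allometric()` fits \(Y = a X^b\). The default space is
**log-linear**: OLS of \(\ln Y\) on \(\ln X\), because the downstream
model-comparison machinery operates on linearized models. Then
\(a = e^{\hat\alpha}\), \(b = \hat\beta\), and 95% intervals come from t
quantiles on the log scale; the interval for \(a\) is back-transformed and
therefore asymmetric. \(R^2\) is reported in the fitting space and the
space is recorded in the object, so parameter tables are unambiguous. A
**nonlinear** space (Levenberg–Marquardt on the original scale,
initialized from the log-linear estimates) is provided for reporting
parity; as noise vanishes the two converge. No weighting is applied — no
heteroscedasticity treatment is part of the model.

Degenerate inputs fail loudly: non-positive values are a domain error
naming the offending rows; constant \(x\) is a rank error; fewer than 3
points is a sample-size error.

## The coincidence F test

`compare_regressions()` implements the four-step comparison of linear
regressions: residual sum of squares of the single pooled line
(\(n - 2\) df), summed residuals of the per-group lines (\(n - 2k\) df),
their difference (\(2(k-1)\) df), and the variance ratio

\[ F = \frac{(RSS_{pooled} - RSS_{within})/2(k-1)}{RSS_{within}/(n-2k)}, \]

compared with the upper-\(\alpha\) F quantile (default \(\alpha = 0.05\),
one test at a time, no multiplicity correction). This is algebraically the
extra-sum-of-squares test of the 2-parameter common-line model against the
2k-parameter separate-lines model, and the test suite verifies the
equality against `anova()` on random instances to \(10^{-9}\). When the
groups lie exactly on distinct lines, \(RSS_{within} = 0\) and the
statistic is reported as `Inf` with `poolable = FALSE` rather than
raising. Degrees of freedom follow the standard bookkeeping
\(df_1 = 2(k-1)\), \(df_2 = n - 2k\), which the package documents as its
own convention for all reported tables.

## NNI and the indirect composition

With \(SNC = a_s \mathrm{CC}^{b_s}\) and \(SDM = a_d \mathrm{CC}^{b_d}\),
substituting into \(\mathrm{NNI} = SNC/(A\,SDM^{B})\) gives the closed
form

\[ \mathrm{NNI} = a'\,\mathrm{CC}^{b'}, \qquad
   a' = \frac{a_s\,a_d^{-B}}{A}, \qquad b' = b_s - B\,b_d , \]

which at the default curve reduces to \(a' = a_s a_d^{0.38}/4.15\),
\(b' = b_s + 0.38\,b_d\). `compose_indirect()` generalizes the formula to
any \((A, B)\) and performs no fitting; the pointwise identity between the
composed model and \(\mathrm{NNI}(SNC(\mathrm{CC}), SDM(\mathrm{CC}))\)
holds to \(10^{-12}\) relative error and is asserted in the tests. The
critical curve carries no plateau segment. N-status classification uses a
configurable tolerance band (default ±0.05) around the strict optimum
NNI = 1, acknowledging measurement noise; the boundary itself is 1.

```{r compose}
compose_indirect(a_s = 3.81, b_s = 0.5, a_d = 6.2, b_d = 1.74,
                 stage = "Feekes 5")
```

## What the synthetic data emulate — and what they do not

`simulate_trial()` generates a 2-site × 2-season × 4-cultivar × 5-N-rate ×
3-replicate × 3-stage factorial (720 records). Canopy cover is
interpolated across stages between per-N-rate endpoints (0.18→0.61 at
0 kg N/ha up to 0.30→0.88 at 300 kg N/ha, linearly interpolated between
rates) with Gaussian jitter of SD 0.05, the between-plot spread typical of
such trials. Growth indices follow per-cultivar power laws of CC whose
default parameters span realistic ranges (e.g. SDM coefficients 4.87–6.72,
exponents 1.54–1.92), with **median-1 multiplicative lognormal noise**
(default CV 0.1) applied independently per index. Median-1 (rather than
mean-1) noise makes the log-space errors mean-zero Gaussian — exactly the
error model the log-linear fit assumes — so confidence intervals attain
their nominal coverage by construction. SNC is *derived* as
\(SNA/(10\,SDM)\), so the unit identity \(SNA = 10 \cdot SDM \cdot SNC\)
holds exactly in every record. Within-treatment coefficients of variation
are free parameters with documented defaults; no field study reports them
directly.

`simulate_canopy_image()` builds a mask of random elliptical leaf blobs
whose cover hits the target **exactly** (the blob crossing the target is
grown from its centre until the pixel count matches, keeping the mask
contiguous), then paints leaf (default RGB 60/130/45, G−R = +70) and soil
(default RGB 115/85/65, G−R = −30; a reddish-brown dry loam) with optional
per-channel Gaussian noise (default SD 8). With these defaults the two
colour classes stay separated at G−R = 0 with large margin, so threshold-0
segmentation recovers the ground-truth cover within 0.01 even under noise.

Passing tests on these data therefore show that the estimators are
*correct under their own assumptions*; they do not show robustness to what
the generator omits: shadows and specular highlights, mixed soil/residue
backgrounds, senescent leaves, within-canopy colour gradients, or
stage-dependent SNC dispersion. In particular, because the generator's
SNC is a stage-free function of CC (plus noise), NNI follows a single
global power law of CC across stages — so the well-known empirical failure
of a *pooled* CC–NNI regression across growth stages (driven by N dilution
at equal CC) is **not** reproduced by the synthetic trial. The pipeline
still reports the pooled fit alongside the per-stage fits so that real
data can exhibit it.

## Numerical and design notes

- Problem sizes in the test suite: 50 scenes of 120×80 px for the
  segmentation study, 200 replicates of 180 records for the CI coverage
  study, 1000 null simulations (4 groups × 15 points) for the size of the
  F test, 2000 statistics for its null-distribution check. These sizes
  give Monte-Carlo standard errors comfortably below the asserted bands.
- All generator randomness flows from explicit integer seeds through an
  isolated RNG stream, so generating data never perturbs the caller's
  `.Random.seed`, and pipeline outputs are byte-identical across reruns
  with one seed.
- F quantiles come from `stats::qf` (the inverse regularized incomplete
  beta); the t² ≡ F(1, df) identity and the F(d, d) median are used as
  independent cross-checks in the tests.
- `nlsLM` bounds the nonlinear-space coefficient at \(a > 0\); the
  exponent is unconstrained, matching the log-linear parameterization
  where \(a\) is positive by construction.
- The reported df pairs of legacy ANOVA-style tables in the field
  sometimes disagree with \(2(k-1), n-2k\); this package always reports
  its own decomposition (k, n, both RSS, both df) so every F value is
  auditable.

## Limitations

- The segmentation is a single colour-index threshold; no machine-learning
  segmentation, shadow correction, or alternative indices (ExG, NDI).
- The critical curve is user-configurable but defaults to the winter-wheat
  curve; no CC-based critical curve is constructed.
- Only the full coincidence test is implemented — no slope-only or
  intercept-only ANCOVA stages.
- CC saturates after the first-node stage; the methods here target the
  early vegetative window where CC still discriminates.
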