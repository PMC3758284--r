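---
title: "Modulatory interactions in resting-state connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulatory interactions in resting-state connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(restppi)
```

## The model

Ordinary resting-state functional connectivity regresses a voxel's BOLD
series $y$ on a seed region's series $x_1$ and reads the slope as the
coupling strength. `restppi` implements the three-region extension: with two
seed regions $x_1$, $x_2$, the voxel-wise model

$$ y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3\, (x_1 \cdot x_2) + \varepsilon $$

contains a *physiophysiological interaction* (PPI) term $x_1 \cdot x_2$.
Rewriting $y = \beta_0 + \beta_1 x_1 + (\beta_2 + \beta_3 x_1)\, x_2 +
\varepsilon$ shows what $\beta_3$ measures: the connectivity between the
voxel and region 2 as a *linear function of region 1's activity*. A nonzero
$\beta_3$ means the third region modulates (or is modulated by) the
coupling of the seed pair.

The multiplicative coupling is a statement about *neuronal* activity, but
BOLD is neuronal activity filtered through the hemodynamic response
function (HRF). Because convolution and multiplication do not commute, the
product of two BOLD series is not the hemodynamic image of the product of
the underlying neuronal series. The pipeline therefore:

1. deconvolves each seed's BOLD eigenvariate with the canonical HRF to an
   approximate neuronal series,
2. detrends both and multiplies them sample-by-sample on a fine
   ("microtime") grid,
3. reconvolves the product with the HRF and resamples it to the scan grid,

yielding the interaction regressor at the hemodynamic level. A raw-product
variant (`build_ppi_raw()`, no deconvolution) is provided for comparison;
on data generated under neuronal-level coupling it is the misspecified
regressor, and `ppi_term_correlation()` quantifies how far the two
disagree.

## HRF and deconvolution

The canonical HRF is the standard difference of two gamma densities (peak
delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6,
32 s support), sampled at 16 microtime bins per TR and peak-normalised to 1
— the absolute scale cancels in every t statistic. The within-TR reference
is the first microtime bin. These are conventions, not estimates; all are
exposed as arguments.

```{r hrf}
k <- canonical_hrf(tr_seconds = 2)
autoplot(k)
```

Deconvolution is an ill-posed inverse problem, solved here in empirical-
Bayes form: the unknown neuronal series is expanded in a discrete-cosine
basis (one function per scan by default, so the neuronal estimate cannot
invent frequencies the data cannot support), and the coefficients solve a
ridge-regularised least-squares inversion of convolution-then-downsampling.
The ridge weight is the noise-to-prior precision ratio; by default it is
chosen by maximising the two-hyperparameter Gaussian evidence with a
fixed-point iteration (at most 32 iterations, relative tolerance 1e-6). A
fixed weight can be supplied instead and is what the deterministic unit
tests use. The exact hyperpriors used by other implementations of this
step are not published, so this evidence-maximisation rule is our
interpretation of "a simple empirical Bayes procedure", not a bit-exact
replica; round-trip tests (convolve after deconvolve, r ≥ 0.95 on
band-limited signals) pin down the behaviour that matters for the PPI
term.

Edge handling: convolution assumes zero signal before scan start, and
round-trip comparisons exclude the first and last kernel-support window,
where the causal boundary makes any deconvolution unreliable.

## Subject-level analysis

Each subject's analysis follows the standard resting-state nuisance model:

* the first 2 volumes are discarded (steady-state magnetisation);
* WM and CSF masks are tissue probability > 0.99 — strictly greater, so a
  voxel exactly at the threshold is excluded, keeping gray matter out;
* each seed is summarised by the *first eigenvariate* (first left singular
  vector of the time-by-voxel matrix) within an 8 mm sphere, after
  residualising every voxel against WM, CSF, six rigid-body motion
  parameters and the drift basis. Output is unit variance (scale cancels
  in t statistics), sign-aligned to correlate positively with the regional
  mean, ties broken toward a positive first element — making the
  eigenvariate fully deterministic;
* the implicit 1/100 Hz high-pass enters as discrete-cosine drift columns
  in the design, K = floor(2·n·TR/cutoff + 1) functions including the
  constant (9 drift columns for 228 scans at TR 2 s). Putting the drift in
  the design is equivalent under OLS projection to filtering data and
  regressors, which is why the filter is "implicit".

The design has 21 columns in a fixed order — two seed main effects, the
PPI regressor, WM, CSF, six motion parameters, nine drift columns, and an
intercept — and is refused if rank-deficient (singular values below
1e-10 of the largest count as zero), naming the collinear columns. The
seed main effects enter as the original BOLD eigenvariates rather than
re-convolved neuronal estimates; the alternative is a switch away, but the
BOLD series is the conventional choice and the contrast of interest is the
interaction column only. "Detrended" is interpreted as removal of mean
*and* linear trend (`detrend = "mean"` is available). Fitting is plain OLS
per voxel — no autoregressive prewhitening, the conventional choice when
inference happens at the group level — and the interaction contrast is the
simple +1/−1 on the PPI column. Voxels whose residual variance is zero at
machine precision (an exact linear fit, as happens in noiseless synthetic
data) get a masked, not-a-number t.

## Group-level inference

Subjects' interaction contrast maps enter a one-sample t-test
(t = mean / (sd/√n), dof = n−1). Cluster inference then follows the
topological-FDR recipe:

1. height-threshold the t map at one-sided p < 0.001 (both contrast signs,
   separately);
2. label suprathreshold voxels into connected components —
   18-connectivity (faces + edges) by default, matching common practice; 6
   and 26 are available;
3. assign each cluster an uncorrected cluster-level p from Gaussian
   random-field theory: with the t-field height converted to an equivalent
   Gaussian threshold $u$ by probability matching, the expected cluster
   count is $E[m] = R\,(4\log 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}$ (R =
   resels) and cluster extent has the exponential tail
   $P(N \ge k) = \exp(-\beta k^{2/3})$. The uncorrected p is that tail
   probability; the family-wise set-level combination
   $1 - e^{-E[m]P(N\ge k)}$ is reported alongside. Smoothness (FWHM per
   axis, hence resels) is estimated from the variance of spatial first
   differences of the standardised between-subject residual maps;
4. apply Benjamini–Hochberg across the clusters of each sign and keep
   those with adjusted p ≤ 0.05.

These RFT expressions are the standard Gaussian-field approximations, and
our Monte-Carlo tests (smooth null fields, FWHM 3 voxels) confirm the
uncorrected cluster p is calibrated to well within a factor of two. They
are an approximation of, not a bit-exact substitute for, any particular
software's implementation. A sign-flipping permutation alternative
(`permutation_cluster_p()`, valid because a no-effect contrast map is
symmetric about zero) uses the max-cluster-extent null and is the
recommended cross-check when the Gaussian-field assumptions — unit
smoothness, high thresholds — are in doubt.

RFT needs appreciable spatial smoothness: on spatially white maps the
estimated FWHM is at the sampling limit (~1.2 voxels) and single-voxel
clusters receive overly small p-values. Real preprocessed fMRI is smoothed
(8 mm kernels), so the synthetic generator gives its noise a matching
spatial correlation (below).

## The synthetic cohort

`simulation_config()` defaults encode the acquisition and effect-size
conditions the pipeline is designed for: 230 acquired volumes at TR 2 s (2 discarded → 228 analysed), a
24×24×24 grid of 3 mm voxels, 8 mm spheres for the two seeds and the
target, neuronal coupling weights β₁ = β₂ = 1, β₃ = 0.5 with 0.1
between-subject SD, band-limited (0.1 Hz) unit-variance Gaussian neuronal
processes, AR(1) noise (φ = 0.3) with marginal SD 1 — giving target
temporal SNR sd(signal)/sd(noise) = 1 — plus a 128 s cosine drift
(slow enough that the 1/100 Hz high-pass must handle it), WM/CSF slabs
carrying shared nuisance signals with probability maps above 0.99, and
smooth low-amplitude random-walk motion traces.

The interaction is planted at the neuronal level and then convolved —
exactly the generative assumption the deconvolution step presumes, which
is what makes the deconvolved regressor the correctly specified one and
the raw-product regressor predictably noisier. The target signal is scaled
by $\sqrt{\beta_1^2+\beta_2^2+\beta_3^2}$ (all components unit variance)
rather than by its empirical SD, so flipping the sign of β₃ flips the
planted interaction component *exactly* — the antisymmetry the tests
assert. Measurement noise receives a Gaussian spatial correlation of FWHM
2 voxels, emulating the smoothness preprocessing induces in real data;
signals stay confined to their spheres so the ground truth is exact.

What the generator does *not* emulate — anatomy, physiological
(cardiac/respiratory) noise, distance-dependent noise correlations,
motion-correlated artifacts, multi-network structure — bounds what passing
tests show: they validate the estimator and its inferential calibration
under the assumed statistical structure, not robustness to every artifact
of real scanner data.

## Problem sizes and numerical choices

Tests and the acceptance script run at the pipeline's native subject scale
(228 scans, 24³ voxels, 20 subjects) for end-to-end checks, with 10 master
seeds for the detection-rate check; purely numerical properties
(OLS-vs-normal-equations, labeling oracles, BH) use small random instances
where exhaustive verification is cheap. Monte-Carlo calibrations use
120–200 replicates, enough to detect miscalibration at the factor-of-two
level being asserted. Other fixed choices: cluster peak ties are broken
toward the smallest linear voxel index (deterministic tables); negative-
contrast clusters are tabulated with negative peak t; permutation p uses
the (1 + exceedances)/(1 + permutations) estimator, so its resolution is
limited by the permutation count; per-subject seeds are drawn from the
master seed with `sample.int`, keeping every derived seed a valid 32-bit
integer.

## Limitations

The interaction *coefficient* is systematically attenuated: high-pass
filtering, confound residualisation and deconvolution each act linearly on
the seed series, but none of them commutes with the seed *product*, so when
the neuronal signals carry power near or below the filter band the
reconstructed interaction regressor is an imperfect image of the true one
and the fitted coefficient shrinks toward zero (we measure ~20–35%
attenuation on noiseless synthetic subjects whose neuronal band extends to
DC). Detection and sign are unaffected — the t statistic is computed
against the same regressor — but the raw magnitude of the PPI coefficient
should not be read as the neuronal coupling weight. The deconvolution rule
is one reasonable empirical-Bayes scheme among several; conclusions that
hinge on the *scale* of the neuronal estimate should not be drawn from it
(the pipeline never uses that scale). RFT
cluster p-values are approximations that degrade at low smoothness or
lenient height thresholds — the permutation path exists for exactly that
reason. The subject GLM is OLS; with strongly autocorrelated residuals its
dof are optimistic, which the group-level one-sample t largely absorbs but
single-subject inference should not rely on. Only two-seed interactions
are modelled; task-modulated (psychophysiological) and multi-seed variants
are out of scope.
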