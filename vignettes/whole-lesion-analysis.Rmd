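---
title: "Whole-lesion histogram and texture analysis of prostate ADC and T2W MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-lesion histogram and texture analysis of prostate ADC and T2W MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wholelesion)
```

## The problem and the pipeline

Benign prostatic hyperplasia (BPH) nodules and prostate cancer (PCa) can be
hard to tell apart on conventional multiparametric MRI. A whole-lesion
approach summarizes every voxel of a segmented lesion instead of a single
slice or a hand-picked region, and characterizes the lesion by histogram
statistics and gray-level co-occurrence (Haralick) texture of two biparametric
contrasts: the apparent diffusion coefficient (ADC) map derived from
diffusion-weighted imaging (DWI), and the T2-weighted (T2W) image.

The package implements that workflow end to end:

1. **Phantom/cohort simulation** — synthetic multi-b DWI, T2W and
   ground-truth masks with the statistical structure the analysis assumes,
   so every downstream stage is testable without patient data.
2. **ADC fitting** — the mono-exponential model
   $S(b) = S(0)\,e^{-b\cdot\mathrm{ADC}}$, fitted per voxel by ordinary
   least squares on $(b, \log S)$.
3. **Random-walker segmentation** — seeded two-label segmentation on the
   $b = 1500\ \mathrm{s/mm^2}$ DWI volume, with the mask propagated to the
   ADC map and T2W image.
4. **Feature extraction** — lesion volume, seven first-order statistics and
   four GLCM texture features per modality.
5. **Diagnostics** — group tests, ROC with DeLong confidence intervals,
   Youden-optimal cutoffs, likelihood ratios, and logistic combination of
   parameters.

## The synthetic cohort generator

The generator emulates a two-class cohort of 90 PCa and 112 BPH patients.
Its defaults are calibration constants taken from a published 3 T
biparametric cohort of exactly that size: per-feature class means and SDs
(`default_cohort_params()`), median lesion volumes of 2.50 ml (PCa) and
1.05 ml (BPH), and the six-b-value DWI protocol
$b \in \{0, 500, 800, 1000, 1500, 2000\}\ \mathrm{s/mm^2}$ on a
$1.867 \times 1.867 \times 4$ mm grid.

Each phantom is an ellipsoidal lesion (semi-axes in ratio 1.25 : 1 : 0.8,
scaled to the class's median volume — the simplest shape with a controllable
volume) in a homogeneous background (ADC $1400 \times 10^{-6}$ mm²/s, chosen
above both class means so lesions are hypointense on ADC, as in vivo).
Within-lesion heterogeneity is Gaussian-smoothed white noise (FWHM 3 mm by
default) standardized to the requested mean/SD; smoothing gives the field
spatial correlation, hence non-degenerate GLCM features. DWI signals follow
the mono-exponential model with Rician corruption
$\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$, $\epsilon_i \sim N(0, \sigma^2)$ —
the magnitude-MRI noise law; the default $\sigma = 20$ a.u. gives SNR ≈ 50
at $b=0$. The T2W field additionally passes through a sinh–arcsinh transform
$z \mapsto \sinh(\operatorname{asinh}(z) + \varepsilon)$, with
$\varepsilon$ solved numerically so the population skewness matches the
class target: PCa lesions are right-skewed on T2W more than BPH, and the
generator reproduces that asymmetry direction.

Two generation modes exist. *Image mode* draws each patient's lesion-level
ADC/T2W mean and SD from the between-patient class distributions and
synthesizes full volumes. *Fast mode* draws the 22 whole-lesion features
directly from the class-conditional normals — the right tool for
statistical calibration studies, since it skips image synthesis entirely.
The published "±" dispersions are interpreted as between-patient SDs of
per-lesion summaries (the generator exposes within-lesion SDs separately,
via `lesion_adc_sd`/`t2w_sd`).

What the generator does **not** emulate: prostate zonal anatomy, multifocal
lesions, anisotropic diffusion (the three orthogonal diffusion gradients are
modeled as a single isotropic trace image), scanner artifacts, inter-feature
correlation in fast mode, and rater variability in seed placement. Passing
tests therefore demonstrate the correctness and calibration of the
*computational* pipeline under the stated generative assumptions, not
clinical performance on real data.

## ADC fitting

Plain (unweighted) log-linear OLS over all b-values is the default — the
simplest reading of an inline vendor calculation; a signal-variance-weighted
fit ($w = S^2$) is available behind a flag, and any b-subset can be
selected (a two-point subset reduces exactly to
$\mathrm{ADC} = \ln(S(b_1)/S(b_2))/(b_2-b_1)$). Non-positive signals are
floored at $10^{-3}$ a.u. before the log and negative fitted slopes are
clamped to zero; both counts are reported in the fit metadata so silent
repair is visible. ADC is reported in $10^{-6}$ mm²/s, the scale on which
prostate values run roughly 500–1200.

## Random-walker segmentation

Edge weights on the 6-connected lattice are
$w_{ij} = \exp(-\beta (g_i - g_j)^2)$ with intensities rescaled to
$[0,1]$; $\beta = 130$ by default (common random-walker practice — the
algorithm's original parameterization), tolerance $10^{-8}$. The foreground
probability of each unseeded voxel is the discrete harmonic function with
seeds as Dirichlet boundary values. The package solves the sparse symmetric
positive-definite system directly (Matrix sparse Cholesky) rather than with
an iterative Krylov scheme: at the grid sizes involved (≤ ~10⁵ voxels) the
direct solve is exact, fast, and has no convergence failure mode; the
residual actually achieved is still checked against `tol` and stored in the
map's metadata. Gaussian weights are strictly positive, so true graph
disconnection only occurs when extreme $\beta$ underflows a weight to zero;
components left without any seed are then flagged and assigned probability
0.5 with a warning. Thresholding at 0.5 gives the two-label decision; seeds
always keep their own label.

Mask propagation between grids assumes both volumes share the
field-of-view corner, with voxel centers at
$(\text{index} - 0.5)\cdot\text{spacing}$; nearest-neighbor lookup in that
frame makes integer upsampling exactly block-replicating and
volume-preserving. On-disk seed files use 0-based (z, y, x) triplets —
fixed conventions, stated once, because mask propagation silently depends
on them.

## Feature extraction

First-order statistics use the sample SD ($n-1$), type-7 percentiles
(linear interpolation between order statistics), and the SPSS-style
bias-corrected skewness ($G_1$) and excess kurtosis ($G_2$, Gaussian → 0) —
the conventions under which the calibration constants' kurtosis magnitudes
near zero make sense. A zero-variance sample returns skewness = kurtosis = 0
by convention.

Texture uses 32 equal-width bins over the in-mask range (a common radiomics
default; the vendor setting is unreported), the 13 unique distance-1 3D
offsets accumulated into one symmetric matrix, and natural logs (base 2
selectable). `diff_variance` is the variance of the difference histogram
$p_{x-y}(k)$ — the literature is split on Haralick's $f_{10}$, so the
definition is documented and oracle-tested. Because bin count, offsets and
log base are all vendor-convention-dependent, absolute texture values are
not comparable across implementations; only within-pipeline contrasts
(class differences, AUCs) are meaningful, and the tests treat them that way.
A mask with no valid voxel pair (e.g. a single voxel) yields missing texture
features rather than a fabricated zero.

## Diagnostic statistics

AUC is the Mann–Whitney pair-counting estimator with half-credit for ties;
`direction = "auto"` orients the score so AUC ≥ 0.5 and records the
orientation as the cutoff inequality (low ADC indicates cancer, so ADC
features report "≤" cutoffs). The 95% CI and the test against AUC = 0.5 use
the DeLong variance estimator — the default of the common clinical ROC
software. Cutoff candidates are the midpoints between adjacent distinct
scores (which is why optimal cutoffs land on half-units); ties in the Youden
index break toward higher sensitivity, then the lower cutoff.
Likelihood ratios are $+LR = \text{sens}/(1-\text{spec})$ and
$-LR = (1-\text{sens})/\text{spec}$ with infinite sentinels at the
boundaries. The t-test defaults to Welch (robust to the unequal class
variances the calibration constants show), with the pooled-variance option
for matching classic "independent-samples t-test" reports. No
multiple-testing correction is applied by default, matching the raw-p
reporting style of the emulated analysis; a Benjamini–Hochberg adjustment
can be applied downstream via `p.adjust`.

Combined parameters are a maximum-likelihood logistic regression on
standardized features; the combined score is the predicted probability, so
its cutoffs live on the 0–1 scale. Complete separation (guaranteed at tiny
n) falls back to a ridge-stabilized fit ($\lambda = 10^{-3}$ on the slopes)
with a warning — the AUC of the score is unaffected by the stabilization
because it is rank-based.

## Numerical choices and problem sizes

Determinism: every stochastic stage derives its seed from a master seed
through a counter scheme (`derive_seed`), so cohorts, phantoms and pipeline
outputs are byte-reproducible; per-patient seeds are independent of cohort
size and order.

The test suite runs its Monte-Carlo checks at sizes chosen to make each
asymptotic claim actually hold while keeping the suite quick: the law of
large numbers and closed-form-AUC checks at 1500–4000 patients per class
(3-SE tolerances), Rician ADC bias at 10⁴ voxels, DeLong coverage at 1000
replicates of 100 + 100 subjects, and the null false-positive rate at 1000
replicates of 30 + 30. Dense-oracle comparisons for the walker run at
$\beta \le 60$: with rescaled unit gaps and $\beta \gtrsim 100$ the dense
Laplacian is numerically singular (weights below $10^{-40}$), which probes
conditioning rather than correctness.

## Known limitations

- Phantoms are geometric idealizations; no claim is made about real-lesion
  morphology or about absolute texture values' transportability.
- Fast-mode features are drawn independently per feature; real radiomics
  features are strongly correlated, so combined-parameter gains in fast-mode
  simulations are optimistic.
- The walker is two-label only, and seeding is programmatic; interactive
  manual correction is represented only as an optional mask-edit step, not
  a GUI.
- DeLong intervals are asymptotic; at very small n (tens per class) their
  coverage runs one to two points below nominal.
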