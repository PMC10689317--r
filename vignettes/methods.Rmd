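---
title: "Radiomics prognostic modelling for MR and DCE-MR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics prognostic modelling for MR and DCE-MR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dceradiomics)
```

## What the package does

`dceradiomics` implements a complete, testable radiomics survival-modelling
workflow for tumour imaging: conventional MR volumes (e.g. proton-density-
and contrast-enhanced T1-weighted sequences) and dynamic contrast-enhanced
(DCE) MR series are quantified into radiomic features inside a tumour ROI,
prognostic Cox models are built from those features by LASSO selection and
backward elimination, and the models are evaluated by concordance, risk
stratification and net reclassification. Because clinical imaging cohorts
of this kind are rarely shareable, the package ships a synthetic-cohort
simulator with known ground truth so that every stage — from the
pharmacokinetic fit to the combined model's incremental value — can be
validated end to end without any external data.

## The synthetic cohort

Each simulated subject is an ellipsoidal tumour ROI inside a 3-D grid.
In-ROI intensities are a smooth Gaussian random field (white noise smoothed
to a configurable correlation length, default 2 voxels) scaled to a
subject-specific *contrast* — the in-ROI intensity SD — drawn from a
population distribution (mean 20, SD 8 on a baseline intensity of 100).
Gaussian fields were chosen because their variance is analytically
controllable, which makes heterogeneity covariates exact ground truth
rather than estimated quantities.

Pharmacokinetic truth is assigned per voxel: subject-mean
$K^{trans}$ (0.2 min$^{-1}$), $v_e$ (0.4) and $v_p$ (0.05) — typical tumour
DCE values — modulated by a spatial field with 20% coefficient of
variation, clipped to physical ranges with $v_e + v_p \le 1$. The DCE
series follows the extended Tofts model

$$C_t(t) = v_p\,C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
  e^{-k_{ep}(t-\tau)}\,d\tau,\qquad k_{ep} = K^{trans}/v_e,$$

driven by a fixed analytic population arterial input function (linear bolus
ramp to 5 mM at 0.4 min, then a bi-exponential washout). A shared analytic
AIF — rather than a patient-specific arterial measurement — keeps the
simulation reproducible and is sufficient for parameter-recovery testing.
The convolution treats the AIF as piecewise linear between samples and is
evaluated by an exact recursion, so the noiseless forward model agrees with
fine-grid quadrature to better than 0.1%. Additive Gaussian noise (default
0.02 mM) models acquisition noise.

Survival ties to the *true* latent covariates, not to extracted features:
the hazard is exponential, $h(t \mid z) = h_0 e^{\beta^\top z}$ with
$h_0 = 0.02$ events/month (baseline median about 35 months, the order of
magnitude of progression-free survival in the cohorts this design targets)
and $z$ the standardised texture contrast and mean $K^{trans}$. Event times
use inverse-transform sampling; independent exponential censoring is
calibrated by root finding so the expected censored fraction matches the
configured rate (default 0.4). Tying risk to truth makes feature-to-risk
recovery a genuine end-to-end test: the pipeline only wins if the extracted
features actually capture the heterogeneity that drives the hazard.
A Weibull baseline is a possible config extension; the exponential was kept
because it is the simplest inverse-transform and suffices for calibration
testing.

What the simulator does *not* emulate: MR physics (coil bias fields,
motion, partial volume), anatomical context, signal-to-concentration
conversion, and realistic feature correlation structure across sequences.
Passing tests therefore demonstrate the correctness of the computational
chain and its statistical calibration, not clinical performance on real
cohorts.

## Pharmacokinetic fitting

`fit_extended_tofts()` uses the linearised form of the extended Tofts
model: regressing $C_t(t_i)$ on $\int_0^{t_i} C_p$, $\int_0^{t_i} C_t$ and
$C_p(t_i)$ (cumulative trapezoids) recovers $k_{ep} = -b$, $v_p = c$,
$K^{trans} = a - k_{ep} v_p$. Linear least squares is deterministic — no
starting values or iteration — which is why it was preferred over nonlinear
fitting. Voxels with unphysical solutions (negative rates, fractions
outside $[0,1]$) are flagged rather than silently clipped; `clip = TRUE`
gives the clipped variant. An identically zero tissue curve is recognised
as the valid null solution. Consistency $v_e = K^{trans}/k_{ep}$ holds to
1e-6 relative on flagged-ok voxels. Noiseless dense sampling recovers
parameters to well under 1%; at 5%-of-peak noise the median $K^{trans}$
error stays under 10% (both asserted in the tests). Conversion from MR
signal to concentration is out of scope: the fit consumes concentration
series.

## Feature extraction

Gray levels are discretised with a fixed bin width
($\ell(x) = \lfloor (x - \min_{ROI} x)/w \rfloor + 1$, default $w = 5$
intensity units). Binning from the in-ROI minimum makes all texture
features invariant to global intensity shifts. The same width applies to
filtered images by default but is configurable per image type; in the
pipeline the pharmacokinetic maps use $w = 0.01$ because their intensities
(fractions, min$^{-1}$ rate constants) live on a scale two orders of
magnitude below MR gray values.

Derived images: square root ($\sqrt{|x|}$), slice-wise local binary
patterns (radius 1, 8 samples, uniform patterns — 2-D because LBP
neighbourhood geometry is conventionally in-plane), and the 8 sub-bands of
a one-level 3-D stationary wavelet decomposition with the coiflet-1 kernel.
The filter pair is normalised by $1/\sqrt{2}$, which makes the undecimated
bank an exact energy partition (sub-band energies sum to the input energy);
sub-band letters are ordered (x, y, z).

Families implemented per the standard matrix definitions: first-order
(population variance, robust mean absolute deviation over the 10th–90th
percentile band, and the usual set), GLCM (13 3-D directions at distance 1,
symmetric matrices, per-direction features averaged — averaging, not matrix
merging, is stated explicitly because both aggregations exist in the
literature), GLSZM (26-connected zones; 8-connected on single slices),
GLDM (dependence $= 1 +$ equal-level neighbours, $\alpha = 0$) and NGTDM.
The maximal correlation coefficient is $\sqrt{\lambda_2}$ of
$Q(i,j) = \sum_k p(i,k)p(j,k)/(p_x(i)p_y(k))$, defined as 1 on a
single-level ROI. Shape features come from the original mask only: voxel
volume, surface area from a marching-tetrahedra mesh of the 3×3×3
box-smoothed mask (a binary iso-surface overestimates a sphere's area by
roughly a quarter; sub-voxel interpolation on the smoothed mask brings the
digitised-ball sphericity within about 1% of 1), sphericity and maximum
3-D diameter. Every texture feature is verified against an independent
brute-force enumeration oracle in the test suite, exactly, on random
images.

The catalogue is deliberately the families above plus a documented
first-order set — not a 1600-feature surface — because feature counts are
config- and data-dependent and parity with any particular platform is a
non-goal.

## Model construction

All thresholds follow the study design the package reproduces: Pearson
redundancy filtering at $|r| > 0.8$ (greedy, column order, so runs are
reproducible), LASSO-Cox with the penalty chosen by 10-fold
cross-validation at minimum partial-likelihood deviance (folds are
event-stratified; features are standardised to train-set mean/SD first,
since L1 penalisation requires a scale convention), backward elimination
dropping the single worst feature by Wald p-value until all $p < 0.05$,
a VIF check flagging values above 5, and a multivariate Cox fit with
Breslow ties. The training-median linear predictor is stored as the risk
cutoff; ties at the cutoff go to the low-risk group.

The combined model decorrelates the DCE feature block against the MR
model's linear predictor at the same 0.8 threshold ("highly correlated" is
otherwise unquantified, so the one quantified threshold in the design is
reused), pools the survivors with the MR prediction, and reruns selection.
If nothing survives decorrelation the MR model is returned unchanged and
flagged — fusing pure duplication should not manufacture a new model.

## Evaluation

Harrell's C counts pairs where the subject with the strictly earlier
observed time had an event; score ties credit 1/2; pairs with tied observed
times are not usable (simulated times are continuous, so this convention is
inconsequential there but is stated for real data). Confidence intervals
are percentile bootstrap over 1000 subject resamples. Kaplan-Meier and
log-rank use the survival package; both are verified against hand
product-limit and observed-minus-expected arithmetic in the tests.

The NRI is the two-category variant at a fixed horizon: subjects are
events if they progressed by the horizon, non-events if followed beyond
it, and excluded when censored earlier (their status is unknown; the
exclusion count is reported). The report always carries the
reclassification counts behind the index because an NRI under a poorly
calibrated risk function can mislead; read it alongside the C-index.

## The pipeline and reproducibility

`run_study()` chains every stage with per-stage RNG seeds derived from a
single master seed by fixed offsets, caches stage outputs keyed by a config
hash, and emits a manifest of every seed and threshold used — rerunning the
same configuration reproduces the report bit for bit. Sliding-window
feature maps assign each in-ROI pixel the feature value of its
window×window in-plane patch (default 21×21, step 1), restricted to
patch∩ROI, discretised per patch from the patch minimum so patches are
self-contained (a global-origin variant is available); patches are clipped
at image borders, pixels whose patch is less than 25% in-ROI are left
undefined, and a window wider than the ROI's smallest bounding edge warns
rather than errors. Maps equal direct per-patch extraction exactly — that
equivalence, not visual plausibility, is the tested contract.

Problem sizes used by the test suite and the acceptance script are scaled
to what the properties need: texture oracles run on images up to 6×6×3
(exactness is size-independent), pharmacokinetic recovery on 60–80-point
curves and 200 voxels, selection/calibration studies on cohorts of n = 200
at the covariate level, and the full imaging pipeline on cohorts of 12–40
subjects with 16–24-voxel grids; these sizes were chosen once as sufficient
for the assertions they support.

## Known limitations

The simulator's texture model is stationary Gaussian — real tumours have
non-Gaussian, non-stationary heterogeneity. The survival mechanism is
exponential with two latent covariates; proportional hazards holds by
construction, so the pipeline is not a test of PH diagnostics. Backward
elimination inherits the known instability of p-value-driven selection in
small event counts — the pipeline reports convergence fallbacks rather than
hiding them. On very small test splits the NRI horizon may precede every
event; the pipeline then reports NA rather than a number.
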