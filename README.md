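# dceradiomics

Radiomics survival modelling for conventional MR and dynamic
contrast-enhanced MR (DCE-MR) tumour imaging, with a synthetic-cohort
simulator that makes the entire workflow testable against known ground
truth.

Quantitative imaging studies of tumour prognosis typically (1) delineate a
tumour ROI on several MR sequences, (2) estimate pharmacokinetic parameter
maps from the DCE series, (3) reduce ROI and maps to radiomic features,
(4) select a sparse feature set and fit a Cox proportional-hazards model,
and (5) report concordance, risk stratification and the incremental value
of fusing modalities. The patient data behind such studies are almost never
shareable, which makes the computational chain hard to verify. This package
implements the full chain as composable, seed-deterministic R functions and
validates every stage on simulated cohorts where the truth is known.

## What is inside

* **Synthetic cohorts** — ellipsoidal tumour phantoms with Gaussian-random-
  field texture of controlled heterogeneity; per-voxel extended-Tofts DCE
  simulation ( $C_t = v_p C_p + K^{trans}\int_0^t C_p e^{-k_{ep}(t-\tau)}d\tau$,
  $k_{ep}=K^{trans}/v_e$ ) under a shared analytic arterial input
  function; exponential proportional-hazards survival tied to the *true*
  heterogeneity covariates, with calibrated independent censoring.
  NIfTI/CSV/JSON round-trip via `write_cohort()` / `read_cohort()`.
* **Pharmacokinetics** — `fit_extended_tofts()`: the linearised extended
  Tofts model solved voxel-wise by least squares on cumulative trapezoid
  integrals; unphysical voxels flagged, not clipped.
* **Features** — fixed-bin-width discretisation (width 5 by default, origin
  at the in-ROI minimum); square-root, slice-wise uniform LBP and 3-D
  stationary coiflet-1 wavelet filters; first-order statistics (population
  variance, robust MAD, ...); GLCM (incl. maximal correlation coefficient),
  GLSZM (incl. large-area high-gray-level emphasis and normalised gray-level
  non-uniformity), GLDM, NGTDM; mesh-based shape features. All texture
  features match independent brute-force oracles exactly in the tests.
* **Models** — `train_radiomics_model()`: cleaning, Pearson redundancy
  filtering (|r| > 0.8), LASSO-Cox (glmnet, 10-fold CV, minimum-deviance
  lambda), backward elimination by Wald p (alpha = 0.05), VIF screening
  (limit 5), Breslow-ties Cox fit with a training-median risk cutoff.
  `build_combined_model()` fuses DCE features with an MR model after
  decorrelating them against the MR prediction.
* **Evaluation** — Harrell's C-index with bootstrap CIs, Kaplan-Meier risk
  stratification with log-rank tests, and a two-category fixed-horizon net
  reclassification improvement, all with tidy tibble outputs, plus
  `tidy()` / `glance()` / `autoplot()` methods.
* **Feature maps** — `compute_feature_map()`: sliding-window (default
  21×21, step 1) per-pixel feature maps over the ROI, and device-free PNG /
  NIfTI overlays via `overlay_map()`.
* **Pipeline** — `run_study()` chains everything on a simulated cohort with
  per-stage derived seeds, stage caching and a reproducibility manifest.

## Worked example

```r
library(dceradiomics)
library(dplyr)

cfg <- study_config(
  cohort = cohort_config(n_subjects = 24, vol_dim = c(24, 24, 24),
                         roi_semiaxes = c(7, 6, 5),
                         dce_times = seq(0, 5, length.out = 20),
                         censor_rate = 0.3, seed = 9),
  map_window = 9, n_map_subjects = 1, seed = 9)
bundle <- run_study(cfg, out_dir = "run1")
bundle
#> <study_bundle>
#>   MR        C-index train 0.841 / test 0.316 (95% CI 0.000-1.000)
#>   DCE       C-index train 0.898 / test 0.579 (95% CI 0.142-1.000)
#>   combined  C-index train 0.898 / test 0.579 (95% CI 0.142-1.000)
#>   NRI combined vs MR: 0.583; vs DCE: 0.000
```

The printout shows, for each model family (MR multi-sequence, DCE
multi-parameter, and their combination), the training and held-out test
concordance: the probability that of two comparable subjects the one who
progresses earlier carries the higher risk score (0.5 is chance). At this
deliberately small n = 24 the 7-subject test split makes the test C-index
very noisy — the wide bootstrap intervals say exactly that; the
training-set concordances and the NRI of the combined model against the MR
model are computed on the same run artefacts. Model internals are tidy:

```r
tidy(bundle$models$mr)
#> # A tibble: 1 × 5
#>   term                              estimate std.error statistic p.value
#>   <chr>                                <dbl>     <dbl>     <dbl>   <dbl>
#> 1 PDw_wavelet-LLL_firstorder_Median    -1.90     0.661     -2.87 0.00410
```

Single stages compose the same way from tibbles:

```r
coh   <- simulate_cohort(cohort_config(n_subjects = 20, seed = 1))
feats <- extract_cohort_features(coh)
data  <- left_join(coh$survival, feats, by = "id") |>
  split_cohort(ratio = 0.7, seed = 1)
model <- train_radiomics_model(filter(data, split == "train"), seed = 1)
stratify_and_test(model, filter(data, split == "test"))$logrank
```

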