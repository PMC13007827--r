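---
title: "Multimodal normative abnormality mapping for epilepsy surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal normative abnormality mapping for epilepsy surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In drug-resistant temporal lobe epilepsy (TLE), surgical outcome depends
on whether the epileptogenic tissue was removed. Patients who need
invasive intracranial EEG (iEEG) evaluation are exactly the ones in whom
localization is hardest, and their outcomes are correspondingly worse.
`epizmap` implements a quantitative, multimodal localization analysis:
regional brain features from three modalities are z-scored against
normative reference cohorts, patient-specific abnormal regions are
identified by change-point thresholding of the ranked z-scores, and the
proportion of abnormal regions that fell inside the surgical resection
is tested as a discriminator of seizure outcome (ILAE class 1–2 versus
3+).

The three modalities are:

* **GM volume** — regional gray-matter volume from T1-weighted MRI;
  atrophy (negative z) is the abnormality of interest.
* **SWM MD** — mean diffusivity of superficial white matter, the WM
  shell within 5 mm of the GM–WM boundary; elevated diffusivity
  (positive z) indicates microstructural disruption.
* **iEEG band power** — relative spectral power of interictal
  recordings in the five canonical bands (δ 1–4, θ 4–8, α 8–13,
  β 13–30, γ 30–80 Hz), z-scored per region and band against a
  normative map built from non-epileptogenic channels; abnormality is
  the maximum |z| across bands.

## Normative modelling

For each region (and band), controls provide a covariate model
`value ~ age + sex` fitted by least squares; the stored normative map
holds the coefficients, the residual standard deviation, and the number
of controls. A patient's z-score is

    z = (value − predicted control mean at the patient's age and sex) / SD.

Signs are preserved throughout: the analysis is direction-aware (GM
volume loss is negative, SWM MD elevation positive).

Decisions worth knowing:

* **Batch harmonization** uses the parametric empirical-Bayes
  location/scale model (ComBat, via the `sva` package), applied jointly
  to controls and patients per modality before the normative fit, with
  age and sex protected. A single-batch table is returned unchanged.
* **Residual-based z-scoring.** Covariates could instead have been
  absorbed into the harmonization step alone; we fit them explicitly on
  controls and predict for patients, which is standard normative-model
  practice and keeps the map interpretable. This choice is testable:
  the leave-one-out self-calibration (`control_self_calibration()`)
  checks that control z-scores pool to mean ≈ 0, SD ≈ 1.
* **`sd_floor`** (default `1e-6` feature units) clamps degenerate
  residual SDs so constant synthetic regions produce z = 0 rather than
  infinities. **`n_min`** (default 10) drops regions with too few
  controls; dropped regions propagate as *missing coverage*, never as
  z = 0.

## iEEG band power

Recordings are downsampled to 200 Hz (zero-phase Butterworth
anti-aliasing for integer ratios, polyphase resampling otherwise),
common-average referenced, and a 70-s interictal epoch is extracted
(with an optional ≥2-h post-seizure metadata check). Welch's method
uses 2-s Hamming windows with 1-s overlap (0.5-Hz resolution), segments
mean-detrended, one-sided density scaling, so that the integrated PSD
recovers the signal variance (a Parseval check is part of the test
suite).

Band powers integrate the PSD over half-open intervals `[lo, hi)`: a
shared edge (4, 8, 13, 30 Hz) belongs to the upper band, so no power is
counted twice. Relative powers are the band powers divided by their sum
over the five bands — they sum to exactly 1 per contact. Because
"log-transform then normalize to sum 1" is ill-defined when logs are
negative, the package normalizes first and then takes log10 of the
relative power for normative z-scoring; relative powers make the whole
pipeline invariant to amplifier gain.

Contacts are assigned to the region with the nearest representative
point (Euclidean, mm): contacts farther than 5 mm from every region are
excluded, as are white-matter contacts farther than 2 mm from gray
matter, and contacts flagged as artifactual. Regional values are the
mean of log10 relative power across a region's retained contacts
(averaging after the transform); regions without contacts are missing,
and missing iEEG coverage can never veto a region into or out of an
abnormal set.

## Ranking and change-point thresholding

Within each modality the patient's regional scores are ranked by the
abnormality convention — GM ascending (most negative first), SWM and
iEEG descending — with ties broken by region id so results are
reproducible. The threshold between "abnormal" and "the rest of the
distribution" is the change point of the ranked curve.

The detector fits a two-segment Bayesian regression with a single
change point: each segment has its own intercept, slope, and noise
variance under conjugate normal-inverse-gamma priors, so the per-split
marginal likelihood is available in closed form. A uniform prior over
admissible splits gives the change model's evidence, which must exceed
the no-change model's (a single regression over the whole curve) by a
log-Bayes-factor margin (default 0); otherwise the abnormal set is
empty.

Two design points deserve emphasis:

* **Linear, not constant, segments.** The ranked curve of a
  well-calibrated null patient is a smooth monotone ramp (sorted
  Gaussian order statistics). A piecewise-*constant* mean model always
  prefers splitting such a ramp in the middle — every null patient
  would get an abnormal set of half the regions. With linear segments
  the no-change model explains the ramp, and a genuine abnormal cluster
  appears as an intercept discontinuity. The classic constant-mean
  model remains available (`segment_model = "constant"`) and is the
  natural choice for sequences in native (unranked) order; both
  variants are verified against an independent sequential-predictive
  evidence oracle.
* **Search limited to the first half** (`max_frac = 0.5`). The abnormal
  segment is by construction the extreme minority at the head of the
  ranking; without the cap, the model happily "detects" the lower tail
  of a sorted null curve, labelling nearly all regions abnormal.

Priors are empirical — intercept centered on the sequence mean, slope
on zero, noise scale tied to the sequence variance — which makes the
selected k and the Bayes factor exactly equivariant under affine
transforms of the scores (a property test). Minimum segment length is 2
so a single extreme region can still form a segment with its neighbour.
The per-patient MRI abnormal set is the union of the GM and SWM sets;
the multimodal set additionally unions the iEEG set over its sampled
coverage, with per-region provenance recorded. Concordance
(intersection) is deliberately not offered.

## Resection overlap and outcome statistics

A region counts as resected when strictly more than 10% of its voxels
overlap the resection mask (`resection_overlap_fractions()` computes
the fractions from label volumes; precomputed fractions are accepted
too). The patient's score is the proportion of abnormal regions
resected; a patient with an empty abnormal set has an undefined score
and is excluded from group comparisons with an explicit count —
imputing 0 or 1 would fabricate signal.

Outcome differentiation uses:

* **AUC** in the Mann–Whitney formulation (midranks for ties), verified
  against O(n²) pair counting and trapezoidal ROC integration.
* **AUPRC** by the non-interpolated step rule at distinct thresholds,
  positives = ILAE 1–2.
* **One-tailed Wilcoxon rank-sum** (seizure-free group stochastically
  greater), exact by complete enumeration up to a combined n of 12
  (valid under ties, via midranks), normal approximation with tie and
  continuity correction beyond; all-tied inputs report p = 1.
* **DeLong's test** for the paired AUC comparison of the MRI-only and
  multimodal scores, using placement-value structural components;
  identical score vectors return z = 0, p = 1, and a zero variance
  estimate with a nonzero AUC difference is an explicit error.
* **Colocalization logistic regressions**, pooling (patient, region)
  observations within each outcome group: response = implanted (or
  iEEG-abnormal among implanted regions), predictor = MRI-abnormal.
  Complete separation (an empty 2×2 cell) is an explicit error, never a
  silent huge coefficient. Pooling without patient random effects
  mirrors a plain binomial regression; within-patient clustering is a
  known limitation (below).
* **Leave-one-out cross-validation**: for each held-out patient the
  threshold on the overlap score maximizing balanced accuracy on the
  rest is chosen (ties resolved to the lowest threshold, strict `>`
  classification), and held-out accuracy is reported.
* Cohort description uses chi-square with Yates continuity correction
  (2×2) and Kruskal–Wallis with tie correction, both via the standard
  base-R implementations.

## The synthetic cohort generator

No patient data ship with the package; the generator produces cohorts
with the statistical structure the analysis assumes, plus the ground
truth needed for parameter-recovery tests. What it emulates:

* **MRI controls** (default 97) in two scanner batches with additive
  offsets (+30 mm³ GM, +2·10⁻⁵ mm²/s MD) and a 1.1× noise scale;
  regional baselines GM ~ U(2800, 4200) mm³ with noise SD 150 mm³ and
  age slope −3 mm³/yr, SWM MD ~ U(7.5, 8.5)·10⁻⁴ mm²/s with noise SD
  2.5·10⁻⁵ and a small positive age slope — realistic magnitudes for
  regional gray-matter volume and diffusivity.
* **A 60-region bilateral parcellation** (30 per hemisphere, 4 deep,
  hippocampus included) standing in for a 460-region scheme at desk
  scale; the full scale is a configuration switch.
* **Patients** (default 40), each with 6 planted epileptogenic regions
  on the surgical side (always including the ipsilateral hippocampus),
  of which 3 express structurally (GM −3 SD, SWM +3 SD — the scale of
  hippocampal sclerosis) and a spec-dependent subset expresses
  functionally. Half the specs are *well-characterized*: concordant
  modalities, implantation targeted at the epileptogenic set (fidelity
  0.9), and 85% of it resected. Half are *mislocalized*: only the
  structurally silent regions express functionally, implantation at
  chance level (fidelity = base implantation rate — effectively
  uniform), and 30% resected. This expresses the clinical narrative
  that poor outcomes reflect mismatches between structural
  abnormalities, implantation, and functional abnormality.
* **iEEG**: 20 implanted regions per patient (comparable in breadth to
  ~74 clinical channels), one contact near each sampled region's
  centroid, channels synthesized as band-limited noise via
  shaped-spectrum inverse FFT with per-subject log-normal band-weight
  jitter (SD 0.4, the between-subject spread the normative map
  measures). The planted spectral abnormality multiplies the designated
  band's power by `exp(4 × 0.4)` ≈ 5 in functionally expressing
  implanted regions. The normative iEEG reference is 30 subjects
  sampling 30 regions each (≈15 subjects per region–band cell).
* **Outcomes** are Bernoulli draws from a logistic link on the true
  proportion of epileptogenic regions resected (intercept −5.5, slope
  10), giving well-characterized patients ≈0.94 and mislocalized
  patients ≈0.10 probability of an ILAE 1–2 outcome — planted
  discriminability on the order of the effect sizes this kind of
  analysis reports (AUC ≈ 0.9).

What it deliberately does **not** emulate: image synthesis and the
imaging preprocessing chain, spatial autocorrelation between
neighbouring regions, seizure dynamics or spikes, line noise and
artifacts (artifact status is an input flag), electrode trajectory
geometry, and within-patient correlation beyond the planted structure.
Passing tests therefore show that the *analysis machinery* recovers
planted structure under its own assumptions — not that the pipeline
would behave identically on real imaging data.

All generators are seed-deterministic: one master seed derives
per-stage child seeds, and identical configurations reproduce
bit-identical cohorts.

## Problem sizes and numerical choices

The test suite exercises the full default cohort (97 controls, 40
patients, 60 regions, 30 iEEG normative subjects) for the end-to-end
recovery checks, and reduced cohorts (30 controls, 8 patients, 20
regions) for orchestration tests. Change-point recovery is measured at
200 replicates of a 3σ shift at index 10 in length-60 sequences;
rank-sum type-I error at 2000 null replicates of n = 19 vs 21; the
DeLong variance against a 2000-replicate paired bootstrap at n = 40;
control leave-one-out calibration on 10 regions × 97 controls. Voxel
feature extraction uses exact blocked brute-force nearest-gray-matter
search, exhaustively verified on ≤10³ grids; it is intended for
desk-scale volumes, not full-resolution images.

## Known limitations

* The colocalization regressions ignore within-patient clustering of
  (patient, region) observations; a mixed model would widen the
  intervals somewhat.
* The change-point model detects a single threshold; a
  multiple-change-point variant is not implemented (the single cut is
  the quantity of interest here).
* LOO z-scores on heavy-tailed control cohorts exceed SD 1 — reported,
  not corrected; the normative model is Gaussian.
* The exact rank-sum enumeration is limited to a combined n of 12 by
  combinatorics; beyond that the corrected normal approximation is
  used.

## A minimal run

```{r example}
library(epizmap)

cfg <- pipeline_config(simulate = cohort_config(seed = 11))
res <- run_pipeline(cfg)

res$stats$mri$auc        # outcome differentiation, MRI abnormalities
res$stats$mri_ieeg$auc   # with iEEG abnormalities added
res$stats$delong$z       # paired comparison of the two AUCs
res$stats$colocalization$implanted_good$z
head(res$prevalence[order(-res$prevalence$fraction), ])
```
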