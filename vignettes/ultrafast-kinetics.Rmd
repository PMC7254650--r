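---
title: "Ultrafast DCE-MRI kinetic markers: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrafast DCE-MRI kinetic markers: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufdce)
```

## The problem

Ultrafast dynamic contrast-enhanced (DCE) breast MRI samples the first
~60 s after gadolinium injection at a temporal resolution of a few
seconds (here 15 phases at ~4 s), fast enough to resolve the arrival and
initial inflow of the contrast bolus in a lesion. Two heuristic kinetic
markers summarize that inflow:

* **Maximum slope (MS)**, in mmol l^-1^ s^-1^: the steepest slope of the
  gadolinium concentration uptake curve between bolus arrival and the
  concentration peak.
* **Bolus arrival time (BAT)**, in seconds: the time from the start of
  contrast injection to the arrival of the bolus at the lesion.

Shorter BAT and larger MS reflect earlier, faster inflow and are
associated with more aggressive disease (invasive rather than in-situ
carcinoma, higher grade, triple-negative/HER2 rather than luminal
subtype). `ufdce` implements the full analysis chain — signal-to-
concentration conversion, voxelwise marker extraction, ROI aggregation,
and the clustered cohort statistics — together with a seeded synthetic
cohort generator that emulates the data structure of a 125-patient /
142-lesion breast MRI study, so that every stage can be validated
against known ground truth.

## Signal model and concentration conversion

Signal formation is modelled as spoiled gradient-echo (SPGR):

$$S(T_1) = M_0 \sin\alpha\,\frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1},$$

with TR = 3.8 ms and flip angle α = 12°. Contrast concentration changes
tissue T1 through the linear fast-exchange relaxivity model
$1/T_{1,\mathrm{post}} = 1/T_{1,\mathrm{pre}} + r_1 C$ with
T1~pre~ fixed at 1444 ms (breast fibroglandular tissue at 3T) and
r1 = 4.9 s^-1^ mM^-1^ (gadobutrol). The conversion of a signal time
series to concentration proceeds per timepoint:

1. the baseline signal S~pre~ is the mean of the first `n_baseline = 3`
   phases (treated as pre-contrast);
2. the SPGR ratio equation $S_\mathrm{post}/S_\mathrm{pre} =
   f(T_{1,\mathrm{post}})/f(T_{1,\mathrm{pre}})$ is solved in closed form
   for T1~post~ (the scale $M_0$ cancels);
3. $C = (1/T_{1,\mathrm{post}} - 1/T_{1,\mathrm{pre}})/r_1$, with T1 in
   seconds so that C is in mmol/l.

The pair (forward model, inversion) is exact: the round trip is accurate
to better than 1e-9 relative over T1 ∈ [100, 3000] ms, and the
conversion is invariant under rescaling of the signal. T2\* decay and B1
non-uniformity are ignored by construction. Two consequences worth
knowing:

* noise can push a sample outside the physical SPGR range (the implied
  E1 outside (0,1)); such samples are returned as `NaN` with a warning
  and treated as below-floor by the kinetics, rather than fabricating a
  concentration;
* small signal drops below baseline produce small *negative*
  concentrations — these are left in place (the BAT floor removes them
  from the log domain).

The baseline definition is ambiguous in practice (first k phases vs
phases before the measured BAT); the package uses the first three phases,
because BAT is not known at conversion time. T1 values are carried in
milliseconds everywhere and converted to seconds only inside the
concentration formula; this is stated explicitly because mixing the two
conventions silently produces a 1000-fold concentration error.

## The BAT backward search

BAT is computed per voxel on the concentration curve with a
gradient-based backward search in the log domain:

1. concentrations below a floor of 0.001 mmol/l are set to zero (noise
   suppression);
2. the curve is mapped to `log(max(C, floor))`, so all pre-arrival
   samples share one finite constant;
3. the peak timepoint is located (global maximum, first occurrence on
   ties);
4. backward gradients `g_i = L_i − L_{i−1}` are formed over the uptake
   segment up to the peak;
5. walking backward from the peak, the *steep-descent run* is the
   contiguous set of gradients at or above `θ · max(g)` containing the
   maximum gradient; BAT is the timepoint immediately before that run —
   the point where, searching backward, steep descent gives way to the
   gradual flat roll-off.

The threshold fraction θ has no published numeric value; the default
θ = 0.1 was fixed by the noiseless truth-recovery sweep (onset-at-sample
curves recovered exactly; random noiseless onsets within one frame) and
is exposed in `bat_config()`. Further deliberate choices:

* **Log of zeros.** Zeroed samples enter the log at the floor value
  rather than being dropped; gradients stay finite and the backward scan
  is total.
* **BAT at the last flat sample** (`t_{b−1}`), not the first steep one:
  "changes direction" names the transition point, and this convention
  makes the noiseless onset-at-a-sample case exact.
* **Ties count as steep** (`≥ θ·g_max`, not `>`).
* A curve that never enhances, peaks at the first timepoint, or has no
  positive backward gradient gets an *undefined* BAT with a reason;
  such voxels are excluded from ROI aggregation and counted.

MS is the maximum finite difference `(C_i − C_{i−1}) / (t_i − t_{i−1})`
over consecutive pairs inside `(BAT, peak]`, computed on the raw
(unsmoothed) curve; a 3-point moving average is available behind a flag
but off by default. At ROI level, BAT is the arithmetic mean of the
defined per-voxel BATs (the published rule is explicit only for BAT);
for MS both readings are implemented — MS of the ROI-mean curve
(default, the conservative reading, and markedly more noise-robust
because averaging precedes differencing) and the mean of per-voxel MS
(`ms_mode = "voxel-mean"`).

`extract_lesion()` internally uses a vectorized matrix implementation of
the per-voxel search; its exact equality with the scalar
`compute_bat()`/`compute_ms()` reference is asserted in the test suite.

## The synthetic cohort generator

No patient data accompany the study the package emulates, so the
generator is the source of every test input. It reproduces, with a
mandatory seed:

* **Cluster structure:** 125 patients with 1/2/3 lesions in proportions
  111:11:3 (142 lesions in expectation, at most 3 per patient).
* **Labels:** histopathology (invasive : DCIS = 124 : 18), lesion type
  per class (mass/NME/focus 91:31:2 invasive, 5:13:0 DCIS), and — for
  invasive lesions — grade (7:48:56 with 13 unavailable), histotype
  (IDC:ILC:mixed = 98:20:6), molecular subtype (TN:HER2:luminal =
  12:21:91), node status (57:64, 3 unavailable) and recurrence risk
  (available for 45 of 91 luminal lesions, high:intermediate:low =
  2:13:30). Labels are drawn independently per lesion.
* **Kinetics:** MS and BAT are log-normal per stratum, parameterized by
  the published median and IQR (`meanlog = log(median)`,
  `sdlog = (log q3 − log q1)/(2 z_{0.75})`). Two prior sets ship:
  `kinetic_priors_histopathology()` (invasive vs DCIS, the published
  cohort-level medians/IQRs) and `kinetic_priors_subtype()` (default;
  DCIS plus invasive split into TN/HER2 vs luminal strata) so that the
  molecular-subtype contrast carries a real kinetic effect. Under the
  subtype priors only histopathology and molecular subtype influence
  kinetics; grade, node status and recurrence risk are label-only.
* **Curve shape:** the enhancement model is piecewise — zero before the
  onset, a linear rise of slope `ms_true` to the peak, then
  mono-exponential washout — chosen so that both target markers are
  *analytically exact* properties of the truth (the maximum slope of the
  curve is `ms_true`; the first departure from zero is at `bat_true`).
  The rise duration is log-normal with median 18 s (sd 0.2 on the log
  scale) and the washout rate is 0.01 s^-1^, giving peak concentrations
  of a few tenths of mmol/l in the 60-s window, typical of breast
  lesions at this dose. Onsets are truncated to fall after the baseline
  window. No arterial input function or pharmacokinetic model is
  implied: the published method defines only MS and BAT, and this shape
  is a stand-in that makes them exact, not a claim about real uptake
  curves.
* **Image formation:** a lesion is an ellipsoid (axis ratio 1 : 0.75 :
  0.75 of the lesion's longest diameter) on an isotropic 1.6-mm grid,
  matching the ultrafast in-plane resolution; in-mask voxels carry the
  SPGR signal of the truth curve, outside voxels the baseline signal.
  Zero-mean Gaussian noise with sd `noise_sigma × baseline` is added to
  the magnitude signal — a high-SNR approximation of Rician noise. The
  default `noise_sigma = 0.01` corresponds to a baseline SNR of ~100,
  a realistic figure for an aggressively accelerated 3T breast
  acquisition. Optional multiplicative within-lesion jitter on slope
  and onset (off by default) exercises ROI aggregation.

What the generator does **not** emulate: k-space view sharing and the
9-s temporal footprint (acquisition is simulated at the image level),
fat suppression, B1/T2\* effects, lesion shape irregularity, motion,
background parenchymal enhancement, and any correlation between labels
beyond their marginal frequencies. Passing tests therefore demonstrate
the correctness of the algorithms under the stated forward model, not
performance on real scanner data.

A systematic property of the measurement under noise is worth stating:
pre-arrival noise samples that clear the concentration floor create
spurious steep log-gradients that can chain onto the true onset cliff,
so the per-voxel BAT estimate is biased *early* — about half a frame for
invasive-like curves and up to a frame for the flatter DCIS-like curves
— while MS on the ROI-mean curve is essentially unbiased. The
discretization itself bounds BAT errors by one frame (the estimate sits
on the sampling grid at or before the true onset).

## The statistical layer

The cohort statistics mirror the published analysis battery: the
invasive-vs-DCIS contrast, five dichotomies within invasive carcinomas
(grade 3 vs 1–2, IDC vs ILC, TN/HER2 vs luminal, node status,
recurrence risk) for both MS and BAT, a multivariate logistic model
(MS + BAT + size) for invasive vs DCIS in non-mass enhancement lesions,
and a paired AUC comparison of that model against lesion size alone.
P-values below 0.05 are flagged with no multiplicity adjustment,
matching the exploratory design. Missing labels are deleted listwise
within each contrast, reproducing the per-contrast lesion counts.

**GEE.** No GEE package is available in the target environment, so the
estimating-equations fitter is implemented in the package: Gaussian
identity and binomial logit families, exchangeable or independence
working correlation (moment estimator for the exchangeable parameter,
Pearson dispersion with denominator N − p), and sandwich robust
covariance. The implementation is validated in the tests against frozen
reference fits from an independent GEE implementation (agreement to
~1e-6 on coefficients and robust SEs) and against the exact degeneracies
(singleton clusters → OLS + HC0, or ordinary logistic).

Two defaults in the *comparison layer* deserve their rationale:

* **Bias-reduced sandwich.** Calibration simulations under a clustered
  null at the study's structure (125 clusters of size 1–3, 1000+
  replicates) showed the plain sandwich Wald test rejecting at
  0.07–0.08 instead of 0.05 — and an independent reference GEE
  implementation reproduces the same inflation, so it is a property of
  the estimator, not of this implementation. `gee_compare()` and
  `gee_logistic()` therefore default to the Mancl–DeRouen (2001)
  bias-corrected sandwich, which inflates each cluster's residual by
  `(I − H_i)^{-1}` and reduces exactly to HC3 for singleton clusters.
  `gee_fit()` itself keeps the plain estimator as default for
  comparability with the reference implementations; both are selectable
  via `cov_type`.
* **Independence working correlation.** With 1–3 lesions per patient,
  only ~17 within-patient pairs inform the exchangeable correlation
  parameter; its sampling noise measurably inflates the test size
  (≈0.060 even with the bias-reduced sandwich, vs ≈0.046 under working
  independence, which brings the empirical size inside the nominal
  band). The sandwich covariance accounts for the clustering regardless
  of the working structure, so the comparison layer defaults to
  independence and retains exchangeable as a sensitivity option — the
  reverse of the more common convention, adopted here on calibration
  evidence.

**ICC.** Inter-reader agreement uses ICC(A,1) — two-way random effects,
absolute agreement, single measurement — computed from the two-way ANOVA
mean squares with the McGraw–Wong F-based confidence interval, and
interpreted on the Cicchetti bands (≥0.75 excellent, 0.60–0.74 good,
0.40–0.59 fair, <0.40 poor). The implementation is validated against a
frozen reference value from an independent implementation. This is the
most conservative common choice for two fixed readers rating a random
lesion sample.

**ROC.** AUC is the Mann–Whitney statistic (ties at half), asserted
equal to exhaustive pair counting on every fixture up to 200 rows.
DeLong's paired test uses placement-value covariances; identical score
vectors give a zero-variance difference and p = 1 by convention. Both
are cross-checked in the tests against the established `pROC`
implementation, which is never the implementation itself.

**Separation.** Logistic fits report a `separation` flag (extreme linear
predictors or exploded SEs) instead of silently regularizing.

## Problem sizes and numerical conventions

The validation suite uses, as the package's own choices: 500 noiseless
lesions for the truth-recovery sweep (≥99% of lesions must recover BAT
within one frame and MS within 5%); 1000 replicates for the type-I
calibration check (band 0.035–0.065 at α = 0.05); pooled medians over
50 seeded 125-patient cohorts for the end-to-end median-recovery check
— a single 18-lesion DCIS class has ~30% Monte-Carlo spread on its MS
median, so per-seed medians would be uninformative, while the pooled
estimate has ~4–5% standard error against a ±10% band; and 40 seeds for
the sign-stability check of the BAT coefficient in the NME logistic
model. The pipeline analyzes at most 300 in-mask voxels per lesion
(`max_voxels` in `run_config()`); ROI aggregates converge well below
this, and the cap keeps a full study-scale run near one second.

Coordinate and unit conventions, stated once: voxel indices are 0-based
in file formats and 1-based inside R; times are seconds from injection
start; phase `i` is stamped at `(i − 0.5)·dt` (frame-center, the
default) or `(i − 1)·dt` (frame-start, configurable — the acquisition
clock convention is not published); masks are nonzero-inside; T1 in ms;
concentrations in mmol/l; MS in mmol l^-1^ s^-1^.

## Known limitations

* The piecewise truth curve makes MS/BAT exact by construction; real
  uptake curves are smoother around onset and peak, so real-data BAT
  dispersion will exceed what the generator shows.
* The Gaussian-noise model understates Rician floor effects at very low
  SNR; a Rician option is a natural extension.
* The generator draws lesion labels independently, so label–label
  correlations (e.g. grade with molecular subtype) and their joint
  kinetic structure are not represented; only contrasts given a kinetic
  effect by the priors have power.
* The GEE small-sample behavior was calibrated at the study's cluster
  structure; very different cluster-size distributions may warrant
  re-checking the `cov_type`/`corstr` defaults.
* Real-data medians and p-values from the emulated study are not
  reproducible desk-side (the patient images are not public); the
  package's claims are about recovering *generator* truth and the
  printed cohort medians used as generator parameters.
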