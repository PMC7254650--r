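# ufdce — kinetic markers from ultrafast DCE breast MRI

Ultrafast dynamic contrast-enhanced (DCE) breast MRI acquires the first
~60 s after gadolinium injection at a temporal resolution of a few
seconds (15 phases at ~4 s/phase here), resolving the arrival and early
inflow of the contrast bolus in a lesion. Two heuristic kinetic markers
summarize that inflow and relate to tumor aggressiveness:

* **Maximum slope (MS)**, mmol l⁻¹ s⁻¹ — the steepest slope of the
  gadolinium concentration uptake curve between bolus arrival and the
  concentration peak;
* **Bolus arrival time (BAT)**, s — the time from the start of contrast
  injection to bolus arrival at the lesion.

`ufdce` is aimed at imaging scientists who want a tested, reusable
implementation of this analysis chain:

1. **Signal → concentration.** Spoiled gradient-echo (SPGR) signal
   S = M₀ sin α (1 − E₁)/(1 − E₁ cos α), E₁ = exp(−TR/T₁), inverted in
   closed form per timepoint against the baseline (mean of the first
   3 phases), with fixed T1_pre = 1444 ms and relaxivity
   r₁ = 4.9 s⁻¹ mM⁻¹; C = (1/T1_post − 1/T1_pre)/r₁ in mmol/l.
2. **Voxelwise kinetics.** BAT by a gradient-based backward search on
   the log-transformed curve (floor 0.001 mmol/l; the steep-descent run
   at ≥ θ·max-gradient ending where descent gives way to flat roll-off),
   MS as the steepest raw finite difference inside (BAT, peak]; ROI BAT
   as the mean over valid voxels, ROI MS from the ROI-mean curve.
3. **Synthetic cohorts.** A seeded generator emulating a 125-patient /
   142-lesion study — 1–3 lesions per patient, published label
   frequencies, log-normal MS/BAT per stratum parameterized by printed
   medians/IQRs, piecewise enhancement curves whose analytic MS/BAT are
   exact, SPGR image formation with Gaussian noise — providing ground
   truth for every downstream stage (NIfTI + CSV fixtures on request).
4. **Cohort statistics.** Generalized estimating equations over patient
   clusters (Gaussian and logistic; bias-reduced sandwich errors),
   two-reader ICC(A,1) with Cicchetti bands, Mann–Whitney AUC and
   DeLong's paired ROC test, and a `run_study()` battery reproducing the
   published comparison layout.

## Worked example

Render one fast, triple-negative-like lesion (true MS 0.145 mmol/s, BAT
18.8 s), write it to NIfTI, and extract its markers blind to the truth:

```r
library(ufdce)
protocol <- acquisition_protocol()   # TR 3.8 ms, flip 12°, 15 phases @ 4 s
truth <- data.frame(lesion_size_mm = 12, bat_true = 18.8, ms_true = 0.145,
                    peak_time_true = 36, washout_rate = 0.01)
vol <- render_lesion_volume(truth, protocol, noise_sigma = 0.01, seed = 42)
img <- tempfile(fileext = ".nii.gz"); msk <- tempfile(fileext = ".nii.gz")
RNifti::writeNifti(RNifti::asNifti(vol$signal), img)
RNifti::writeNifti(RNifti::asNifti(vol$mask), msk)
extract_from_files(img, msk, protocol)
#> Lesion kinetics (128/128 voxels valid)
#>   MS  0.1457 mmol/l/s (roi-mean-curve)
#>   BAT 17.47 s, peak 38.00 s
```

The measured MS (0.1457) recovers the truth to under 1%; the BAT
(17.47 s) sits one sample below the true onset — the estimate lives on
the 4-s sampling grid at or before the onset, so per-lesion errors are
bounded by one frame.

Run the full simulate → extract → stats pipeline at study scale:

```r
cfg <- run_config(cohort = cohort_spec(seed = 2024))
run <- run_pipeline(cfg)
print(run$report)
#> Study report: 135 lesions in 125 patients
#>   Invasive carcinoma vs DCIS             ms  P = 0.00213 *
#>   Invasive carcinoma vs DCIS             bat P = 0.0001727 *
#>   Grade 3 vs grades 1-2                  ms  P = 0.1124
#>   Grade 3 vs grades 1-2                  bat P = 0.408
#>   IDC vs ILC                             ms  P = 0.686
#>   IDC vs ILC                             bat P = 0.01475 *
#>   TN/HER2 vs luminal                     ms  P = 0.02789 *
#>   TN/HER2 vs luminal                     bat P = 0.003499 *
#>   Node positive vs negative              ms  P = 0.3628
#>   Node positive vs negative              bat P = 0.3046
#>   High/intermediate vs low recurrence risk ms  P = 0.4056
#>   High/intermediate vs low recurrence risk bat P = 0.2628
#> Logistic model (NME, invasive vs DCIS):
#>            term estimate robust_se p_value
#>     (Intercept)   6.9554    3.5692 0.05133
#>              ms  30.9209   35.6706 0.38603
#>             bat  -0.3382    0.1294 0.00898
#>  lesion_size_mm   0.0366    0.0534 0.49326
#> AUC full model 0.896 vs size alone 0.611, DeLong P = 0.001084
```

The contrasts given a kinetic effect by the default generator priors
(histopathology; molecular subtype, which also drives the IDC-heavy
histotype split) come out significant; the label-only contrasts (node
status, recurrence risk) do not. In the non-mass-enhancement logistic
model, shorter BAT predicts invasiveness (negative coefficient), and
the MS + BAT + size model clearly outperforms lesion size alone.

A thin command-line wrapper ships in `inst/cli/ufdce.R` with
`simulate`, `extract`, `stats` and `run-all` subcommands over YAML
configs, NIfTI images and CSV cohort tables.

## The methods vignette

`vignettes/ultrafast-kinetics.Rmd` documents the signal model and its
assumptions, the BAT/MS algorithms and their tie-break and threshold
conventions, what the synthetic generator does and does not emulate,
the GEE calibration study behind the default covariance and working
correlation choices, and known limitations.
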