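# cmrquant

Quantitative cardiovascular magnetic resonance (CMR) analysis for a
nonhuman-primate heart-failure model, built for researchers characterising
cardiac phenotypes (diffuse fibrosis, microvascular perfusion) in
cynomolgus macaques with heart failure with preserved (HFpEF) or reduced
(HFrEF) ejection fraction — and for anyone who needs a fully simulatable,
testable reference implementation of this pipeline.

The package covers the whole chain:

* **MOLLI T1 mapping** — per-pixel three-parameter inversion-recovery fits
  `S(TI) = |A − B·exp(−TI/T1*)|` with polarity restoration, and the
  Look-Locker correction `T1 = T1*·(B/A − 1)`; schemes 5(3)3 (native) and
  4(1)3(1)2 (post-contrast) at high heart rate (~150 bpm, RR 400 ms).
* **ECV mapping** — `ECV = (1 − Hct)·ΔR1_myo / ΔR1_blood` with `R1 = 1/T1`,
  pixel-wise over the myocardium with a blood-pool ROI reference.
* **Perfusion quantification** — dual-bolus first-pass imaging
  (0.01/0.09 mmol/kg; AIF scaled by the dose ratio 9) and
  Fermi-constrained deconvolution
  `R(t) = F·(1 + e^(−w/k)) / (1 + e^((t−τ₀−w)/k))`, normalised so
  `R(τ₀) = F` = myocardial blood flow (ml/min/g); myocardial perfusion
  reserve `MPR = stress flow / rest flow`.
* **Classification & statistics** — echo-based grouping (EF < 65% → HFrEF;
  ≥ 2 of 3 diastolic criteria → HFpEF), one-way ANOVA, age-adjusted ANCOVA
  and partial correlation, empirical ROC with Youden cutoffs.
* **Simulation** — a digital short-axis phantom (blood pool + myocardial
  annulus with ground-truth T1/flow per label) and a cohort generator at
  the reference group means/SDs, so every stage is testable without animal
  data.

Everything is tidyverse-native where the data are tabular: cohorts and
statistics flow as tibbles, fitted objects have `tidy()`/`glance()`
methods, result types have `autoplot()` methods. Image maps are
matrix-backed `cmr_map` objects with NIfTI I/O.

## Worked example

Simulate a phantom at the HFpEF fibrosis level, map T1 and ECV, quantify
stress perfusion, and analyse a simulated cohort:

```r
library(cmrquant)

ph <- make_phantom(
  phantom_spec(image_size = c(48L, 48L), blood_radius = 6,
               myo_inner_radius = 9, myo_outer_radius = 14),
  tissue_truth_from_ecv(0.2706, hct = 0.51))

pre  <- simulate_molli_series(ph$t1_pre,  molli_scheme("5(3)3"),
                              noise_sd = 1/30, seed = 1)
post <- simulate_molli_series(ph$t1_post, molli_scheme("4(1)3(1)2"),
                              noise_sd = 1/30, seed = 2)
mask    <- ph$myo_mask | ph$blood_mask
t1_pre  <- compute_t1_map(pre$stack,  pre$tis,  mask)
t1_post <- compute_t1_map(post$stack, post$tis, mask)

ecv <- compute_ecv_map(t1_pre, t1_post,
  blood_roi_pre_mean  = roi_mean(t1_pre,  ph$blood_mask),
  blood_roi_post_mean = roi_mean(t1_post, ph$blood_mask),
  hct = 0.51, myo_mask = ph$myo_mask)
ecv
#> <cmr_map: ecv [fraction]> 48 x 48 pixels, 360 in mask, 360 valid
#>   valid-pixel range: 0.2172 .. 0.3053 (mean 0.2695)
100 * roi_mean(ecv)   # global ECV 26.95% vs ground truth 27.06%

aif_high <- scale_dual_bolus_aif(simulate_aif(),
                                 dose_low = 0.01, dose_high = 0.09)
fit <- fermi_deconvolve(aif_high, simulate_tissue_curve(aif_high, 2.40))
fit
#> <fermi_fit> MBF = 2.400 ml/min/g (tau0 1.01 s, w 3.99 s, k 1.00 s, rss 6.25e-14)
compute_mpr(1.31, fit$mbf)
#> [1] 1.83

cohort <- classify_cohort(generate_cohort(default_cohort_specs(n = 10),
                                          seed = 7))
report <- run_cohort_analysis(cohort)
glance(report$roc$hf_vs_healthy)
#> # A tibble: 1 × 7
#>     auc cutoff sensitivity specificity youden_j n_pos n_neg
#>   <dbl>  <dbl>       <dbl>       <dbl>    <dbl> <int> <int>
#> 1   0.9   26.5         0.8           1      0.8    20    10
```

The ECV map recovers the prescribed fibrosis level within the noise of an
SNR-30 acquisition; the noise-free deconvolution recovers the stress flow
of 2.40 ml/min/g exactly, giving the healthy-level MPR of 1.83; and in the
simulated cohort, ECV separates heart-failure-like from healthy animals
with AUC 0.90 at a Youden cutoff of 26.5%.

`run_pipeline(default_pipeline_config(out_dir = "run1", seed = 1))` chains
all stages (phantoms for all three groups → T1 → ECV → perfusion → MPR →
cohort statistics) and writes NIfTI maps, CSV/JSON reports, and a manifest
with per-file checksums; it completes in a couple of minutes on one CPU.

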