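---
title: "Quantitative CMR in a primate heart-failure model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CMR in a primate heart-failure model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrquant)
```

cmrquant implements the quantitative imaging pipeline used to characterise a
cynomolgus macaque heart-failure model by cardiovascular magnetic resonance:
MOLLI T1 mapping with Look-Locker correction, extracellular volume (ECV)
mapping, dual-bolus first-pass perfusion quantification by Fermi-constrained
deconvolution with myocardial perfusion reserve (MPR), echocardiographic
group classification, and the cohort statistics (ANOVA, age-adjusted
ANCOVA/partial correlation, ROC with Youden cutoff). Because the animal
images themselves are not publicly available, the package ships a digital
phantom and cohort simulator that generates every input the pipeline needs;
all accuracy claims below are made against that simulator's known ground
truth.

## T1 mapping

A MOLLI acquisition samples the inversion recovery over consecutive
heartbeats: the scheme "5(3)3" acquires 5 images after a first inversion,
waits 3 recovery beats, then acquires 3 more after a second inversion.
Within inversion group $g$, image $k$ is read at
$TI = TI_{\min,g} + k \cdot RR$. The defaults follow the protocol the
package emulates: 5(3)3 pre-contrast and 4(1)3(1)2 post-contrast at
$RR = 400$ ms (heart rate near 150 bpm, typical of cynomolgus monkeys). The
vendor TI minima are not published, so the package defaults to 100 ms for
the first group, staggered by 80 ms per later group so effective TIs
interleave; they are configurable.

Each pixel's magnitude signal follows the three-parameter apparent recovery

$$S(TI) = |A - B e^{-TI/T1^*}|,$$

and the Look-Locker correction converts the apparent constant to true T1,
$T1 = T1^*(B/A - 1)$. The simulator inverts exactly this algebra: it fixes
$A = 1$, $B/A = 2$ (ideal inversion, configurable) and sets
$T1^* = T1/(B/A-1)$, so a noise-free simulation/fit round trip is exact by
construction — that round trip is what the T1 tests verify, to 0.1%.
Noise is additive Gaussian on the signed signal *before* the magnitude
operation, so SNR can be stated simply as $A/\sigma$.

**Fitting.** Magnitude data lose the sign of the early inverted samples, so
the fitter performs polarity restoration: for every candidate split
$k = 0..n-1$ it negates the $k$ earliest-TI samples and fits the signed
model, keeping the minimum-RSS candidate. For fixed $T1^*$ the signed model
is linear in $(A, B)$, so the fit uses variable projection — a closed-form
linear solve for $(A, B)$ plus a one-dimensional search over $T1^*$
(48-point log grid on [50, 5000] ms, then bounded refinement). Compared to a
generic bounded nonlinear least-squares iteration this is deterministic,
has no convergence failures, and is fast enough to run per pixel. Fits with
$B/A \le 1$, non-positive $A$, or $T1^*$ on a search bound are flagged
invalid and excluded from ROI means (never an error: a constant signal is a
data property, not a usage bug).

## ECV mapping

With $R_1 = 1/T1$, the extracellular volume fraction is

$$\mathrm{ECV} = (1 - \mathrm{Hct})\,
  \frac{\Delta R_{1,\mathrm{myo}}}{\Delta R_{1,\mathrm{blood}}},$$

computed pixel-wise over the myocardial mask with a single blood
$\Delta R_1$ taken from blood-pool ROI means (pixel-wise blood values are
avoided because of flow artifacts). ECV is carried as a fraction internally
and rendered as percent in reports; hematocrit above 1 in a CSV is
interpreted as percent and converted, since cohort tables conventionally
print Hct in percent. Pixels with ECV outside $[0, 1]$ or a non-positive
$\Delta R_1$ are flagged and excluded, not clipped — clipping would hide
exactly the pixels a reader should inspect. Post-contrast timing dependence
is not modelled; the 15–20 min acquisition is treated as equilibrium.

## Perfusion quantification

Tissue concentration is modelled as the causal convolution of the arterial
input function (AIF) with a Fermi-shaped impulse response

$$R(t) = F\,\frac{1 + e^{-w/k}}{1 + e^{(t - \tau_0 - w)/k}}
  \quad (t \ge \tau_0;\ 0\ \text{before}),$$

normalised so that $R(\tau_0) = F$ exactly. In residue-function theory the
initial amplitude of the impulse response equals myocardial blood flow, so
this normalisation both ties the amplitude to flow and removes the
amplitude degeneracy among $F$, $w$, $k$ at $t = \tau_0$. $F$ is carried in
1/s internally and reported as ml/min/g via the factor 60, assuming
density-normalised relative-enhancement concentration.

**Dual bolus.** The AIF is measured from a small bolus (0.01 mmol/kg),
where blood signal remains linear in concentration, and multiplied by the
dose ratio (9 for the 0.01/0.09 mmol/kg pair) to represent the input of the
large tissue bolus. Signal is converted to concentration by relative
enhancement $C = (S - S_0)/S_0$ over the leading baseline frames; the
linearity of that conversion is the premise of the dual-bolus design rather
than an extra assumption. The identity "analysis with the scaled low-dose
AIF equals analysis with the true high-dose AIF" is verified to 1% in the
tests.

**Fitting.** The model is linear in $F$, so the deconvolution profiles the
amplitude out (closed-form least-squares given the shape) and searches only
$(\tau_0, w, k)$ by Nelder–Mead with a box penalty
($\tau_0 \in [0,10]$ s, $w \in [0,30]$ s, $k \in [0.05,10]$ s,
$F \in [0, 10]$ ml/min/g), multi-started around a delay estimate from
bolus-onset detection (first crossing of 10% of peak on each smoothed
curve) with a cross-correlation lag as fallback. Two design points matter
for accuracy:

* *First-pass restriction.* The fit uses frames up to 8 s past the smoothed
  tissue peak (configurable). Past the first pass, plateau width and decay
  sharpness trade off against the amplitude under noise; restricting the
  window pins the amplitude to the upslope and peak, which is where flow
  information lives. In simulation this single choice moves the median flow
  error at SNR 20 from roughly 20–30% (full 70-frame window) to under 10%.
* *Local minima.* The onset kink at $\tau_0$ makes the cost surface kinked
  and multi-modal in the delay; the onset-based multi-start reliably lands
  in the correct basin where a single cross-correlation start does not.

Noise-free round trips recover flows in 0.5–3 ml/min/g to well under 1%;
at SNR 20 (tissue-peak over noise SD) the median relative error over 200
replicates stays under 10%. The frame interval defaults to 0.4 s — one
frame per heartbeat at 150 bpm, 70 frames per series. The simulated AIF is
a gamma-variate $C(t) = A(t-t_0)^\alpha e^{-(t-t_0)/\beta}$ with
$\alpha = 2.5$, $\beta = 1.5$ s — a first-pass bolus of realistic width for
a small primate at this heart rate; its peak time $t_0 + \alpha\beta$ and
closed-form area $A\beta^{\alpha+1}\Gamma(\alpha+1)$ anchor the simulator
tests.

MPR is the per-subject (or per-pixel) ratio of stress to rest flow. The
published group tables do not state whether MPR was averaged as a ratio of
means or a mean of ratios; the package computes the mean of per-subject
ratios. Dobutamine pharmacology is not simulated — stress is represented
simply as a higher ground-truth flow, and the published heart-rate target
(at least 25% above resting) only parameterises the cohort simulator.

## Group classification

Monkey-specific echocardiographic criteria assign the groups: ejection
fraction below 65% gives HFrEF outright. Otherwise at least two of three
diastolic-dysfunction criteria give HFpEF: (1) E′/A′ or E/A outside
[0.8, 3]; (2) septal E′ < 7 cm/s; (3) E/E′ > 10. The three published
group-mean echo profiles classify to their own groups under these rules,
which the tests assert exactly.

## Cohort simulator

The generator draws every variable independently as Gaussian(mean, SD)
within group, using the published group-level means and SDs (n = 10 per
group) as defaults: age, hematocrit, ECV, rest/stress perfusion and the
echo indices; MPR is derived per subject; perfusion is absent in HFrEF
(the stress exam is not performed there for safety). Only marginal
mean ± SD are published, so no covariance structure is imposed beyond an
optional linear age–ECV coupling (`age_ecv_slope`) included to exercise the
age-adjusted analyses. Non-physical Gaussian tails are clipped (Hct to
(0,1), EF to (0,100), positive quantities to a small floor). What the
simulator deliberately does not emulate: measurement error correlated
across variables, non-Gaussian biology, k-space/MRI physics (banding,
motion, off-resonance), or contrast-agent saturation — so passing tests
demonstrate correctness of the analysis chain under the stated model, not
robustness to every artifact of real data.

## Statistics

Group comparisons use classical one-way ANOVA (the named method of the
analysis this package reproduces; Welch's correction is available behind a
flag). Age adjustment fits `value ~ age + group` and tests the group effect
by the extra-sum-of-squares F test (Type II — with a single covariate this
is the unambiguous choice), reporting adjusted group means at the
grand-mean age. How the reference analysis computed its printed
age-adjusted values is not stated, so exact reproduction of those numbers
is not claimed. Partial correlation regresses both variables on the
covariate and correlates the residuals (t test on n − 3 df).

ROC analysis is empirical: AUC by the midrank (Mann–Whitney) convention so
ties count one half, the Youden cutoff maximises J = sensitivity +
specificity − 1 with ties broken toward the lowest cutoff for deterministic
output, and orientation is fixed (higher score = diseased, as for ECV); an
AUC below 0.5 produces a note rather than a silent flip. For two Gaussian
classes the replicate-mean empirical AUC converges to
$\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2})$, which the tests use as the
analytic limit. P-values are raw and two-sided throughout; no multiplicity
correction is applied (matching the reference analysis), and the report
counts the tests it ran.

## Numerical and engineering choices

* All stochastic operations take a `seed` and are bit-reproducible;
  the pipeline derives per-stage seeds from one master seed and records
  them in the run manifest alongside md5 checksums of every output.
* Problem sizes in the test suite are chosen for fast, stable runs: 32 × 32
  phantoms (myocardial annulus of ~200 pixels), 200 noisy-replicate
  deconvolutions, 1000 replicate cohorts for the stochastic statistics,
  and a 28 × 28 end-to-end pipeline. Accuracy targets do not depend on
  these sizes; they only set Monte-Carlo resolution.
* Maps are written as float32 NIfTI with pixel spacing in the header and
  units in a JSON sidecar (T1 in ms, ECV as a fraction — percent only in
  CSV reports, perfusion in ml/min/g); cohorts as UTF-8 comma CSV with
  header and '.' decimal. DICOM input is not supported (no R DICOM reader
  in the package's dependency set); NIfTI + sidecar is the interchange
  format.

## Known limitations

* The Fermi parameterisation of the original custom software is not
  published; the convention here ($R(\tau_0) = F$, first-pass window) is
  stated above and validated against the package's own simulator, not
  against the original implementation.
* Simulated cohort statistics reproduce published group-level results only
  in distribution (the real cohort is one draw of n = 10 per group).
* No motion correction, no inversion-efficiency calibration beyond the
  B/A formulation, no shMOLLI/SASHA variants, no model-independent
  deconvolution, no segmental (AHA) analysis, no GLS.
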