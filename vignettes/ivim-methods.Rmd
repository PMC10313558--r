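---
title: "IVIM signal models, fitting, and the prognostic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVIM signal models, fitting, and the prognostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimprog)
```

## Background and scope

Intravoxel incoherent motion (IVIM) diffusion-weighted MRI separates two
sources of signal attenuation inside a voxel: thermal diffusion of tissue
water and "pseudo-diffusion" — blood moving through randomly oriented
capillary segments, which dephases like very fast diffusion at low
diffusion weightings. In head-and-neck oncology, pre-treatment IVIM
parameters of the primary tumor have been studied as predictors of
chemoradiotherapy outcome: the working hypothesis is that poorly perfused
tumors respond worse, so perfusion-sensitive parameters carry prognostic
information that the plain apparent diffusion coefficient blurs.

`ivimprog` implements that analysis chain as a reusable, testable
pipeline: the three signal models and their fitting procedures, per-voxel
parameter maps, circular-ROI extraction, and the downstream prognostic
statistics (group comparison, ROC cut-offs, Kaplan–Meier, forward Cox).
Because patient images for this kind of study are generally not shared,
the package also ships the synthetic counterparts needed to exercise the
chain end to end: digital DWI phantoms with known ground truth and Rician
noise, and simulated two-group cohorts whose parameter distributions and
survival structure follow published group summaries.

## Signal models

With $S_b$ the signal at diffusion weighting $b$ (s/mm²) and $S_0$ the
unweighted signal, the three models are

* mono-exponential: $S_b/S_0 = \exp(-b\,\mathrm{ADC})$;
* bi-exponential (IVIM):
  $S_b/S_0 = (1-f)\exp(-bD) + f\exp\{-b(D^*+D)\}$, with true diffusion
  coefficient $D$, pseudo-diffusion coefficient $D^*$ and perfusion
  fraction $f$;
* stretched-exponential:
  $S_b/S_0 = \exp\{-(b\,\mathrm{DDC})^\alpha\}$, with distributed
  diffusion coefficient DDC and heterogeneity index
  $\alpha \in (0, 1]$ ($\alpha = 1$ is mono-exponential decay).

Two conventions deserve a note. First, the fast-compartment exponent is
written $-b(D^*+D)$, exactly as in the source model; part of the IVIM
literature uses $-bD^*$ instead, and the two parameterizations give
different $D^*$ for the same curve. Second, all diffusivities are carried
internally in mm²/s; only the reporting layer (CSV exporters, cohort
tables) multiplies by $10^3$ to the conventional $10^{-3}$ mm²/s scale.
Keeping a single internal unit makes every $b \cdot D$ product
dimensionless and removes a classic source of silent errors.

The default acquisition protocol has 12 b-values (0, 10, 20, 30, 50, 70,
100, 150, 200, 400, 800, 1000 s/mm²) with 2 signal averages (NEX) up to
b = 200 and 3 from b = 400, mirroring a clinical head-and-neck EPI
protocol; the NEX vector matters only for the noise model (channel SD
scales as $1/\sqrt{\mathrm{NEX}}$).

## Fitting

All fits act on the normalized signal $s/s_0$, so the baseline intensity
is never a free parameter, and the model curve passes exactly through 1
at $b = 0$.

* **ADC** comes from ordinary least squares of $\ln(s/s_0)$ on $b$ over
  all b-values (negated slope, clamped at zero). Unweighted log-linear
  OLS matches common vendor behavior; weighting schemes are out of scope.
* **Segmented bi-exponential** (the default IVIM estimator): above
  b = 200 s/mm² the pseudo-diffusion term has decayed to numerical
  irrelevance whenever $D^* \gg D$ — for $D^* \ge 20 \times 10^{-3}$
  mm²/s its contribution to $s/s_0$ at b = 400 is below $10^{-4}$ — so
  step 1 estimates $D$ by log-linear OLS on the b > 200 subset (the free
  intercept absorbs $1-f$), and step 2 fixes $D$ and fits $(f, D^*)$ by
  bounded Levenberg–Marquardt over all b-values, initialized at
  $f_0 = 1 - e^{\mathrm{intercept}}$ (clipped to [0.01, 0.99]) and
  $D^*_0 = 10 D$.
* **Simultaneous bi-exponential** fits $(D, D^*, f)$ jointly, initialized
  from the segmented fit, with $D^*$ parameterized as $D + \delta$,
  $\delta \ge 0$, so the constraint $D^* \ge D$ is honored by box bounds.
  It exists as a cross-check; which variant vendor workstations use is
  generally undocumented, so both are provided with the segmented fit as
  the default.
* **Stretched-exponential** fits $(\mathrm{DDC}, \alpha)$ by bounded
  Levenberg–Marquardt over the b > 0 points, initialized at the
  mono-exponential ADC and $\alpha_0 = 0.8$.

Box bounds (in $10^{-3}$ mm²/s where applicable): $D \in (0.01, 3]$,
$D^* \in [D, 500]$, $f \in [0, 1]$, $\mathrm{DDC} \in (0.001, 5]$,
$\alpha \in (0.1, 1]$. These bracket every reported head-and-neck tumor
value with wide margins; they are constraints against pathological
noise-driven excursions, not priors. Non-convergence triggers exactly one
deterministic restart (the second start parameter scaled by 1.5) before
the fit is flagged unusable; there is no randomness anywhere in fitting,
so maps are bit-reproducible. The residual sum of squares is always
reported on the normalized-signal scale and never exceeds its value at
the initialization point (a property the test suite asserts).

On noiseless in-model curves all fitters recover their generating
parameters to well below 1% relative error, including the two published
worked cases used as fixtures ($D = 0.673$, $D^* = 67.5$, $f = 26.6\%$
and $D = 1.01$, $D^* = 29.6$, $f = 48.3\%$, with the matching
stretched-exponential pairs). $D^*$ is the ill-conditioned IVIM
parameter: under Rician noise at SNR 50 its coefficient of variation
exceeds those of $D$ and $f$, which the tests verify rather than assume.

## ROI analysis

The region of interest is a fixed circle of 25–50 mm² placed on one slice
(the largest solid-tumor slice in the clinical workflow), with in-plane
pixel spacing defaulting to 1.625 mm (260 mm field of view, 160 matrix).
Digitization is area-preserving: the ROI consists of the
$\lceil \pi r^2 / a_{\mathrm{voxel}} \rceil$ voxel centers closest to the
ROI center, with a deterministic tie-break. A plain
"center-within-radius" rule jumps in whole symmetry rings (9, 13, 21
voxels across the 25–50 mm² range when centered on a voxel), which both
overshoots the area window and makes summaries discontinuous in the
radius; the nearest-center rule selects essentially the same disc while
keeping the digitized area within one voxel of the requested circle.

Per lesion the package reports the ADC mean, maximum, minimum and range
(maximum minus minimum) over non-missing ROI voxels of the ADC map, and
ROI means of the bi-exponential and stretched parameters. The published
abstract of the source study defines the ADC range as maximum − mean
while its methods define maximum − minimum, and the printed per-case
values satisfy neither; the methods definition is implemented, and the
discrepancy is deliberately left documented rather than resolved.
Measurements are taken in triplicate and averaged field-wise
(`average_triplicate()`), which for arithmetic means preserves
range = max − min exactly. As an alternative to map summaries, the
ROI-averaged signal curve can be fitted directly (`roi_mean_signal()`
then any fitter), emulating per-ROI signal integration; averaging $n$
voxels reduces the noise SD by $\sqrt{n}$, which the tests check against
Monte-Carlo draws.

## Synthetic data

**Phantoms.** `make_phantom()` builds a 4-D stack voxel-wise from one
forward model: a uniform background and a circular lesion with their own
parameter sets, plus stored ground-truth maps and the lesion mask.
`add_rician_noise()` replaces each intensity $s$ by
$\sqrt{(s+g_1)^2 + g_2^2}$ with $g_1, g_2$ zero-mean Gaussians of SD
$\sigma/\sqrt{\mathrm{NEX}_b}$ — the magnitude-image noise model of MRI.
At zero signal this is a Rayleigh distribution with mean
$\sigma_\mathrm{eff}\sqrt{\pi/2}$ (the noise floor), and the magnitude
bias makes noisy means sit above noiseless means at every b; both
properties are asserted by the tests. The phantoms emulate parameter
contrast and noise only: no partial volume, motion, susceptibility
distortion or spatial texture, so passing tests demonstrate estimator
correctness, not robustness to real-world artifacts.

**Cohorts.** `simulate_cohort()` draws the nine per-patient IVIM
parameters per group from truncated normal distributions (diffusivities
> 0, perfusion fraction in (1, 99)%, $\alpha \in (0.1, 1]$), with the
published group means and SDs of the treatment-failure (n = 31) and
local-control (n = 14) groups as defaults. Truncation shifts moments, so
the generator solves for the parent $(\mu, \sigma)$ such that the
post-truncation mean equals the target exactly (the truncated mean is
strictly increasing in $\mu$, giving a unique root at every $\sigma$) and
the SD is as close as the family permits. Several printed rows are
mathematically unreachable for any truncated normal on the stated
support — a distribution truncated at zero cannot have SD/mean above 1
(the limit is an exponential-like tail), yet e.g. the DDC rows print
SD/mean near 9–17 — so for those rows the mean is exact and the SD is the
closest attainable; the test suite checks SDs only where the target is
achievable. Parameters are drawn independently across the nine measures
(only marginal summaries are published); per-patient orderings such as
ADCmin ≤ ADCmean ≤ ADCmax are therefore not enforced.

Failure-group event times are log-normal — positive, right-skewed, and
able to match a mean (13.97 months) close to its SD (12.31 months) —
calibrated so that the *administratively censored* observation
min(T, 60) has exactly the target mean and SD (censored moments in
closed form, two-parameter solve); calibrating the raw distribution
instead would leave the realized censored mean biased low. Weibull and
exponential families are selectable. Control patients are censored at 60
months with no events. N stage is drawn per group from the published
stage frequencies so the ordinal-statistics branch is exercised.
`inject_effect()` overwrites the survival outcome with an exponential
proportional-hazards model $h = h_0 \cdot \mathrm{HR}^z$ at a known
hazard ratio, creating ground truth for calibration and coverage tests of
the Cox stage. One master seed drives everything through deterministic
per-stage child seeds; identical specs give bit-identical outputs.

## Prognostic statistics

* `compare_groups()`: continuous variables use Student's t-test when both
  groups pass Shapiro–Wilk at $\alpha = 0.05$, otherwise the Mann–Whitney
  U test (the screen rule is a package choice; published methods sections
  typically state only the test menu). Binary categoricals use chi-square
  without continuity correction; ordered categoricals (N stage, UICC
  stage) use the rank-sum test on ordinal codes. If both groups are
  constant the comparison degenerates to an exact equality check.
* `roc_analysis()`: empirical ROC with the AUC computed through the
  Mann–Whitney U identity (ties count one half), oriented so AUC ≥ 0.5
  with the risk direction recorded; the cut-off maximizes Youden's J over
  observed values, the cut-off value itself assigned to the higher-risk
  side, ties resolved toward higher sensitivity then the smaller
  cut-off. Treatment failure is the positive class.
* `km_logrank()`: product-limit curves for the "< cut-off" versus
  "≥ cut-off" strata (the dichotomization convention of the source
  tables) and the two-sided log-rank test; the median survival is
  reported as undefined when a curve never reaches 0.5, as happens for
  fully censored control strata.
* `cox_forward()`: candidates are screened univariately at p < 0.1 — by
  default the log-rank test at the marker's ROC cut-off, matching a
  Kaplan–Meier-then-Cox workflow; univariate Cox screening is available
  by flag — then entered by forward steps on the smallest Wald p below
  0.05 (both thresholds configurable), with Efron tie handling and a
  recorded selection trace. Continuous covariates enter on their reported
  scale, so hazard ratios read "per $10^{-3}$ mm²/s" (a hazard ratio of
  1.008 per unit $D^*$ is a realistic magnitude on that scale). With a
  single null candidate the selection rate calibrates to the nominal 5%
  level — a property the suite checks over 1000 simulated cohorts using
  the Cox screen, since the screen and entry test must coincide for the
  nominal level to apply. All tests are two-sided and no multiplicity
  correction is applied anywhere, matching the analysis style being
  reproduced.

## Numerical and design notes

* Truncated-normal sampling uses inverse-CDF on upper-tail
  log-probabilities with reflection, so draws stay finite and unbiased
  even when the best-effort parent sits thousands of SDs from the
  support; bounded-support moments are computed on a 2001-point grid of
  re-centered log-weights, immune to tail underflow.
* Degenerate voxels (any non-positive intensity) raise a classed
  condition in scalar fits and become missing values counted by the
  volumetric driver's fit-quality report.
* The full test suite runs in well under a minute on one core; the heavy
  Monte-Carlo blocks (1000-cohort null calibration, 200-replicate
  coverage at 1000–2000 patients, $10^5$-draw noise-floor and
  moment-matching checks, $10^4$-per-group generator fidelity) were sized
  to keep Monte-Carlo error far below the tolerances they assert.
* Known limitations: no DICOM ingestion, no registration or motion/eddy
  correction, no kurtosis or tri-exponential models, no relaxation
  correction of $f$, no spatial regularization of maps, no bootstrap CIs
  for the AUC, no competing risks. Patient-level published results
  (specific AUCs, sensitivities, hazard ratios) depend on the original
  images and follow-up and are represented here only by structural
  analogues with known synthetic truth.
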