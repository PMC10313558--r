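# ivimprog

Intravoxel incoherent motion (IVIM) diffusion-weighted MRI models and the
prognostic survival pipeline built on them, for head-and-neck
(laryngeal/hypopharyngeal) tumor imaging studies.

IVIM imaging acquires diffusion-weighted volumes over a range of b-values
and decomposes the per-voxel signal decay into tissue diffusion and
capillary "pseudo-diffusion". `ivimprog` implements the three standard
signal models and everything needed to take them from raw 4-D stacks to
survival statistics:

* **Signal models** — mono-exponential
  `S_b/S_0 = exp(-b·ADC)`, bi-exponential (IVIM)
  `S_b/S_0 = (1-f)·exp(-bD) + f·exp(-b(D*+D))`, and stretched-exponential
  `S_b/S_0 = exp(-(b·DDC)^α)`, over a 12-b-value protocol
  (0–1000 s/mm², NEX 2/3).
* **Fitting** — log-linear ADC fit; segmented IVIM fit (D from the
  b > 200 s/mm² subset where pseudo-diffusion is negligible, then (f, D*)
  by bounded Levenberg–Marquardt with D fixed); simultaneous bounded
  bi-exponential fit as a cross-check; bounded stretched-exponential fit;
  a per-voxel driver producing NIfTI parameter maps with a fit-quality
  report.
* **ROI analysis** — fixed 25–50 mm² circular ROIs with area-preserving
  digitization, ROI-mean signal curves, ADC mean/max/min/range and
  model-parameter summaries, triplicate averaging, CSV export.
* **Synthetic data** — digital DWI phantoms with known ground truth and
  Rician noise (NEX-scaled, with the correct Rayleigh noise floor), and
  simulated failure/control patient cohorts whose IVIM parameter
  distributions are moment-matched truncated normals and whose
  progression-free survival has log-normal event times under
  administrative censoring at 60 months.
* **Prognostic statistics** — group comparisons (t / Mann–Whitney /
  chi-square / rank-sum with a normality screen), ROC analysis with
  Youden-optimal cut-offs, Kaplan–Meier curves with log-rank tests at
  those cut-offs, and forward-stepwise Cox proportional-hazards
  regression with univariate screening at p < 0.1.

The methods vignette (`vignettes/ivim-methods.Rmd`) documents the models,
parameter bounds, digitization and calibration choices, and limitations.

## Worked example

Fit a noiseless bi-exponential curve generated from a published worked
case (D = 0.673 × 10⁻³ mm²/s, D* = 67.5 × 10⁻³ mm²/s, f = 26.6%):

```r
library(ivimprog)

protocol <- default_protocol()
truth <- biexp_params(d = 0.673e-3, d_star = 67.5e-3, f = 0.266)
curve <- biexp_signal(truth, protocol, s0 = 1000)
fit_biexp_segmented(curve)
#> IVIM fit (biexp_segmented)
#>   d = 0.000673
#>   d_star = 0.0675
#>   f = 0.266
#>   rss = 2.677e-25 on 12 points
```

The segmented fit recovers all three generating parameters to machine
precision (diffusivities are in mm²/s internally; exporters report
10⁻³ mm²/s). The same works voxel-wise on a noisy digital phantom:

```r
spec <- phantom_spec(dim = c(32, 32, 3), model = "biexp",
                     lesion = truth, lesion_center = c(15, 15, 1),
                     lesion_radius = 3.3, s0 = 1000, noise_sigma = 20,
                     seed = 7)
ph <- make_phantom(spec, protocol)
maps <- fit_volume(ph$dwi, protocol, model = "biexp", mask = ph$mask)
summarize_roi(maps, circular_roi(c(15, 15, 1), radius = 3.3))
#> ROI summary over 13 voxels
#>  adc_mean   adc_max   adc_min adc_range         d    d_star         f
#>        NA        NA        NA        NA  0.000655  0.066232  0.271247
```

At SNR 50 the ROI means sit within a few percent of the generating
values, with D* the noisiest parameter — the known ill-conditioned one.
Simulated cohorts feed the full statistics stage:

```r
cohort <- simulate_cohort(cohort_spec(seed = 1))   # 31 failure / 14 control
res <- prognosis_tables(cohort)
res$roc[res$roc$parameter %in% c("ADCmean", "Dstar"), ]
#>   parameter   auc  p_value cutoff sensitivity specificity orientation
#> 1   ADCmean 0.811 9.75e-04   1.08        64.5        92.9       below
#> 6     Dstar 0.878 6.11e-05  47.89        77.4        92.9       above
```

Lower ADCmean and higher D* mark the treatment-failure group, so the ROC
orientation differs per marker; each marker is then dichotomized at its
cut-off for Kaplan–Meier/log-rank, and the significant ones enter the
forward Cox selection (`res$cox`).

A thin command-line front end over the same functions lives at
`inst/cli/ivim_pipeline.R` with subcommands `simulate-phantom`,
`simulate-cohort`, `fit` and `prognosis`, driven by a YAML configuration
(see `run_config()`).

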