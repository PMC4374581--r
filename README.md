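# mmresponse

Quantifying early tumour response to head-and-neck (chemo)radiotherapy from
serial multi-modality imaging — and validating every step of that analysis
against synthetic phantom cohorts with known ground truth.

Small serial-imaging cohorts (eight patients scanned at baseline and after
fractions 11 and 21 of a radiotherapy course) are analyzed with a mix of
anatomic and functional readouts:

* **Gross tumour volumes** (GTV-CT / GTV-MR / GTV-DW / GTV-PET) in cm³ from
  ROI masks;
* **FDG-PET**: SUVmax and a metabolic tumour volume segmented at the
  contrast-oriented adaptive threshold `T = a·mSUV70 + b·BG`, where mSUV70
  is the mean SUV within the 70%-of-SUVmax isocontour, BG the background
  mean, and (a, b) scanner coefficients calibrated from phantoms;
* **DW-MRI**: voxelwise apparent diffusion coefficient maps from the
  mono-exponential decay `S(b) = S0·exp(−b·ADC)` (OLS on log-signal,
  b = 0/400/800 s/mm²) and the ROI mean ADC;
* **DCE-MRI**: baseline-subtracted concentration curves, an arterial input
  function from the single brightest artery voxel on the maximal-enhancement
  map, model-free plasma-flow maps by truncated-SVD deconvolution, and a
  two-compartment exchange model (2CXM) fit of the mean tumour curve:

      vp·dCp/dt = Fp·(Ca − Cp) + PS·(Ce − Cp)
      ve·dCe/dt = PS·(Cp − Ce),      Ct = vp·Cp + ve·Ce

  yielding PF, PV, νe, PS and the derived EF = 100·PS/(PS+PF) and
  Ktrans = (PS·PF/(PS+PF))/100 min⁻¹;
* **Cohort statistics**: per-patient percentage changes between timepoints,
  the **exact** one-sample Wilcoxon signed-rank test (full enumeration of
  all 2ⁿ sign assignments — a same-signed cohort of n = 8 gives exactly
  p = 2/2⁸ = 0.0078125), and a Pearson correlation screen over all 66
  pairs of parameter changes.

Because clinical images for such cohorts are not generally shareable, the
package includes a first-class synthetic cohort generator
(`cohort_config()`, `generate_cohort()`): seeded ellipsoidal tumour
phantoms whose volumes shrink and whose functional parameters move by
configurable cohort-median effects with per-patient jitter, rendered as
PET / DWI / DCE NIfTI volumes with ground-truth masks. Every analysis stage
is validated by recovering that ground truth.

## Worked example

An exact small-sample test — eight same-signed percentage changes:

```r
library(mmresponse)
signed_rank_exact(c(-24, -31, -53, -20, -26, -78, -6, -82))
#> Exact one-sample signed-rank test: W = 0, n = 8, p = 0.0078125
```

Fit the 2CXM to a noisy synthetic tissue curve and read the result the
broom way:

```r
set.seed(7)
times <- (0:149) * 2.5                               # 150 frames at 2.5 s
aif   <- generate_aif(times, bolus_time = times[11]) # bolus after 10 frames
ct    <- twocxm_forward(list(PF = 40, PV = 8, ve = 20, PS = 10), aif, times)
fit   <- fit_2cxm(ct + rnorm(150, 0, 0.01), aif, times)
tidy(fit)
#> # A tibble: 6 × 4
#>   term   estimate unit         derived
#>   <chr>     <dbl> <chr>        <lgl>
#> 1 PF      42.2    ml/min/100ml FALSE
#> 2 PV       8.04   ml/100ml     FALSE
#> 3 ve      20.7    ml/100ml     FALSE
#> 4 PS       9.88   ml/min/100ml FALSE
#> 5 EF      19.0    %            TRUE
#> 6 Ktrans   0.0801 1/min        TRUE
deconvolve_pf(ct, aif, times)$PF                     # model-free route
#> [1] 40.58292
```

The estimates sit within a few percent of the generating values
(PF 40, PV 8, ve 20, PS 10), and the model-free deconvolution recovers the
same plasma flow without assuming the model.

Run a small cohort end-to-end (simulate → analyze → summarize):

```r
run <- run_pipeline(cohort_config(seed = 20260921, n_patients = 3,
                                  timepoints = c("baseline", "fx11"),
                                  grid_dim = 32, n_frames = 100))
run$change_summary
#> # A tibble: 12 × 7
#>    parameter interval          n median_pct min_pct max_pct p_value
#>  1 gtv_ct    baseline-fx11     3     -24.6   -27.0   -22.8     0.25
#>  2 gtv_mr    baseline-fx11     3     -30.6   -47.2   -23.4     0.25
#>  5 suvmax    baseline-fx11     3     -21.2   -31.4   -18.9     0.25
#>  6 adc       baseline-fx11     3      31.4    30.8    39.5     0.25
#>  7 pf        baseline-fx11     3      35.4    21.7    41.0     0.25
#>  ...
```

Volumes and SUVmax fall, ADC and plasma flow rise — the on-treatment
response signature — with the exact p bottoming out at 2/2³ = 0.25 for a
3-patient toy cohort (the full 8-patient default reaches 0.0078125).
`plot_parameter_trajectories(run$records)` and
`plot_change_summary(run$change_summary)` draw the standard cohort figures;
`autoplot(fit)` shows an individual kinetic fit.

## Package layout

| Module | Contents |
| --- | --- |
| `R/image_core.R` | `image_volume` / `roi_mask` / `dynamic_series` types, volumes in cm³, NIfTI + CSV I/O |
| `R/phantoms.R` | seeded synthetic cohort generator and ground truth |
| `R/pet_segmentation.R` | SUV statistics, adaptive threshold, connected-component GTV-PET, coefficient calibration |
| `R/dwi_adc.R` | voxelwise ADC mapping and ROI means |
| `R/dce_pk.R` | 2CXM forward model and fit, AIF selection, deconvolution PF |
| `R/cohort_stats.R` | exact signed-rank test, Pearson screen, change summaries |
| `R/pipeline.R` | per-cell analysis and the full simulate→analyze→summarize run |

The methods vignette (`vignettes/multimodality-response.Rmd`) documents the
models, defaults, numerical choices and limitations in detail.
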