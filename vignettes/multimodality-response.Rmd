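---
title: "Methods: multi-modality on-treatment response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modality on-treatment response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mmresponse` quantifies early tumour response to head-and-neck radiotherapy
from serial multi-modality imaging: anatomic gross tumour volumes (GTV) from
CT/MR/DW contours, metabolic volume and SUVmax from FDG-PET, mean apparent
diffusion coefficient (ADC) from diffusion-weighted MRI, and microvascular
parameters from dynamic contrast-enhanced (DCE) MRI. Because clinical images
for such small serial cohorts are rarely shareable, the package pairs every
analysis stage with a seeded synthetic phantom generator whose ground truth
is known exactly, so the whole chain is validated by parameter recovery
rather than by visual plausibility. This vignette records the models, the
tunable parameters, and the design decisions.

## PET: contrast-oriented adaptive threshold

The metabolic tumour volume is segmented at an adaptive threshold

$$T = a \cdot \mathrm{mSUV}_{70} + b \cdot \mathrm{BG},$$

where $\mathrm{mSUV}_{70}$ is the mean SUV of lesion voxels at or above 70%
of SUVmax (computed in a single pass, no iterative re-estimation), BG is the
mean over an explicit background ROI, and $(a, b)$ are scanner-specific
coefficients calibrated from phantom measurements by least squares
(`calibrate_coefficients()`). Published scanner coefficients for this
threshold family are not generally available, so the defaults are
$a = b = 0.5$, always overridable. The thresholded set is restricted to the
26-connected component (faces + edges + corners) containing the SUVmax
voxel; 26-connectivity avoids fragmenting thin necks on desk-scale grids
and is configurable down to 6. If $\mathrm{mSUV}_{70} \le \mathrm{BG}$ the
lesion is not distinguishable from background and segmentation is refused
rather than returning an arbitrary contour — the same failure mode that
makes on-treatment metabolic volumes unreliable clinically as tumour-to-
background contrast collapses.

## DWI: mono-exponential ADC

Signal decays as $S(b) = S_0 e^{-b\,\mathrm{ADC}}$; the ADC map is minus
the slope of an unweighted ordinary least-squares fit of $\log S$ against
$b$ (default $b \in \{0, 400, 800\}$ s/mm²), reported in
$10^{-3}$ mm²/s. Unweighted log-linear OLS matches standard scanner-console
ADC maps; with three b-values and phantom-level SNR, weighted or nonlinear
fitting changes nothing material. Voxels with any non-positive signal
cannot be log-transformed and are flagged invalid; negative fitted ADCs are
retained by default (keeping the estimator unbiased around zero) and can be
excluded from ROI means with `clip_negative = TRUE`. Whether a scanner uses
two or three b-values is acquisition-dependent; both work through
`b_value_set()`.

## DCE: two-compartment exchange model and deconvolution

Tissue concentration is modelled by the two-compartment exchange model
(2CXM): a plasma compartment (volume fraction $v_p = \mathrm{PV}/100$) fed
at plasma flow $F_p = \mathrm{PF}/6000$ s⁻¹ exchanging with an interstitial
compartment ($v_e = \nu_e / 100$) at rate $PS/6000$ s⁻¹:

$$v_p \dot{C}_p = F_p (C_a - C_p) + ps (C_e - C_p), \qquad
  v_e \dot{C}_e = ps (C_p - C_e), \qquad
  C_t = v_p C_p + v_e C_e.$$

Parameters are quoted per minute per 100 ml tissue; the single unit
conversion (×1/60) happens at the model boundary and nowhere else. Two
derived quantities follow: the extraction fraction
$EF = 100\,PS/(PS + PF)$ and the volume transfer constant
$K^{trans} = (PS \cdot PF/(PS + PF))/100$ min⁻¹. When flow dominates
permeability ($PF \gg PS$), $K^{trans} \to PS/100$: uptake is
permeability-limited and percentage changes in $K^{trans}$ track percentage
changes in PS essentially exactly — the package reproduces this regime as a
correlation of 1.000 between the two on flow-dominated synthetic cohorts.
$K^{trans}$ is derived from the fitted PF and PS rather than fitted as a
free parameter; with an $r = 1.000$ coupling to PS in the flow-dominated
regime this is the self-consistent choice, though it is a package decision,
not a claim about any particular scanner software.

**Numerics.** The system is linear and time-invariant, so `twocxm_forward()`
integrates it *exactly* for a piecewise-linear arterial input: the 2×2
system matrix is eigendecomposed analytically and each frame interval is
advanced with the exponential-integrator $\varphi_1/\varphi_2$ functions
(series-guarded below $|z| < 10^{-5}$). The only discretization is the
linear interpolation of the AIF between frames, which is also what an ODE
solver would see; agreement with `deSolve::lsoda` is at solver tolerance.
Degenerate parameter sets reduce to analytic limits instead of dividing by
zero: $PS = 0$ or $v_e = 0$ gives the one-compartment plasma model,
$v_p = 0$ the uptake (Tofts-like) limit, $F_p = 0$ no enhancement.
(Near-)repeated eigenvalues are lifted by a $10^{-6}$ relative nudge of PS.
A second route — the analytic bi-exponential impulse response convolved with
the AIF — is kept as an internal cross-check that both derivations agree.

**Concentrations** are approximated by baseline subtraction (mean of the
first `n_baseline = 10` pre-contrast frames), with no T1 mapping. Artery
and tissue then share one unknown proportionality constant, which cancels
in the kinetic fit, so the fitted parameters are absolute; the test suite
asserts this scale equivariance. The AIF is the single brightest voxel of
the maximal-enhancement map inside the artery ROI, with deterministic
lowest-linear-index tie-breaking. No partial-volume or inflow correction is
applied to the AIF.

**Plasma-flow maps** come from model-free deconvolution: $C_t = A h$ with
$A$ the lower-triangular discrete convolution operator of the AIF, solved
by truncated SVD and $PF = 6000 \max_t h(t)$. The operator uses an exact
piecewise-linear (Volterra) quadrature — both $h$ and $C_a$ treated as
piecewise linear on the frame grid — rather than the rectangle rule, whose
half-frame smearing biases the recovered peak low by ~20% at 2.5 s
sampling. With this operator the relative singular-value cutoff was
calibrated once on the noise-free reference fixture (PF = 40 ml/min/100 ml,
PV = 8, ve = 20, PS = 10, 150 frames at 2.5 s) to `reg = 0.05`, which keeps
noise-free PF recovery within ±8% across the physiologic 25–60 range;
recovery degrades for very fast residue functions (PF ≳ 100) whose decay is
genuinely unresolvable at 2.5 s frames. A single-sample (discrete delta)
AIF is not piecewise linear, so the operator then reduces to the shift
matrix, making the identity case exact. Tikhonov regularization is
available behind the same interface.

**Fitting** is bounded Levenberg–Marquardt least squares (minpack.lm) on
(PF, PV, ve, PS) with bounds [0, 500] / [0, 100]. The cost surface is
multi-modal at coarse temporal sampling, so a 3×3×3×3 start grid
(PF ∈ {10, 40, 120}, PV ∈ {2, 8, 20}, ve ∈ {5, 20, 40}, PS ∈ {1, 10, 40})
is screened by residual sum of squares and the best five starts are refined
fully — screening first makes the 81-start strategy affordable without
changing which optimum wins. The ROI fit uses the mean tumour concentration
curve (one fit per tumour), matching how small-cohort DCE analyses are
reported; voxelwise model fitting is deliberately limited to the
deconvolution PF map. An all-zero curve short-circuits to PF = 0 with a
degeneracy flag.

## Cohort statistics

Percentage change is $100\,(x_2 - x_1)/x_1$ on complete pairs only; a
missing modality reduces n and is never imputed. The location test for
"median percentage change = 0" is the **exact one-sample Wilcoxon
signed-rank test**: zeros dropped, midranks for ties, and the null
distribution of the positive-rank sum enumerated exactly over all $2^n$
sign assignments (via the equivalent generating-function recursion; the
test suite checks it against literal enumeration). Two-sided p doubles the
smaller tail, capped at 1, so a same-signed sample gives exactly
$2/2^n$ — 0.0078125 at n = 8, 0.015625 at n = 7, the values a complete and
a one-short cohort print. A minimum-likelihood two-sided convention is
available behind a flag. The test is named with care: small-cohort imaging
studies sometimes label this comparison a rank-sum test, but a one-sample
null on paired changes is the signed-rank setting, and the printed
$2/2^n$ tail values are only consistent with the exact signed-rank
distribution. Correlations between percentage-change pairs use Pearson's r
with the $t$-distribution p-value on $n - 2$ degrees of freedom
($p = 0$ at $|r| = 1$); the screen tests all 66 unordered pairs of the 12
parameters per interval at $\alpha$ = 0.05 **without** multiplicity
correction, reflecting exploratory practice in small cohorts, with Holm
correction available via `holm = TRUE`.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults encode the study conditions: 8 patients imaged
at baseline, fraction 11 and fraction 21 of radiotherapy, on a 48³ grid of
2 mm isotropic voxels (desk-scale, while leaving well over 100 tumour
voxels at the smallest timepoint), with 150 dynamic frames at 2.5 s and
contrast arriving after 10 pre-contrast frames. Baseline anatomic volumes
are patient-specific (2–33 cm³, median 8.5); other baselines are typical
head-and-neck values (SUVmax 12 over background 2, tumour ADC
0.95×10⁻³ mm²/s under a 1.6 background, PF 45, PV 8, ve 20, PS 10). The
default effect profile moves each driven parameter by the cohort-median
percentage changes that on-treatment head-and-neck imaging shows: anatomic
volumes down 24–53% by fraction 11 and 53–79% by fraction 21, metabolic
volume down ~20% then partially rebounding, SUVmax down 26% then 60%, ADC
up 37% then 48%, PF up 35% then 62%, PV up 36%, ve and PS rising late. Each
patient's effect is jittered multiplicatively (log-normal, σ = 0.25 on the
magnitude, sign-preserving), so the direction of every driven change is
cohort-consistent — which is what makes the exact $2/2^n$ significance
levels attainable at n = 8 — while magnitudes disperse realistically.
Within-cohort dispersion is a configuration choice, not an inferable
quantity, since per-patient parameter values are not published for such
cohorts beyond baseline MR volumes.

The tumour is a centred ellipsoid (axis ratios 1 : 0.85 : 0.7) per
modality; the restricted-diffusion contour is emulated by thresholding the
noise-free b = 800 image at half the lesion–background contrast, keeping
the lesion side of the threshold (as tumour ADC rises the contrast shrinks
and can invert; a reader contours the lesion either way). PET uptake is
uniform at the true SUVmax over a warm background; DWI decays
mono-exponentially voxelwise; DCE tumour voxels share one 2CXM curve and a
designated artery voxel outside the tumour carries the AIF and is, by
construction (asserted at generation time), the global maximum of
enhancement. Noise is Rician on PET and DWI magnitudes (Gaussian fallback
flag) and Gaussian on DCE frames; noise-free phantoms are *exactly*
consistent with the generative equations, which is what the recovery tests
exploit. All randomness is Mersenne-Twister from the mandatory seed, with
per-cell substreams derived arithmetically so any single patient-timepoint
regenerates identically in isolation.

What the phantoms do **not** emulate — and therefore what passing tests do
not show about clinical data: anatomically realistic geometry, spatial
heterogeneity of kinetics within the tumour, partial-volume and
point-spread effects, motion and susceptibility artefacts, EPI geometric
distortion, peri-tumoural inflammation (the mechanism behind paradoxical
on-treatment metabolic volume increases), and inter-observer contouring
variability. Recovery on these phantoms demonstrates the correctness of
the estimators, not the clinical accuracy of the measurements.

## Orchestration and reproducibility

`run_pipeline()` simulates and analyzes every cohort cell in memory and
summarizes the records; with `out_dir` it writes `records.csv`,
`change_summary.csv`, `correlations.csv` and a YAML manifest (seed, RNG
algorithm, configuration echo, package version, MD5 of every file).
Re-running with the manifest's seed reproduces byte-identical CSVs.
`generate_cohort()` writes the full image tree as NIfTI + CSV for use with
`read_patient_timepoint()`; orientation metadata beyond voxel spacing is
ignored throughout, because phantoms live on one axis-aligned grid and
in-core resampling is out of scope. Stage failures (a corrupt file, an
overlapping background ROI, a non-identifiable lesion) downgrade to missing
record fields with a logged cause, and the complete-case statistics
downstream see the reduced n — the same path a cohort takes when one
patient's scan is unusable. The package's interface is R functions
(`cohort_config() |> run_pipeline()` and the per-stage functions above);
there is no shell wrapper, as the functions and this vignette are the
intended entry points.

Problem sizes used by the shipped validation suite (chosen to keep the
default test run fast while preserving the acquisition geometry where it
matters): forward-model and deconvolution checks run at the full 150-frame,
2.5 s acquisition; parameter recovery covers a 3⁴ physiologic grid
noise-free plus 200 noisy replicates at one reference parameter set;
end-to-end cohort checks run the full 8 × 3 default cohort once, and
smaller 2–3-patient, 24³–32³ configurations elsewhere.

## Known limitations

* Deconvolution PF is accurate in the physiologic 25–60 ml/min/100 ml range
  at 2.5 s sampling; very fast residue decays are under-resolved and PF is
  then underestimated — a sampling limit, not a solver artifact.
* ve and PS are the weakest-identified 2CXM pair on a ~6 min acquisition
  when exchange is slow; noise-free recovery is exact, but small fit errors
  under noise can flip the sign of a near-zero ve change.
* The exact signed-rank enumeration is limited to n ≤ 20 (ample for
  small-cohort work; larger samples should use a standard implementation).
* SUVmax measured on noisy phantoms carries the familiar max-statistic
  inflation, which attenuates measured percentage declines slightly
  relative to the configured truth.
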