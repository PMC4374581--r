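# Seeded synthetic phantom cohorts. Each patient-timepoint image set renders
# an ellipsoidal tumour on a 48^3 grid of 2 mm isotropic voxels: uniform FDG
# uptake over a warm background (PET), mono-exponential diffusion decay
# (DWI), and a dynamic contrast series whose tumour voxels follow the 2CXM
# forward model with a designated artery voxel carrying the input function.
# The cohort-level effect profile (how volumes shrink and functional
# parameters move across the baseline / fraction-11 / fraction-21
# timepoints) is the generator's ground truth, against which every analysis
# stage is validated.

#' Default cohort effect profile
#'
#' Median percentage changes of each driven parameter from baseline to the
#' fraction-11 and fraction-21 timepoints: anatomic and metabolic volumes
#' and SUVmax fall, ADC and plasma flow rise, permeability rises late.
#' Values are fractions (e.g. -0.24 is a 24% reduction). EF and Ktrans are
#' not driven; they derive from PF and PS.
#'
#' @return Tibble with columns `parameter`, `fx11`, `fx21`.
#' @export
default_effect_profile <- function() {
  tibble::tribble(
    ~parameter, ~fx11, ~fx21,
    "gtv_ct",  -0.24, -0.53,
    "gtv_mr",  -0.31, -0.70,
    "gtv_dw",  -0.53, -0.79,
    "gtv_pet", -0.20, -0.16,
    "suvmax",  -0.26, -0.60,
    "adc",      0.37,  0.48,
    "pf",       0.35,  0.62,
    "pv",       0.36,  0.31,
    "ve",       0.11,  0.99,
    "ps",       0.12,  2.90)
}

#' Default per-patient baseline values
#'
#' Typical locally-advanced head-and-neck values. The anatomic MR tumour
#' volume is patient-specific (2-33 cm^3, median 8.5); other modality volumes
#' scale from it (CT contours slightly larger, restricted-diffusion and
#' metabolic volumes slightly smaller). Functional baselines: SUVmax 12,
#' tumour ADC 0.95e-3 mm^2/s, PF 45 ml/min/100 ml, PV 8 ml/100 ml,
#' ve 20 ml/100 ml, PS 10 ml/min/100 ml.
#'
#' @return Named list of baseline medians and the per-patient MR volumes.
#' @export
default_baseline_profile <- function() {
  list(gtv_mr_patients = c(3.0, 14.7, 4.0, 32.8, 10.6, 6.4, 16.7, 2.0),
       gtv_ct_ratio = 1.15, gtv_dw_ratio = 0.75, gtv_pet_ratio = 0.90,
       suvmax = 12, adc = 0.95, pf = 45, pv = 8, ve = 20, ps = 10)
}

#' Cohort simulation configuration
#'
#' All tunables of the synthetic cohort in one validated object. Defaults
#' reproduce the study conditions: 8 patients at baseline / fraction 11 /
#' fraction 21, a 48^3 grid of 2 mm voxels, 150 dynamic frames at 2.5 s with
#' contrast arriving after 10 baseline frames, and the effect profile of
#' [default_effect_profile()].
#'
#' @param seed Mandatory integer seed; all randomness derives from it
#'   (Mersenne-Twister).
#' @param n_patients Number of patients (>= 2; default 8).
#' @param timepoints Imaging timepoints (subset of baseline/fx11/fx21).
#' @param grid_dim Grid size per axis (voxels).
#' @param spacing_mm Isotropic voxel size, mm.
#' @param n_frames,frame_dt_s Dynamic series length and frame spacing (s).
#' @param n_baseline Pre-contrast frames before bolus arrival.
#' @param effect_profile Tibble as [default_effect_profile()].
#' @param baseline_profile List as [default_baseline_profile()].
#' @param effect_jitter_sd Log-normal sd of the per-patient multiplicative
#'   jitter on effect magnitudes (sign-preserving; default 0.25).
#' @param baseline_jitter_sd Log-normal sd of per-patient baseline jitter.
#' @param pet_sigma,dwi_sigma,dce_sigma Noise levels: Rician sigma in SUV,
#'   Rician sigma in DWI signal a.u. (b = 0 tumour signal is 100), Gaussian
#'   sigma in DCE signal a.u.
#' @param noise_model `"rician"` (default) for PET/DWI magnitude data, or
#'   `"gaussian"` as a fallback.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_patients = 8,
                          timepoints = c("baseline", "fx11", "fx21"),
                          grid_dim = 48, spacing_mm = 2,
                          n_frames = 150, frame_dt_s = 2.5,
                          n_baseline = 10,
                          effect_profile = default_effect_profile(),
                          baseline_profile = default_baseline_profile(),
                          effect_jitter_sd = 0.25,
                          baseline_jitter_sd = 0.30,
                          pet_sigma = 0.2, dwi_sigma = 1.25,
                          dce_sigma = 0.05,
                          noise_model = c("rician", "gaussian")) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory", call. = FALSE)
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  timepoints <- match.arg(timepoints, TIMEPOINT_LEVELS, several.ok = TRUE)
  if (any(effect_profile$fx11 <= -1) || any(effect_profile$fx21 <= -1))
    stop("effect percentages must exceed -100%", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    timepoints = timepoints, grid_dim = as.integer(grid_dim),
    spacing_mm = spacing_mm, n_frames = as.integer(n_frames),
    frame_dt_s = frame_dt_s, n_baseline = as.integer(n_baseline),
    effect_profile = effect_profile, baseline_profile = baseline_profile,
    effect_jitter_sd = effect_jitter_sd,
    baseline_jitter_sd = baseline_jitter_sd,
    pet_sigma = pet_sigma, dwi_sigma = dwi_sigma, dce_sigma = dce_sigma,
    noise_model = match.arg(noise_model),
    rng_kind = "Mersenne-Twister"), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d patients x {%s}, %d^3 voxels @ %g mm, %d frames @ %g s, seed %d\n",
    x$n_patients, paste(x$timepoints, collapse = ", "), x$grid_dim,
    x$spacing_mm, x$n_frames, x$frame_dt_s, x$seed))
  invisible(x)
}

#' Synthetic arterial input function
#'
#' A short boxcar bolus convolved with a bi-exponential washout (fast
#' first-pass plus slow tail), in closed form: zero before bolus arrival,
#' non-negative, with analytic total area `dose * area` (so quadrature of
#' the returned curve converges to that value) and pointwise linear in
#' `dose`.
#'
#' @param times Time grid in seconds, strictly increasing.
#' @param bolus_time Bolus arrival time, s.
#' @param width Boxcar bolus width, s.
#' @param area Area under the unit-dose curve (a.u. * s).
#' @param dose Dose multiplier.
#' @param frac_fast Fraction of area in the fast component.
#' @param tau_fast,tau_slow Washout time constants, s.
#' @return Concentration curve (a.u.) at `times`.
#' @export
generate_aif <- function(times, bolus_time, width = 10, area = 100,
                         dose = 1, frac_fast = 0.8, tau_fast = 12,
                         tau_slow = 300) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  tt <- times - bolus_time
  box_exp <- function(tt, tau) {
    ifelse(tt <= 0, 0,
           ifelse(tt <= width, tau * (1 - exp(-tt / tau)),
                  tau * (exp(-(tt - width) / tau) - exp(-tt / tau))))
  }
  dose * area * (frac_fast * box_exp(tt, tau_fast) / (width * tau_fast) +
                 (1 - frac_fast) * box_exp(tt, tau_slow) / (width * tau_slow))
}

#' Simulate a 2CXM tissue curve (generator side)
#'
#' Shares its implementation with [twocxm_forward()] — the generator and the
#' fitted model are one forward model by construction — but additionally
#' refuses kinetically degenerate parameter sets (PF + PS = 0 with non-zero
#' compartment volumes), which cannot produce any enhancement.
#'
#' @inheritParams twocxm_forward
#' @return Tissue concentration curve (a.u.).
#' @export
simulate_2cxm_tissue <- function(params, aif, times) {
  if ((params$PF + params$PS) == 0 && (params$PV + params$ve) > 0)
    stop("degenerate kinetics: PF + PS = 0 with non-zero volumes",
         call. = FALSE)
  twocxm_forward(params, aif, times)
}

# jittered multiplier for one effect fraction: sign-preserving log-normal
# scaling of the magnitude, floored so values stay positive
effect_multiplier <- function(effect, z, sd) {
  max(1 + effect * exp(sd * z), 0.05)
}

#' Cohort ground truth
#'
#' Draws the true per-patient, per-timepoint parameter values implied by a
#' configuration: per-patient baselines (log-normal jitter around the
#' baseline profile; MR volumes patient-specific), and per-cell effect
#' multipliers (log-normal, sign-preserving jitter around the effect-profile
#' medians, so the direction of every driven change is cohort-consistent).
#' Deterministic given `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return Tibble, one row per patient-timepoint, with the ten driven
#'   parameters plus derived `ef` and `ktrans`.
#' @export
cohort_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed, kind = config$rng_kind)
  bp <- config$baseline_profile
  ep <- config$effect_profile
  np <- config$n_patients
  gtv_mr0 <- rep_len(bp$gtv_mr_patients, np)
  rows <- list()
  for (p in seq_len(np)) {
    jb <- function(x) x * exp(config$baseline_jitter_sd * rnorm(1))
    base <- c(
      gtv_mr = gtv_mr0[p],
      gtv_ct = gtv_mr0[p] * jb(bp$gtv_ct_ratio),
      gtv_dw = gtv_mr0[p] * jb(bp$gtv_dw_ratio),
      gtv_pet = gtv_mr0[p] * jb(bp$gtv_pet_ratio),
      suvmax = jb(bp$suvmax), adc = jb(bp$adc), pf = jb(bp$pf),
      pv = jb(bp$pv), ve = jb(bp$ve), ps = jb(bp$ps))
    for (tp in TIMEPOINT_LEVELS) {
      vals <- base
      if (tp != "baseline") {
        eff <- ep[[tp]]
        names(eff) <- ep$parameter
        for (nm in ep$parameter)
          vals[nm] <- base[nm] *
            effect_multiplier(eff[nm], rnorm(1), config$effect_jitter_sd)
      }
      if (vals["pv"] + vals["ve"] > 95)   # keep compartments physical
        vals["ve"] <- 95 - vals["pv"]
      if (!tp %in% config$timepoints) next
      dk <- derive_ef_ktrans(vals[["pf"]], vals[["ps"]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient = sprintf("P%02d", p), timepoint = tp,
        !!!setNames(as.list(vals), names(base)),
        ef = dk$EF, ktrans = dk$Ktrans)
    }
  }
  dplyr::bind_rows(rows)
}

# ellipsoid mask with axis ratios (1, 0.85, 0.7) scaled to a target volume
# (cm^3); coordinates at voxel centres, tumour centred on the grid
ellipsoid_mask <- function(target_cm3, grid_dim, spacing_mm) {
  ratios <- c(1, 0.85, 0.7)
  s <- (target_cm3 * 1000 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
  ax <- s * ratios
  ctr <- (grid_dim + 1) / 2 * spacing_mm
  g <- (seq_len(grid_dim) - 0.5) * spacing_mm
  dx2 <- ((g - ctr) / ax[1])^2
  dy2 <- ((g - ctr) / ax[2])^2
  dz2 <- ((g - ctr) / ax[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

add_magnitude_noise <- function(x, sigma, model) {
  if (sigma == 0) return(x)
  if (model == "gaussian") return(x + rnorm(length(x), 0, sigma))
  sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
}

ARTERY_VOXEL <- c(4L, 6L, 6L)

#' Generate one patient-timepoint image set
#'
#' Renders the full multi-modality image set for one cohort cell: PET with
#' uniform tumour uptake at the true SUVmax over a warm background, three
#' diffusion-weighted volumes decaying voxelwise as `S0 exp(-b ADC)`, a
#' dynamic contrast series whose tumour voxels follow the 2CXM forward model
#' and whose designated artery voxel carries the input function (the unique
#' global maximum of enhancement, by construction), plus the ground-truth
#' ROI masks. The restricted-diffusion contour is emulated by thresholding
#' the noise-free b = 800 image at half the lesion-background contrast.
#'
#' @param config A `cohort_config`.
#' @param patient Patient number (1-based) or id (`"P01"`).
#' @param timepoint One of `"baseline"`, `"fx11"`, `"fx21"`.
#' @param truth Optional precomputed [cohort_ground_truth()] table (avoids
#'   regenerating it per cell).
#' @return List: `pet` (`image_volume`), `dwi` (list of three volumes),
#'   `dce` (`dynamic_series`), `times`, `masks` (gtv_ct / gtv_mr / gtv_dw /
#'   pet_search / pet_bg / artery `roi_mask`s), `truth` (one-row tibble),
#'   `aif_true`.
#' @export
generate_patient_timepoint <- function(config, patient, timepoint,
                                       truth = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(truth)) truth <- cohort_ground_truth(config)
  pid <- if (is.character(patient)) patient else sprintf("P%02d", patient)
  pnum <- as.integer(sub("^P", "", pid))
  row <- truth[truth$patient == pid & truth$timepoint == timepoint, ]
  if (nrow(row) != 1)
    stop("no ground truth for ", pid, " at ", timepoint, call. = FALSE)
  d <- config$grid_dim
  sp <- rep(config$spacing_mm, 3)
  vox_cm3 <- prod(sp) / 1000
  for (v in c("gtv_ct", "gtv_mr", "gtv_dw", "gtv_pet"))
    if (row[[v]] < vox_cm3)
      stop("tumour volume below one voxel after shrinkage (", v, ")",
           call. = FALSE)
  tp_index <- match(timepoint, TIMEPOINT_LEVELS)
  set.seed(config$seed + 7919L * pnum + 101L * tp_index,
           kind = config$rng_kind)

  masks <- list(
    gtv_ct = roi_mask(ellipsoid_mask(row$gtv_ct, d, config$spacing_mm),
                      "GTV-CT"),
    gtv_mr = roi_mask(ellipsoid_mask(row$gtv_mr, d, config$spacing_mm),
                      "GTV-MR"))
  pet_lesion <- ellipsoid_mask(row$gtv_pet, d, config$spacing_mm)

  # PET: uniform lesion over warm background
  pet <- array(2.0, dim = c(d, d, d))
  pet[pet_lesion] <- row$suvmax
  pet <- add_magnitude_noise(pet, config$pet_sigma, config$noise_model)
  pet_vol <- image_volume(array(pet, c(d, d, d)), sp, "PET", "SUV")

  # search ROI: bounding box of the largest lesion this patient will show,
  # fixed across timepoints; background ROI: distant corner slab
  vmax <- max(truth$gtv_pet[truth$patient == pid]) * 1.05
  rmax <- (vmax * 1000 / (4 / 3 * pi * 0.595))^(1 / 3) / config$spacing_mm
  ctr <- (d + 1) / 2
  lo <- max(1L, floor(ctr - rmax - 3)); hi <- min(d, ceiling(ctr + rmax + 3))
  search <- array(FALSE, c(d, d, d)); search[lo:hi, lo:hi, lo:hi] <- TRUE
  # background: a slab beside the search box (disjoint along x suffices)
  bg <- array(FALSE, c(d, d, d))
  if (lo >= 2L) {
    bg[seq_len(min(4L, lo - 1L)), 1:min(6L, d), 1:min(6L, d)] <- TRUE
  } else if (hi <= d - 1L) {
    bg[(max(hi + 1L, d - 3L)):d, 1:min(6L, d), 1:min(6L, d)] <- TRUE
  } else {
    stop("grid too small to place a background ROI outside the search box",
         call. = FALSE)
  }
  masks$pet_search <- roi_mask(search, "PET-search")
  masks$pet_bg <- roi_mask(bg, "background")

  # DWI: mono-exponential decay; lesion ADC is the ground truth, background
  # a fixed 1.6e-3 mm^2/s with lower proton density
  dw_lesion <- ellipsoid_mask(row$gtv_dw, d, config$spacing_mm)
  s0 <- array(60, c(d, d, d)); s0[dw_lesion] <- 100
  adc_true <- array(1.6, c(d, d, d)); adc_true[dw_lesion] <- row$adc
  bvals <- c(0, 400, 800)
  dwi_clean <- lapply(bvals, function(b) s0 * exp(-b * adc_true * 1e-3))
  # restricted-diffusion contour: threshold noise-free b = 800 at half the
  # lesion-background contrast, keeping the lesion side (a stand-in for
  # visual contouring; as treatment raises the tumour ADC the b = 800
  # contrast shrinks and can invert, but the reader still contours the
  # lesion, not the background)
  b800 <- dwi_clean[[3]]
  s_les <- 100 * exp(-0.8 * row$adc)
  s_bg <- 60 * exp(-0.8 * 1.6)
  thr <- (s_les + s_bg) / 2
  masks$gtv_dw <- roi_mask(if (s_les >= s_bg) b800 >= thr else b800 <= thr,
                           "GTV-DW")
  dwi <- lapply(dwi_clean, function(x) image_volume(
    array(add_magnitude_noise(x, config$dwi_sigma, config$noise_model),
          c(d, d, d)), sp, "DWI", "signal"))
  names(dwi) <- paste0("b", bvals)

  # DCE: tumour voxels share one 2CXM curve; one artery voxel carries the AIF
  times <- (seq_len(config$n_frames) - 1) * config$frame_dt_s
  bolus_time <- times[config$n_baseline + 1]
  aif <- generate_aif(times, bolus_time = bolus_time)
  ct <- simulate_2cxm_tissue(list(PF = row$pf, PV = row$pv, ve = row$ve,
                                  PS = row$ps), aif, times)
  stopifnot(max(aif) > 2 * max(ct))  # artery must dominate enhancement
  s0_dce <- 50
  dce <- if (config$dce_sigma == 0) {
    array(s0_dce, dim = c(d, d, d, config$n_frames))
  } else {
    array(rnorm(as.numeric(d)^3 * config$n_frames, 0, config$dce_sigma),
          dim = c(d, d, d, config$n_frames)) + s0_dce
  }
  tum_idx <- which(masks$gtv_mr$mask)
  art <- array(FALSE, c(d, d, d))
  art[ARTERY_VOXEL[1], ARTERY_VOXEL[2], ARTERY_VOXEL[3]] <- TRUE
  art_idx <- which(art)
  stopifnot(!any(art & masks$gtv_mr$mask))  # artery sits outside the tumour
  nvox <- as.numeric(d)^3
  for (t in seq_len(config$n_frames)) {
    off <- (t - 1) * nvox
    dce[off + tum_idx] <- dce[off + tum_idx] + ct[t]
    dce[off + art_idx] <- dce[off + art_idx] + aif[t]
  }
  art_box <- array(FALSE, c(d, d, d))
  art_box[pmax(1, ARTERY_VOXEL[1] - 1):(ARTERY_VOXEL[1] + 1),
          (ARTERY_VOXEL[2] - 1):(ARTERY_VOXEL[2] + 1),
          (ARTERY_VOXEL[3] - 1):(ARTERY_VOXEL[3] + 1)] <- TRUE
  masks$artery <- roi_mask(art_box, "artery")

  list(pet = pet_vol, dwi = dwi,
       dce = dynamic_series(dce, times, sp, units = "signal"),
       times = times, masks = masks, truth = row, aif_true = aif)
}

#' Generate a cohort to disk
#'
#' Calls [generate_patient_timepoint()] for every cohort cell and writes the
#' image volumes and masks as NIfTI, the ground truth as CSV, and a manifest
#' (YAML) recording the seed, RNG algorithm, configuration and an MD5 hash
#' of every file written. Regenerating from the manifest's seed reproduces
#' the ground truth exactly.
#'
#' @param config A `cohort_config`.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
generate_cohort <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohort_ground_truth(config)
  files <- character(0)
  for (p in seq_len(config$n_patients)) {
    for (tp in config$timepoints) {
      cell <- generate_patient_timepoint(config, p, tp, truth = truth)
      stem <- file.path(out_dir, sprintf("P%02d_%s", p, tp))
      write_volume(cell$pet, paste0(stem, "_pet.nii.gz"))
      for (b in names(cell$dwi))
        write_volume(cell$dwi[[b]], paste0(stem, "_dwi_", b, ".nii.gz"))
      img <- RNifti::asNifti(cell$dce$data)
      RNifti::pixdim(img) <- c(cell$dce$spacing, config$frame_dt_s)
      RNifti::writeNifti(img, paste0(stem, "_dce.nii.gz"),
                         datatype = "double")
      readr::write_csv(tibble::tibble(time_s = cell$times),
                       paste0(stem, "_dce_times.csv"))
      for (mn in names(cell$masks))
        write_mask(cell$masks[[mn]], paste0(stem, "_mask_", mn, ".nii.gz"),
                   cell$dce$spacing)
      files <- c(files, list.files(out_dir, pattern = basename(stem),
                                   full.names = TRUE))
    }
  }
  write_table_csv(truth, file.path(out_dir, "ground_truth.csv"))
  files <- sort(unique(c(files, file.path(out_dir, "ground_truth.csv"))))
  manifest <- list(
    seed = config$seed, rng_kind = config$rng_kind,
    n_patients = config$n_patients, timepoints = config$timepoints,
    grid_dim = config$grid_dim, spacing_mm = config$spacing_mm,
    n_frames = config$n_frames, frame_dt_s = config$frame_dt_s,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
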