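# Voxelwise apparent diffusion coefficient mapping. Signal decays
# mono-exponentially with diffusion weighting, S(b) = S0 exp(-b * D); the
# ADC is minus the OLS slope of log S against b, reported in 1e-3 mm^2/s.
# Unweighted log-linear OLS matches standard scanner-console ADC maps; with
# three b-values and phantom-level SNR, weighting is immaterial.

#' Diffusion b-value set
#'
#' @param b Acquired b-values in s/mm^2 (>= 2 distinct, all >= 0).
#'   Default `c(0, 400, 800)`.
#' @return An object of class `b_value_set`.
#' @export
b_value_set <- function(b = c(0, 400, 800)) {
  b <- as.numeric(b)
  if (length(unique(b)) < 2 || any(b < 0) || any(!is.finite(b)))
    stop("need >= 2 distinct non-negative b-values", call. = FALSE)
  structure(list(b = b), class = "b_value_set")
}

b_values <- function(bset) {
  if (inherits(bset, "b_value_set")) bset$b else as.numeric(bset)
}

#' Fit the ADC for one voxel
#'
#' Ordinary least squares of `log(S)` on b; ADC is minus the slope. Voxels
#' with any non-positive signal cannot be log-transformed and are flagged
#' invalid (`NA`), to be excluded from ROI means.
#'
#' @param signals Signal intensities (a.u.), one per b-value.
#' @param bset A `b_value_set` (or numeric b-values).
#' @return ADC in 1e-3 mm^2/s, or `NA_real_` for an invalid voxel.
#' @export
fit_adc_voxel <- function(signals, bset = b_value_set()) {
  b <- b_values(bset)
  signals <- as.numeric(signals)
  if (length(signals) != length(b))
    stop("one signal per b-value required", call. = FALSE)
  if (any(!is.finite(signals)) || any(signals <= 0)) return(NA_real_)
  y <- log(signals)
  bc <- b - mean(b)
  -(sum(bc * y) / sum(bc^2)) * 1000
}

#' Voxelwise ADC map
#'
#' Applies the mono-exponential fit at every voxel of a set of co-registered
#' diffusion-weighted volumes. Invalid voxels (non-positive signal at any
#' b-value) are `NA` in the map. Negative fitted ADCs are retained (and can
#' be excluded later via `clip_negative` in [mean_adc()]), keeping the
#' estimator unbiased around zero.
#'
#' @param dwi_volumes List of `image_volume`s, one per b-value, on one grid.
#' @param bset A `b_value_set`.
#' @return An `image_volume` (modality `MAP`, units `adc`, 1e-3 mm^2/s).
#' @export
adc_map <- function(dwi_volumes, bset = b_value_set()) {
  b <- b_values(bset)
  if (length(dwi_volumes) != length(b))
    stop("one volume per b-value required", call. = FALSE)
  d <- dim(dwi_volumes[[1]]$values)
  sp <- dwi_volumes[[1]]$spacing
  for (v in dwi_volumes) {
    check_aligned(v$values, dwi_volumes[[1]])
    if (max(abs(v$spacing - sp)) > 1e-9)
      stop("alignment error: DWI volumes differ in spacing", call. = FALSE)
  }
  S <- vapply(dwi_volumes, function(v) as.numeric(v$values),
              numeric(prod(d)))
  valid <- rowSums(S <= 0 | !is.finite(S)) == 0
  out <- rep(NA_real_, prod(d))
  if (any(valid)) {
    bc <- b - mean(b)
    slope <- (log(S[valid, , drop = FALSE]) %*% bc) / sum(bc^2)
    out[valid] <- -slope * 1000
  }
  vol <- dwi_volumes[[1]]
  structure(list(values = array(out, dim = d), spacing = sp,
                 modality = "MAP", units = "adc"),
            class = "image_volume")
}

#' Mean ADC over an ROI
#'
#' Arithmetic mean of valid (non-`NA`) ADC voxels inside the ROI.
#'
#' @param map ADC `image_volume` from [adc_map()].
#' @param roi `roi_mask` with at least one valid voxel.
#' @param clip_negative If `TRUE`, negative fitted ADCs are excluded from the
#'   mean (default `FALSE`).
#' @return Mean ADC in 1e-3 mm^2/s.
#' @export
mean_adc <- function(map, roi, clip_negative = FALSE) {
  m <- as_mask_array(roi)
  check_aligned(m, map)
  vals <- map$values[m]
  vals <- vals[is.finite(vals)]
  if (clip_negative) vals <- vals[vals >= 0]
  if (length(vals) == 0L)
    stop("no valid ADC voxels in ROI", call. = FALSE)
  mean(vals)
}
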