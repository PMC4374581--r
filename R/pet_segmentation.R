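# Contrast-oriented adaptive-threshold PET delineation. The threshold is a
# linear combination of lesion and background uptake,
#   T = a * mSUV70 + b * BG,
# where mSUV70 is the mean SUV inside the 70%-of-SUVmax isocontour and BG the
# background mean; a and b are scanner-specific coefficients determined from
# phantom measurements.

#' Scanner coefficients for the adaptive threshold
#'
#' @param a Weight on the lesion term (mSUV70), dimensionless, >= 0.
#' @param b Weight on the background term, dimensionless, >= 0.
#' @return An object of class `homburg_coefficients`.
#' @export
homburg_coefficients <- function(a = 0.5, b = 0.5) {
  if (!is.finite(a) || !is.finite(b) || a < 0 || b < 0 || a + b <= 0)
    stop("need a >= 0, b >= 0 and a + b > 0", call. = FALSE)
  structure(list(a = a, b = b), class = "homburg_coefficients")
}

#' Maximum standardized uptake value within an ROI
#'
#' @param vol `image_volume` of SUV.
#' @param search_roi Non-empty `roi_mask` over the lesion search region.
#' @return List with `value` (SUVmax), `index` (i, j, k of the hottest voxel;
#'   ties resolve to the lowest linear index) and `linear_index`.
#' @export
suv_max <- function(vol, search_roi) {
  m <- as_mask_array(search_roi)
  check_aligned(m, vol)
  idx <- which(m)
  if (length(idx) == 0L) stop("search ROI is empty", call. = FALSE)
  best <- idx[which.max(vol$values[idx])]
  list(value = vol$values[best],
       index = as.integer(arrayInd(best, dim(vol$values))),
       linear_index = best)
}

#' Mean SUV within a fractional isocontour of SUVmax
#'
#' Mean of ROI voxels at or above `fraction` of SUVmax (default 70%),
#' computed in a single pass with no iterative re-estimation. The hottest
#' voxel always qualifies, so the isocontour set is never empty.
#'
#' @inheritParams suv_max
#' @param fraction Isocontour level in (0, 1).
#' @return Mean SUV of the isocontour voxels.
#' @export
mean_suv_isocontour <- function(vol, search_roi, fraction = 0.70) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  m <- as_mask_array(search_roi)
  check_aligned(m, vol)
  vals <- vol$values[m]
  if (length(vals) == 0L) stop("search ROI is empty", call. = FALSE)
  mean(vals[vals >= fraction * max(vals)])
}

#' Background mean uptake
#'
#' Arithmetic mean SUV over an explicit background ROI, which must be
#' disjoint from the tumour search region.
#'
#' @param vol `image_volume` of SUV.
#' @param bg_roi Non-empty background `roi_mask`.
#' @param search_roi Optional tumour search ROI for the disjointness check.
#' @return Mean background SUV.
#' @export
background_mean <- function(vol, bg_roi, search_roi = NULL) {
  m <- as_mask_array(bg_roi)
  check_aligned(m, vol)
  if (!any(m)) stop("background ROI is empty", call. = FALSE)
  if (!is.null(search_roi)) {
    if (any(m & as_mask_array(search_roi)))
      stop("background ROI overlaps the tumour search ROI", call. = FALSE)
  }
  mean(vol$values[m])
}

#' Adaptive segmentation threshold
#'
#' `T = a * mSUV70 + b * bg`. Refuses to produce a threshold when the lesion
#' is not distinguishable from background (mSUV70 <= bg).
#'
#' @param msuv70 Mean SUV of the 70% isocontour.
#' @param bg Background mean SUV (>= 0).
#' @param coeffs `homburg_coefficients`.
#' @return Threshold in SUV.
#' @export
homburg_threshold <- function(msuv70, bg, coeffs = homburg_coefficients()) {
  stopifnot(inherits(coeffs, "homburg_coefficients"))
  if (bg < 0) stop("background SUV must be non-negative", call. = FALSE)
  if (msuv70 <= bg)
    stop("lesion not distinguishable from background (mSUV70 <= background); refusing to segment",
         call. = FALSE)
  coeffs$a * msuv70 + coeffs$b * bg
}

# 26-connected component (3D: faces + edges + corners) containing `seed`,
# within the logical array `candidate`. Breadth-first flood fill on voxel
# indices; connectivity 6 (faces only) also supported.
connected_component <- function(candidate, seed, connectivity = 26) {
  d <- dim(candidate)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity != 26)
    stop("connectivity must be 6 or 26", call. = FALSE)
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  comp <- array(FALSE, dim = d)
  if (!candidate[seed]) return(comp)
  comp[seed] <- TRUE
  frontier <- seed
  sx <- arrayInd(seq_along(candidate), d)  # guard against wrap-around
  while (length(frontier) > 0) {
    nb <- rep(frontier, each = nrow(offs)) + rep(lin_off, length(frontier))
    fx <- sx[rep(frontier, each = nrow(offs)), , drop = FALSE]
    nx <- fx + offs[rep(seq_len(nrow(offs)), length(frontier)), , drop = FALSE]
    ok <- nb >= 1 & nb <= length(candidate) &
      nx[, 1] >= 1 & nx[, 1] <= d[1] &
      nx[, 2] >= 1 & nx[, 2] <= d[2] &
      nx[, 3] >= 1 & nx[, 3] <= d[3]
    nb <- unique(nb[ok])
    nb <- nb[candidate[nb] & !comp[nb]]
    comp[nb] <- TRUE
    frontier <- nb
  }
  comp
}

#' Segment the PET gross tumour volume
#'
#' Thresholds the search region at the adaptive threshold and keeps the
#' 26-connected component containing the SUVmax voxel, yielding the GTV-PET.
#'
#' @inheritParams background_mean
#' @param search_roi Non-empty `roi_mask` encompassing the primary tumour.
#' @param coeffs `homburg_coefficients`.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `gtv_pet`: `mask` (`roi_mask`), `threshold`,
#'   `suvmax`, `msuv70`, `background`, `volume_cm3`.
#' @export
segment_gtv_pet <- function(vol, search_roi, bg_roi,
                            coeffs = homburg_coefficients(),
                            connectivity = 26) {
  sm <- suv_max(vol, search_roi)
  msuv <- mean_suv_isocontour(vol, search_roi)
  bg <- background_mean(vol, bg_roi, search_roi)
  thr <- homburg_threshold(msuv, bg, coeffs)
  cand <- as_mask_array(search_roi) & (vol$values >= thr)
  comp <- connected_component(cand, sm$linear_index,
                              connectivity = connectivity)
  mask <- roi_mask(comp, label = "GTV-PET")
  structure(list(mask = mask, threshold = thr, suvmax = sm$value,
                 msuv70 = msuv, background = bg,
                 volume_cm3 = mask_volume_cm3(mask, vol$spacing)),
            class = "gtv_pet")
}

#' @export
print.gtv_pet <- function(x, ...) {
  cat(sprintf(
    "<gtv_pet> SUVmax %.3g, mSUV70 %.3g, BG %.3g, T %.3g -> %.3g cm^3 (%d voxels)\n",
    x$suvmax, x$msuv70, x$background, x$threshold, x$volume_cm3,
    sum(x$mask$mask)))
  invisible(x)
}

#' Calibrate threshold coefficients from phantom measurements
#'
#' Least-squares solution of `T_true = a * mSUV70 + b * BG` over a set of
#' phantom measurements (no intercept), as done in scanner-specific phantom
#' studies.
#'
#' @param measurements Data frame with columns `msuv70`, `bg`, `threshold`
#'   (>= 2 linearly independent rows).
#' @return `homburg_coefficients` with the fitted a and b.
#' @export
calibrate_coefficients <- function(measurements) {
  measurements <- as.data.frame(measurements)
  need <- c("msuv70", "bg", "threshold")
  if (!all(need %in% names(measurements)))
    stop("measurements need columns msuv70, bg, threshold", call. = FALSE)
  if (nrow(measurements) < 2)
    stop("need at least 2 phantom measurements", call. = FALSE)
  X <- cbind(measurements$msuv70, measurements$bg)
  if (qr(X)$rank < 2)
    stop("rank-deficient design: phantom measurements are not linearly independent",
         call. = FALSE)
  ab <- qr.solve(X, measurements$threshold)
  homburg_coefficients(a = ab[1], b = ab[2])
}
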