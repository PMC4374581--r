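#' @importFrom rlang .data
#' @importFrom stats coef lm median optimize pt quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

VALID_MODALITIES <- c("PET", "CT", "T2", "DWI", "DCE_FRAME", "MAP")
VALID_UNITS <- c("SUV", "signal", "adc", "ml/min/100ml", "ml/100ml", "none")

#' Create a 3D image volume
#'
#' The basic container used throughout the package: a 3D scalar grid plus
#' voxel spacing in millimetres, tagged with a modality and a unit so that
#' mixing incompatible quantities is caught at module boundaries rather than
#' silently propagated.
#'
#' @param values Numeric 3D array of voxel values (all finite).
#' @param spacing Numeric length-3 vector of voxel sizes in mm (all > 0).
#' @param modality One of `"PET"`, `"CT"`, `"T2"`, `"DWI"`, `"DCE_FRAME"`,
#'   `"MAP"`.
#' @param units Unit tag: `"SUV"`, `"signal"` (arbitrary units),
#'   `"adc"` (x 1e-3 mm^2/s), `"ml/min/100ml"`, `"ml/100ml"` or `"none"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, modality = "MAP", units = "none") {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("`values` must be a non-empty 3D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all voxel values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  modality <- match.arg(modality, VALID_MODALITIES)
  units <- match.arg(units, VALID_UNITS)
  structure(list(values = values, spacing = spacing,
                 modality = modality, units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %dx%dx%d voxels, %.3gx%.3gx%.3g mm, %s [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$modality, x$units))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Create a region-of-interest mask
#'
#' A boolean grid aligned voxel-for-voxel with a reference volume. Masks are
#' the source of all gross tumour volume (GTV) measurements; tumour-labelled
#' masks must contain at least one voxel.
#'
#' @param mask Logical 3D array.
#' @param label Free-text label, e.g. `"GTV-PET"`, `"background"`.
#' @param reference Optional `image_volume` whose grid the mask must match.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "ROI", reference = NULL) {
  if (is.numeric(mask)) mask <- array(mask != 0, dim = dim(mask))
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a logical 3D array", call. = FALSE)
  if (anyNA(mask)) stop("mask may not contain NA", call. = FALSE)
  if (!is.null(reference)) check_aligned(mask, reference)
  if (grepl("^GTV", label, ignore.case = TRUE) && !any(mask))
    stop(sprintf("degenerate ROI: tumour mask '%s' has no voxels", label),
         call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<roi_mask> '%s': %d / %d voxels set (%dx%dx%d grid)\n",
              x$label, sum(x$mask), length(x$mask), d[1], d[2], d[3]))
  invisible(x)
}

as_mask_array <- function(x) {
  if (inherits(x, "roi_mask")) x$mask else x
}

check_aligned <- function(mask, vol) {
  m <- as_mask_array(mask)
  v <- if (inherits(vol, "image_volume")) vol$values else vol
  if (!identical(dim(m), dim(v)))
    stop(sprintf("alignment error: mask grid %s does not match volume grid %s",
                 paste(dim(m), collapse = "x"),
                 paste(dim(v), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Create a dynamic (4D) image series
#'
#' Time-ordered stack of frames on a common grid, e.g. a dynamic
#' contrast-enhanced acquisition of ~150 frames at ~2.5 s resolution.
#'
#' @param data Numeric 4D array `[x, y, z, t]`.
#' @param times Frame mid-times in seconds, strictly increasing, one per frame.
#' @param spacing Voxel spacing in mm (length 3).
#' @param units Unit tag for the voxel values (default `"signal"`).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, times, spacing, units = "signal") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array [x, y, z, t]", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) != dim(data)[4])
    stop("length(times) must equal the number of frames", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  structure(list(data = data, times = times, spacing = spacing,
                 units = match.arg(units, VALID_UNITS)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_series> %dx%dx%d voxels x %d frames, t = %.3g..%.3g s [%s]\n",
    d[1], d[2], d[3], d[4], x$times[1], x$times[d[4]], x$units))
  invisible(x)
}

#' Volume of an ROI mask in cubic centimetres
#'
#' Counts true voxels and multiplies by the voxel volume; this realizes every
#' GTV measurement (GTV-CT/MR/DW/PET) reported in cm^3.
#'
#' @param mask An `roi_mask` or logical 3D array.
#' @param spacing Voxel spacing in mm (length 3), or an `image_volume` whose
#'   spacing (and grid, for the alignment check) is used.
#' @return Volume in cm^3 (scalar).
#' @export
mask_volume_cm3 <- function(mask, spacing) {
  m <- as_mask_array(mask)
  if (inherits(spacing, "image_volume")) {
    check_aligned(m, spacing)
    spacing <- spacing$spacing
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  lab <- if (inherits(mask, "roi_mask")) mask$label else "ROI"
  n <- sum(m)
  if (n == 0L && grepl("^GTV", lab, ignore.case = TRUE))
    stop(sprintf("degenerate ROI: tumour mask '%s' is empty", lab),
         call. = FALSE)
  n * prod(spacing) / 1000
}

# ---- NIfTI + CSV I/O --------------------------------------------------------

#' Read / write image volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti. Only the voxel grid and spacing are used;
#' orientation metadata beyond spacing is ignored (phantom data are
#' axis-aligned on a common grid, and no resampling is done in-core).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol An `image_volume`.
#' @param modality,units Tags to attach on read (not stored in NIfTI).
#' @return `read_volume()` returns an `image_volume`; `write_volume()` its
#'   path, invisibly.
#' @export
read_volume <- function(path, modality = "MAP", units = "none") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  image_volume(vals, RNifti::pixdim(img)[1:3], modality = modality,
               units = units)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname read_volume
#' @param label Mask label to attach on read.
#' @param reference Optional `image_volume`; shape and spacing are checked.
#' @export
read_mask <- function(path, label = "ROI", reference = NULL) {
  img <- RNifti::readNifti(path)
  m <- array(as.numeric(img) > 0.5, dim = dim(img)[1:3])
  if (!is.null(reference)) {
    check_aligned(m, reference)
    sp <- RNifti::pixdim(img)[1:3]
    if (max(abs(sp - reference$spacing)) > 1e-6)
      stop("alignment error: mask voxel spacing differs from reference",
           call. = FALSE)
  }
  roi_mask(m, label = label)
}

#' @rdname read_volume
#' @param mask An `roi_mask`.
#' @param spacing Voxel spacing in mm for the written mask.
#' @export
write_mask <- function(mask, path, spacing) {
  m <- as_mask_array(mask)
  img <- RNifti::asNifti(array(as.numeric(m), dim = dim(m)))
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read / write record tables as CSV
#'
#' CSV with a header row; floats are serialized at full precision so that
#' write-then-read round-trips are exact to double precision.
#'
#' @param rows A data frame / tibble.
#' @param path File path.
#' @return `read_table_csv()` returns a tibble.
#' @export
write_table_csv <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
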