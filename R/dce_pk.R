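# Two-compartment exchange model (2CXM) machinery.
#
# State (Cp, Ce) per unit tissue volume, driven by an arterial input Ca(t):
#   vp dCp/dt = fp (Ca - Cp) + ps (Ce - Cp)
#   ve dCe/dt = ps (Cp - Ce)
#   Ct        = vp Cp + ve Ce
# with fractional volumes vp = PV/100, ve = nu_e/100 and per-second rates
# fp = PF/6000, ps = PS/6000 (parameters are quoted per minute per 100 ml;
# the time grid is in seconds, hence the /60 at this boundary and nowhere
# else). The system is linear and time-invariant, so the solution is the
# convolution of a bi-exponential impulse response with Ca.

#' Two-compartment exchange model parameters
#'
#' Bundles the four primary microvascular parameters and computes the two
#' derived ones. Units follow the perfusion literature: PF and PS in
#' ml/min/100 ml, PV and ve in ml/100 ml, Ktrans in min^-1, EF in percent.
#'
#' @param PF Plasma flow, ml/min/100 ml.
#' @param PV Plasma volume, ml/100 ml.
#' @param ve Interstitial (extravascular extracellular) volume, ml/100 ml.
#' @param PS Permeability-surface-area product, ml/min/100 ml.
#' @return An object of class `twocxm_params` with fields `PF`, `PV`, `ve`,
#'   `PS` and derived `EF` (extraction fraction, %) and `Ktrans` (min^-1).
#' @export
twocxm_params <- function(PF, PV, ve, PS) {
  vals <- c(PF = PF, PV = PV, ve = ve, PS = PS)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("2CXM parameters must be finite and non-negative", call. = FALSE)
  if (PV + ve > 100 + 1e-9)
    stop("PV + ve must not exceed 100 ml/100 ml", call. = FALSE)
  dk <- derive_ef_ktrans(PF, PS)
  structure(list(PF = PF, PV = PV, ve = ve, PS = PS,
                 EF = dk$EF, Ktrans = dk$Ktrans),
            class = "twocxm_params")
}

#' @export
print.twocxm_params <- function(x, ...) {
  cat(sprintf(
    "<twocxm_params> PF %.3g, PV %.3g, ve %.3g, PS %.3g (EF %.3g%%, Ktrans %.4g /min)\n",
    x$PF, x$PV, x$ve, x$PS, x$EF, x$Ktrans))
  invisible(x)
}

#' Derived extraction fraction and volume transfer constant
#'
#' EF = 100 PS / (PS + PF); Ktrans = (PS PF / (PS + PF)) / 100. When flow is
#' high relative to permeability (PF >> PS), Ktrans approaches PS / 100:
#' contrast uptake is permeability-limited, and percentage changes in Ktrans
#' track percentage changes in PS almost exactly.
#'
#' @param PF,PS Plasma flow and permeability-surface-area product,
#'   ml/min/100 ml (vectorized).
#' @return A list with `EF` (%), `Ktrans` (min^-1) and `degenerate`
#'   (TRUE where PS + PF = 0, for which both are defined as 0).
#' @export
derive_ef_ktrans <- function(PF, PS) {
  if (any(PF < 0 | PS < 0, na.rm = TRUE))
    stop("PF and PS must be non-negative", call. = FALSE)
  tot <- PF + PS
  deg <- is.finite(tot) & tot == 0
  EF <- ifelse(deg, 0, 100 * PS / tot)
  Ktrans <- ifelse(deg, 0, (PS * PF / tot) / 100)
  list(EF = EF, Ktrans = Ktrans, degenerate = deg)
}

# phi-functions of the exponential integrator, series-guarded near 0
phi1 <- function(z) ifelse(abs(z) < 1e-5, 1 + z / 2 + z * z / 6, (exp(z) - 1) / z)
phi2 <- function(z) ifelse(abs(z) < 1e-5, 0.5 + z / 6 + z * z / 24,
                           (exp(z) - 1 - z) / (z * z))

# Decompose the 2CXM into exponential modes: Ct(t) responds to the input as
# sum_m wv_m * z_m with dz_m/dt = lambda_m z_m + bt_m Ca(t). Returns a list
# of lambda (per second), bt, wv; NULL means the response is identically zero.
twocxm_modes <- function(params) {
  fp <- params$PF / 6000   # fractional flow, s^-1
  ps <- params$PS / 6000   # fractional exchange, s^-1
  vp <- params$PV / 100
  ve <- params$ve / 100
  if (fp == 0 || (vp == 0 && ve == 0)) return(NULL)
  if (ps == 0 || ve == 0) {
    if (vp == 0) return(NULL)
    k <- fp / vp                       # one-compartment plasma model
    return(list(lambda = -k, bt = k, wv = vp))
  }
  if (vp == 0) {                       # instantaneous plasma: uptake limit
    k <- (fp * ps / (fp + ps)) / ve
    return(list(lambda = -k, bt = k, wv = ve))
  }
  m11 <- -(fp + ps) / vp; m12 <- ps / vp
  m21 <- ps / ve;         m22 <- -ps / ve
  tr <- m11 + m22
  dt2 <- m11 * m22 - m12 * m21
  disc <- tr * tr - 4 * dt2
  if (disc < (1e-7 * tr)^2) {          # (near-)repeated eigenvalues: nudge PS
    return(twocxm_modes(list(PF = params$PF, PV = params$PV,
                             ve = params$ve, PS = params$PS * (1 + 1e-6))))
  }
  sq <- sqrt(disc)
  lam <- c((tr + sq) / 2, (tr - sq) / 2)
  V <- cbind(c(m12, lam[1] - m11), c(m12, lam[2] - m11))
  dv <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  Vinv <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]),
                 2, 2, byrow = TRUE) / dv
  b <- c(fp / vp, 0)
  bt <- as.numeric(Vinv %*% b)
  wv <- as.numeric(c(vp, ve) %*% V)
  list(lambda = lam, bt = bt, wv = wv)
}

#' Forward two-compartment exchange model
#'
#' Tissue concentration-time curve produced by the 2CXM for a given arterial
#' input function. The linear system is integrated exactly for a
#' piecewise-linear AIF using an eigenmode exponential integrator, so the
#' only discretization is the linear interpolation of `aif` between frames.
#' Degenerate parameter sets (PV = 0, ve = 0 or PS = 0) reduce analytically
#' to the uptake / one-compartment limits rather than dividing by zero.
#'
#' @param params A `twocxm_params` object (or list with PF, PV, ve, PS).
#' @param aif Arterial concentration at each time point (a.u.).
#' @param times Time grid in seconds, strictly increasing.
#' @return Tissue concentration at each time point (same a.u. as `aif`).
#' @export
twocxm_forward <- function(params, aif, times) {
  times <- as.numeric(times); aif <- as.numeric(aif)
  n <- length(times)
  if (length(aif) != n) stop("aif and times lengths differ", call. = FALSE)
  if (n < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing (>= 2 points)", call. = FALSE)
  md <- twocxm_modes(params)
  if (is.null(md)) return(numeric(n))
  h <- diff(times)
  uniform <- (max(h) - min(h)) < 1e-9 * max(h)
  ct <- numeric(n)
  if (uniform) {
    hh <- h[1]
    for (m in seq_along(md$lambda)) {
      z <- md$lambda[m] * hh
      E <- exp(z)
      p1 <- phi1(z); p2 <- phi2(z)
      a0 <- hh * (p1 - p2) * md$bt[m]
      a1 <- hh * p2 * md$bt[m]
      x <- a0 * aif[-n] + a1 * aif[-1]
      zser <- stats::filter(x, E, method = "recursive")
      ct <- ct + md$wv[m] * c(0, as.numeric(zser))
    }
  } else {
    for (m in seq_along(md$lambda)) {
      lam <- md$lambda[m]
      E <- exp(lam * h)
      p1 <- phi1(lam * h); p2 <- phi2(lam * h)
      a0 <- h * (p1 - p2) * md$bt[m]
      a1 <- h * p2 * md$bt[m]
      zz <- numeric(n)
      for (i in 2:n)
        zz[i] <- E[i - 1] * zz[i - 1] + a0[i - 1] * aif[i - 1] + a1[i - 1] * aif[i]
      ct <- ct + md$wv[m] * zz
    }
  }
  ct
}

#' Impulse response of the 2CXM
#'
#' h(t) such that `Ct = (h * Ca)(t)` (convolution over seconds). The response
#' is a non-negative bi-exponential with `h(0) = PF / 6000` per second, i.e.
#' plasma flow sets the peak of the tissue residue function.
#'
#' @inheritParams twocxm_forward
#' @return h evaluated at `times` (units s^-1).
#' @export
twocxm_impulse_response <- function(params, times) {
  md <- twocxm_modes(params)
  if (is.null(md)) return(numeric(length(times)))
  h <- numeric(length(times))
  for (m in seq_along(md$lambda))
    h <- h + md$wv[m] * md$bt[m] * exp(md$lambda[m] * times)
  h
}

# Second route: direct trapezoidal convolution of the analytic impulse
# response with the AIF. Kept as an internal cross-check of twocxm_forward
# ("both routes agree" on fine grids); not the production path.
twocxm_forward_conv <- function(params, aif, times) {
  n <- length(times)
  h <- twocxm_impulse_response(params, times - times[1])
  dt <- diff(times)
  if ((max(dt) - min(dt)) > 1e-9 * max(dt))
    stop("convolution route requires a uniform grid", call. = FALSE)
  dt <- dt[1]
  ct <- numeric(n)
  for (i in 2:n) {
    w <- rep(1, i); w[1] <- 0.5; w[i] <- 0.5
    ct[i] <- sum(w * h[1:i] * aif[i:1]) * dt
  }
  ct
}

# ---- concentration curves ---------------------------------------------------

#' Baseline-subtracted concentration series
#'
#' Approximates contrast concentration by subtracting, per voxel, the mean
#' signal over the pre-contrast frames (default 10, matching injection after
#' about 10 measurements). No T1 mapping is used, so concentrations share one
#' unknown proportionality constant between artery and tissue, which cancels
#' in the kinetic fit.
#'
#' @param series A `dynamic_series` of raw signal.
#' @param n_baseline Number of pre-contrast frames averaged (>= 2 and fewer
#'   than the number of frames).
#' @return A `dynamic_series` of concentrations (a.u.).
#' @export
baseline_subtract <- function(series, n_baseline = 10) {
  stopifnot(inherits(series, "dynamic_series"))
  nt <- dim(series$data)[4]
  if (n_baseline < 2 || n_baseline >= nt)
    stop("n_baseline must be >= 2 and less than the number of frames",
         call. = FALSE)
  d <- dim(series$data)
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  base <- rowMeans(flat[, seq_len(n_baseline), drop = FALSE])
  conc <- flat - base
  dynamic_series(array(conc, dim = d), series$times, series$spacing,
                 units = "signal")
}

#' Map of maximal signal enhancement
#'
#' Per-voxel temporal maximum of a concentration series; the map on which the
#' arterial input voxel is identified.
#'
#' @param conc_series A `dynamic_series` of concentrations.
#' @return An `image_volume` (modality `MAP`).
#' @export
max_enhancement_map <- function(conc_series) {
  stopifnot(inherits(conc_series, "dynamic_series"))
  d <- dim(conc_series$data)
  flat <- matrix(conc_series$data, nrow = prod(d[1:3]), ncol = d[4])
  mx <- do.call(pmax, as.data.frame(flat))
  image_volume(array(mx, dim = d[1:3]), conc_series$spacing,
               modality = "MAP", units = "signal")
}

#' Select the arterial input function
#'
#' Returns the concentration-time curve of the single brightest voxel of the
#' maximal-enhancement map inside the artery ROI (the internal carotid in the
#' clinical setting). Ties break deterministically to the lowest linear voxel
#' index.
#'
#' @param map Maximal-enhancement `image_volume`.
#' @param artery_roi `roi_mask` over the artery (non-empty).
#' @param conc_series The concentration `dynamic_series`.
#' @return List with `aif` (numeric curve), `index` (i, j, k voxel index) and
#'   `linear_index`.
#' @export
select_aif <- function(map, artery_roi, conc_series) {
  m <- as_mask_array(artery_roi)
  check_aligned(m, map)
  idx <- which(m)
  if (length(idx) == 0L) stop("artery ROI is empty", call. = FALSE)
  best <- idx[which.max(map$values[idx])]   # which.max: first max = lowest index
  d <- dim(conc_series$data)
  flat <- matrix(conc_series$data, nrow = prod(d[1:3]), ncol = d[4])
  list(aif = as.numeric(flat[best, ]),
       index = as.integer(arrayInd(best, d[1:3])),
       linear_index = best)
}

# ---- deconvolution plasma flow ----------------------------------------------

# Discrete convolution operator of the AIF (lower-triangular) and its SVD.
# For a smooth AIF the quadrature treats both the impulse response and the
# AIF as piecewise linear on the frame grid (exact for such functions, so
# the peak of the recovered response is not biased by the rectangle rule's
# half-frame smearing). An AIF with a single non-zero sample is a discrete
# delta, for which piecewise linearity is wrong; the operator then reduces
# to the shift matrix, making the identity case exact.
aif_operator_svd <- function(aif, times) {
  dt <- diff(times)
  if ((max(dt) - min(dt)) > 1e-6 * max(dt))
    stop("deconvolution requires a uniform time grid", call. = FALSE)
  dt <- mean(dt)
  n <- length(aif)
  ca <- function(j) ifelse(j >= 1 & j <= n, aif[pmax(pmin(j, n), 1)], 0)
  if (sum(aif != 0) == 1L) {
    A <- matrix(0, n, n)
    for (j in seq_len(n)) A[j:n, j] <- aif[seq_len(n - j + 1)] * dt
  } else {
    m <- seq_len(n - 1)
    f <- dt / 6 * (ca(m) + 4 * ca(m + 1) + ca(m + 2))
    lag <- outer(seq_len(n), seq_len(n), "-")
    A <- matrix(0, n, n)
    pos <- lag >= 1
    A[pos] <- f[lag[pos]]
    i <- 2:n
    A[cbind(i, 1)] <- dt / 6 * (2 * ca(i) + ca(i - 1))
    A[cbind(i, i)] <- dt / 6 * (ca(2) + 2 * ca(1))
  }
  sv <- svd(A)
  list(svd = sv, dt = dt)
}

#' Plasma flow by model-free deconvolution
#'
#' Solves `Ct = A h` for the tissue impulse response, where `A` is the
#' lower-triangular discrete convolution operator built from the AIF, by
#' truncated singular value decomposition: singular values below
#' `reg * max(singular values)` are discarded. Plasma flow is the peak of the
#' recovered response, converted to ml/min/100 ml (`max(h) * 6000` for a time
#' grid in seconds). Tikhonov regularization is available behind the same
#' interface.
#'
#' @param conc_curve Tissue concentration curve (a.u.).
#' @param aif Arterial concentration curve on the same grid.
#' @param times Uniform time grid, seconds.
#' @param reg Relative singular-value cutoff (default 0.05) or, for
#'   `method = "tikhonov"`, the relative ridge parameter.
#' @param method `"tsvd"` (default) or `"tikhonov"`.
#' @param op Optional precomputed operator from a previous call (internal
#'   reuse for maps).
#' @return List with `PF` (ml/min/100 ml), `h` (impulse response, s^-1) and
#'   `n_components` (retained singular values).
#' @export
deconvolve_pf <- function(conc_curve, aif, times, reg = 0.05,
                          method = c("tsvd", "tikhonov"), op = NULL) {
  method <- match.arg(method)
  if (is.null(op)) {
    if (max(abs(aif)) == 0)
      stop("uninformative AIF: identically zero", call. = FALSE)
    op <- aif_operator_svd(aif, times)
  }
  sv <- op$svd
  keep <- sv$d >= reg * sv$d[1]
  if (!any(keep))
    stop("uninformative AIF: all singular values below cutoff", call. = FALSE)
  if (method == "tsvd") {
    inv_d <- ifelse(keep, 1 / sv$d, 0)
  } else {
    mu <- (reg * sv$d[1])^2
    inv_d <- sv$d / (sv$d^2 + mu)
  }
  h <- sv$v %*% (inv_d * crossprod(sv$u, conc_curve))
  h <- as.numeric(h)
  list(PF = max(h) * 6000, h = h, n_components = sum(keep))
}

#' Voxelwise plasma-flow map by deconvolution
#'
#' Applies [deconvolve_pf()] to every voxel inside `roi` (or the whole grid),
#' reusing one SVD of the AIF operator. Voxels with no enhancement get PF 0.
#'
#' @param conc_series Concentration `dynamic_series`.
#' @param aif,times,reg,method As in [deconvolve_pf()].
#' @param roi Optional `roi_mask` restricting the computation.
#' @return An `image_volume` of PF (ml/min/100 ml); voxels outside `roi` are 0.
#' @export
pf_map <- function(conc_series, aif, times, reg = 0.05,
                   method = c("tsvd", "tikhonov"), roi = NULL) {
  method <- match.arg(method)
  d <- dim(conc_series$data)
  idx <- if (is.null(roi)) seq_len(prod(d[1:3])) else {
    m <- as_mask_array(roi)
    if (!identical(dim(m), d[1:3]))
      stop("alignment error: ROI grid does not match the series grid",
           call. = FALSE)
    which(m)
  }
  op <- aif_operator_svd(aif, times)
  sv <- op$svd
  keep <- sv$d >= reg * sv$d[1]
  if (!any(keep))
    stop("uninformative AIF: all singular values below cutoff", call. = FALSE)
  inv_d <- if (method == "tsvd") ifelse(keep, 1 / sv$d, 0) else
    sv$d / (sv$d^2 + (reg * sv$d[1])^2)
  flat <- matrix(conc_series$data, nrow = prod(d[1:3]), ncol = d[4])
  # h for all voxels at once: V diag(inv_d) U' C
  H <- sv$v %*% (inv_d * crossprod(sv$u, t(flat[idx, , drop = FALSE])))
  pf <- apply(H, 2, max) * 6000
  out <- array(0, dim = d[1:3])
  out[idx] <- pf
  image_volume(out, conc_series$spacing, modality = "MAP",
               units = "ml/min/100ml")
}

# ---- nonlinear fit ----------------------------------------------------------

default_init_grid <- function() {
  expand.grid(PF = c(10, 40, 120), PV = c(2, 8, 20),
              ve = c(5, 20, 40), PS = c(1, 10, 40))
}

#' Fit the two-compartment exchange model to a concentration curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via minpack.lm) of
#' the 2CXM forward model to a tissue concentration curve. The cost surface
#' is multi-modal at coarse temporal sampling, so a coarse multi-start grid
#' is screened by residual sum of squares and the best `n_refine` starts are
#' refined; the lowest-residual refined fit wins. EF and Ktrans are derived
#' from the fitted PF and PS.
#'
#' @param conc_curve Tissue concentration curve (>= 20 frames).
#' @param aif Arterial input curve with non-zero enhancement, same grid.
#' @param times Time grid, seconds.
#' @param init_grid Data frame of starting values (columns PF, PV, ve, PS);
#'   default a 3x3x3x3 grid spanning physiologic ranges.
#' @param lower,upper Box bounds on (PF, PV, ve, PS).
#' @param n_refine Number of screened starts refined by full optimization.
#' @return A `twocxm_fit` object: `params` (`twocxm_params`), `residual_norm`,
#'   `converged`, `degenerate`, `n_iterations`, `n_starts`, `fitted`,
#'   `observed`, `times`.
#' @export
fit_2cxm <- function(conc_curve, aif, times, init_grid = NULL,
                     lower = c(0, 0, 0, 0), upper = c(500, 100, 100, 500),
                     n_refine = 5) {
  conc_curve <- as.numeric(conc_curve)
  n <- length(conc_curve)
  if (n < 20) stop("need at least 20 frames to fit the 2CXM", call. = FALSE)
  if (length(aif) != n || length(times) != n)
    stop("conc_curve, aif and times must share one grid", call. = FALSE)
  if (max(abs(aif)) == 0)
    stop("AIF has no enhancement; cannot fit", call. = FALSE)
  if (max(abs(conc_curve)) == 0) {
    return(structure(list(
      params = twocxm_params(0, 0, 0, 0), residual_norm = 0,
      converged = TRUE, degenerate = TRUE, n_iterations = 0L,
      n_starts = 0L, fitted = numeric(n), observed = conc_curve,
      times = times), class = "twocxm_fit"))
  }
  if (is.null(init_grid)) init_grid <- default_init_grid()
  fwd <- function(p) twocxm_forward(
    list(PF = p[1], PV = p[2], ve = p[3], PS = p[4]), aif, times)
  resid_fn <- function(p) conc_curve - fwd(p)
  sse <- apply(as.matrix(init_grid), 1, function(p) sum(resid_fn(p)^2))
  ord <- order(sse)[seq_len(min(n_refine, nrow(init_grid)))]
  best <- NULL
  for (i in ord) {
    p0 <- pmin(pmax(as.numeric(init_grid[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn)
      best <- list(par = fit$par, rn = rn, info = fit$info,
                   niter = fit$niter)
  }
  if (is.null(best)) {
    return(structure(list(
      params = twocxm_params(0, 0, 0, 0), residual_norm = Inf,
      converged = FALSE, degenerate = TRUE, n_iterations = 0L,
      n_starts = length(ord), fitted = numeric(n), observed = conc_curve,
      times = times), class = "twocxm_fit"))
  }
  p <- pmin(pmax(best$par, lower), upper)
  structure(list(
    params = twocxm_params(p[1], p[2], p[3], p[4]),
    residual_norm = best$rn,
    converged = best$info %in% 1:4,
    degenerate = FALSE,
    n_iterations = best$niter,
    n_starts = length(ord),
    fitted = fwd(p),
    observed = conc_curve,
    times = times), class = "twocxm_fit")
}

#' @export
print.twocxm_fit <- function(x, ...) {
  cat("<twocxm_fit>\n")
  print(x$params)
  cat(sprintf("  residual norm %.4g, converged: %s, %d iterations, %d starts\n",
              x$residual_norm, x$converged, x$n_iterations, x$n_starts))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 2CXM fit
#'
#' @param x A `twocxm_fit`.
#' @param ... Unused.
#' @return One row per parameter (four primary, two derived) with columns
#'   `term`, `estimate`, `unit`, `derived`.
#' @method tidy twocxm_fit
#' @export
tidy.twocxm_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("PF", "PV", "ve", "PS", "EF", "Ktrans"),
    estimate = c(p$PF, p$PV, p$ve, p$PS, p$EF, p$Ktrans),
    unit = c("ml/min/100ml", "ml/100ml", "ml/100ml", "ml/min/100ml",
             "%", "1/min"),
    derived = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
}

#' @rdname tidy.twocxm_fit
#' @return `glance()`: a one-row tibble with fit diagnostics.
#' @method glance twocxm_fit
#' @export
glance.twocxm_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, converged = x$converged,
                 degenerate = x$degenerate, n_iterations = x$n_iterations,
                 n_starts = x$n_starts, n_frames = length(x$observed))
}
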