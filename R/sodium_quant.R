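#' Normalize a sodium image by a uniform-phantom reference
#'
#' Corrects the multiplicative B1 reception/excitation profile by dividing
#' the image voxel-wise by a Gaussian-smoothed image of a large uniform
#' phantom filling the coil. The smoothed reference is rescaled so its mean
#' over its own support is 1, which preserves the global intensity scale
#' (any residual gain is absorbed by the phantom calibration). Voxels where
#' the smoothed reference falls below `floor_rel` times its maximum are
#' marked invalid (`NA`).
#'
#' @param image a [volume_map] to correct.
#' @param reference a [volume_map] of the uniform phantom, same grid.
#' @param smoothing_fwhm_mm Gaussian FWHM applied to the reference, mm.
#' @param floor_rel relative support floor on the smoothed reference.
#' @return Corrected [volume_map]; attribute `n_invalid` counts masked
#'   voxels.
#' @export
b1_normalize <- function(image, reference, smoothing_fwhm_mm = 15,
                         floor_rel = 0.05) {
  if (!identical(dim(image), dim(reference)))
    stop("image and reference grids differ")
  if (smoothing_fwhm_mm < 0) stop("smoothing FWHM must be >= 0")
  ref <- unclass(reference); attributes(ref) <- list(dim = dim(reference))
  ref[is.na(ref)] <- 0
  if (all(ref == 0)) stop("reference image is identically zero")
  sm <- unclass(gaussian_smooth(rewrap(ref, reference), smoothing_fwhm_mm))
  support <- sm > floor_rel * max(sm)
  scale <- mean(sm[support])
  out <- unclass(image) / (sm / scale)
  out[!support] <- NA_real_
  res <- rewrap(out, image)
  attr(res, "n_invalid") <- sum(!support)
  res
}

#' Point spread function of the T2-weighted center-out acquisition
#'
#' Models the blurring of a center-out ultra-short-TE sodium acquisition in
#' the image domain: a Cartesian k-space grid is weighted by the
#' biexponential transverse decay evaluated at the time each sample is
#' read, \eqn{t(k) = TE + T_{ro} |k| / k_{max}} (radially linear
#' center-out timing), and inverse Fourier transformed. The short T2
#' component suppresses high spatial frequencies and broadens the kernel.
#'
#' The kernel is returned with its absolute gain: its sum equals the
#' k-space weight at the origin, \eqn{f e^{-TE/T_{2s}} + (1-f)
#' e^{-TE/T_{2l}}}. [deconvolve()] renormalizes to unit mass internally, so
#' the echo-time decay is corrected once, by [lambda_factor()].
#'
#' @param shape grid size, single integer or length 3.
#' @param acq an [acq_spec]; `readout_ms` and `TE` set the time map.
#' @param relax a [relax_times].
#' @return A `psf_kernel`: list with `kernel` (3D array, centre at
#'   `floor(shape/2)+1`), `voxel_mm`, `acq`, `relax`.
#' @export
compute_psf <- function(shape, acq, relax) {
  stopifnot(inherits(acq, "acq_spec"), inherits(relax, "relax_times"))
  if (acq$readout_ms <= 0) stop("readout duration must be positive")
  d <- rep_len(as.integer(shape), 3L)
  # normalized k-space radius; per-axis indices span [-1, 1)
  kr <- 0
  for (ax in 1:3) {
    k <- if (d[ax] == 1L) 0 else fft_freq(d[ax]) / floor(d[ax] / 2)
    kr <- kr + outer_axis(k, d, ax)^2
  }
  kr <- sqrt(kr)
  t_k <- acq$TE[1] + acq$readout_ms * kr / max(kr[kr > 0], 1)
  f <- relax$fast_fraction
  w <- f * exp(-t_k / relax$T2s) + (1 - f) * exp(-t_k / relax$T2l)
  kern <- Re(stats::fft(w, inverse = TRUE)) / prod(d)
  kern <- fftshift3(kern)
  structure(list(kernel = kern, voxel_mm = acq$voxel_mm, acq = acq,
                 relax = relax),
            class = "psf_kernel")
}

#' @export
print.psf_kernel <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("psf_kernel: %s grid, sum = %.4g, FWHM = %s voxels\n",
              paste(d, collapse = "x"), sum(x$kernel),
              paste(signif(psf_fwhm(x), 3), collapse = " x ")))
  invisible(x)
}

# circular shift putting the DC sample at the grid centre
fftshift3 <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1)
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

ifftshift3 <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + ceiling(n / 2)) %% n) + 1)
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Full width at half maximum of a PSF kernel
#'
#' Measured by linear interpolation along each axis profile through the
#' kernel centre, in voxel units.
#'
#' @param psf a `psf_kernel`.
#' @return Length-3 numeric vector, voxels.
#' @export
psf_fwhm <- function(psf) {
  k <- psf$kernel
  d <- dim(k)
  ctr <- floor(d / 2) + 1
  vapply(1:3, function(ax) {
    prof <- switch(ax, k[, ctr[2], ctr[3]], k[ctr[1], , ctr[3]],
                   k[ctr[1], ctr[2], ])
    profile_fwhm(prof, ctr[ax])
  }, numeric(1))
}

# FWHM of a 1D profile peaked at index ctr, by linear interpolation.
profile_fwhm <- function(prof, ctr) {
  half <- prof[ctr] / 2
  right <- prof[ctr:length(prof)]
  i <- which(right < half)[1]
  if (is.na(i)) return(Inf)
  # crossing between i-1 and i
  x_r <- (i - 1) + (right[i - 1] - half) / (right[i - 1] - right[i]) - 1
  left <- prof[ctr:1]
  j <- which(left < half)[1]
  x_l <- (j - 1) + (left[j - 1] - half) / (left[j - 1] - left[j]) - 1
  x_r + x_l
}

# FFT convolution of a 3D array with a centred kernel (periodic boundary).
convolve_psf <- function(arr, kern, conj = FALSE) {
  otf <- stats::fft(ifftshift3(kern))
  if (conj) otf <- Conj(otf)
  Re(stats::fft(stats::fft(arr) * otf, inverse = TRUE)) / length(arr)
}

#' Blur a map with a PSF kernel
#'
#' Forward model counterpart of [deconvolve()]: circular FFT convolution
#' with the same nonnegative, unit-mass blur operator that
#' Richardson-Lucy models — the kernel's small negative ringing is
#' clipped and the result renormalized, exactly as in [deconvolve()].
#' Absolute signal scaling is carried by the lambda factor, not the blur.
#'
#' @param x a [volume_map] matching the kernel grid.
#' @param psf a `psf_kernel`.
#' @return Blurred [volume_map].
#' @export
apply_psf <- function(x, psf) {
  k <- rl_kernel(psf$kernel)
  if (!identical(dim(x), dim(k))) stop("map and PSF grids differ")
  arr <- unclass(x); attributes(arr) <- list(dim = dim(x))
  rewrap(convolve_psf(arr, k), x)
}

# The nonnegative unit-mass blur operator shared by the forward model and
# Richardson-Lucy: negative ringing clipped, renormalized.
rl_kernel <- function(k) {
  k[k < 0] <- 0
  k / sum(k)
}

#' Richardson-Lucy deconvolution
#'
#' Iterative restoration of a nonnegative image blurred by a known PSF.
#' The kernel is clipped of any tiny negative ringing (an error if the
#' negative mass exceeds `neg_tol` of the total) and renormalized to unit
#' sum, so the restoration conserves total intensity.
#'
#' @param image nonnegative [volume_map]; `NA` voxels are treated as 0 and
#'   restored as `NA`.
#' @param psf a `psf_kernel` on the same grid.
#' @param iterations number of multiplicative updates (>= 1).
#' @param neg_tol maximum tolerated fraction of negative kernel mass.
#' @return Restored [volume_map]; attribute `clipped_kernel_mass` records
#'   the negative mass removed from the kernel.
#' @export
deconvolve <- function(image, psf, iterations = 10, neg_tol = 0.1) {
  if (iterations < 1) stop("iterations must be >= 1")
  k <- psf$kernel
  if (!identical(dim(image), dim(k))) stop("image and PSF grids differ")
  neg <- -sum(k[k < 0])
  if (neg > neg_tol * sum(abs(k)))
    stop("PSF has substantial negative mass (", signif(neg, 3),
         "); not a valid Richardson-Lucy kernel")
  k <- rl_kernel(k)
  arr <- unclass(image); attributes(arr) <- list(dim = dim(image))
  na <- is.na(arr)
  arr[na] <- 0
  if (any(arr < 0)) stop("image must be nonnegative")
  eps <- .Machine$double.eps * max(arr)
  est <- arr + eps
  for (i in seq_len(iterations)) {
    pred <- convolve_psf(est, k)
    ratio <- arr / pmax(pred, eps)
    est <- est * pmax(convolve_psf(ratio, k, conj = TRUE), 0)
  }
  est[na] <- NA_real_
  out <- rewrap(est, image)
  attr(out, "clipped_kernel_mass") <- neg
  out
}

#' Fit the phantom calibration line
#'
#' Ordinary least-squares line through (concentration, corrected mean
#' signal) pairs from the calibration gels. Signals must already be B1-
#' normalized, deconvolved and divided by each gel's own lambda factor.
#'
#' @param concentration_mM known gel concentrations (>= 2 distinct).
#' @param signal corrected mean gel signals.
#' @return A `calibration_curve`: slope (signal per mM), intercept,
#'   `r_squared`, and the pairs.
#' @export
fit_calibration <- function(concentration_mM, signal) {
  if (length(concentration_mM) != length(signal))
    stop("concentration and signal lengths differ")
  if (length(unique(concentration_mM)) < 2L)
    stop("need >= 2 distinct concentrations")
  fit <- stats::lm(signal ~ concentration_mM)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 pairs = data.frame(concentration_mM = concentration_mM,
                                    signal = signal)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration: signal = %.4g * C + %.4g  (R^2 = %.4f, %d gels)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$pairs)))
  invisible(x)
}

#' Convert a corrected sodium image to a TSC map
#'
#' Inverts the calibration line after relaxation correction:
#' \eqn{TSC = (S / \lambda - b) / a} per voxel, with `a`, `b` the
#' calibration slope and intercept and \eqn{\lambda} evaluated for the
#' tissue relaxation times. The image must already be B1-normalized and
#' deconvolved. Negative concentrations are clipped to 0 and counted.
#'
#' @param image corrected sodium [volume_map].
#' @param cal a `calibration_curve` with positive slope.
#' @param tissue_relax [relax_times] of the imaged tissue.
#' @param acq the sodium [acq_spec].
#' @return TSC [volume_map] in mM; attribute `n_clipped` counts
#'   negative voxels clipped to zero.
#' @export
signal_to_tsc <- function(image, cal, tissue_relax, acq) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (!is.finite(cal$slope) || cal$slope <= 0)
    stop("calibration slope must be positive")
  lam <- lambda_factor(tissue_relax, acq)
  tsc <- (unclass(image) / lam - cal$intercept) / cal$slope
  n_clip <- sum(tsc < 0, na.rm = TRUE)
  tsc[!is.na(tsc) & tsc < 0] <- 0
  out <- rewrap(tsc, image)
  attr(out, "n_clipped") <- n_clip
  out
}
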