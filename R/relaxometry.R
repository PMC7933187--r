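#' Sodium relaxation times
#'
#' Container for the global sodium relaxation parameters used by the
#' correction factor and the PSF model. Transverse relaxation is treated as
#' purely quadrupolar and biexponential, with a short component `T2s`
#' carrying `fast_fraction` of the signal and a long component `T2l` the
#' rest; the default split is 60:40.
#'
#' @param T1 longitudinal relaxation time, ms.
#' @param T2s short transverse component, ms.
#' @param T2l long transverse component, ms; must satisfy `T2l >= T2s`.
#' @param fast_fraction fraction of the signal decaying with `T2s`, in
#'   `[0, 1]`.
#' @return A `relax_times` object.
#' @examples
#' relax_times()  # breast fibroglandular tissue defaults
#' @export
relax_times <- function(T1 = 37, T2s = 0.5, T2l = 15, fast_fraction = 0.6) {
  if (!is.finite(T1) || T1 <= 0) stop("T1 must be positive")
  if (!is.finite(T2s) || T2s <= 0 || !is.finite(T2l) || T2l <= 0)
    stop("T2 components must be positive")
  if (T2s > T2l) stop("T2s must not exceed T2l")
  if (fast_fraction < 0 || fast_fraction > 1)
    stop("fast_fraction must lie in [0, 1]")
  structure(list(T1 = T1, T2s = T2s, T2l = T2l,
                 fast_fraction = fast_fraction),
            class = "relax_times")
}

#' @export
print.relax_times <- function(x, ...) {
  cat(sprintf(
    "sodium relaxation: T1 = %.3g ms, T2s = %.3g ms, T2l = %.3g ms (%.0f:%.0f)\n",
    x$T1, x$T2s, x$T2l, 100 * x$fast_fraction, 100 * (1 - x$fast_fraction)))
  invisible(x)
}

#' Acquisition parameters
#'
#' Imaging parameters of a (spoiled gradient-echo style) acquisition. For
#' multi-echo proton imaging `TE` may be a vector.
#'
#' @param TR repetition time, ms.
#' @param TE echo time(s), ms.
#' @param flip_deg excitation flip angle, degrees.
#' @param readout_ms duration of the center-out readout, ms; governs the
#'   T2 weighting across k-space and hence the PSF width.
#' @param matrix_size image matrix, single integer or length 3.
#' @param voxel_mm nominal voxel size, mm.
#' @return An `acq_spec` object.
#' @examples
#' acq_spec()  # the sodium FLORET protocol settings
#' @export
acq_spec <- function(TR = 60, TE = 0.2, flip_deg = 80, readout_ms = 10,
                     matrix_size = 64, voxel_mm = 2.8) {
  if (!is.finite(TR) || TR <= 0) stop("TR must be positive")
  if (any(!is.finite(TE)) || any(TE < 0)) stop("TE must be >= 0")
  if (flip_deg <= 0 || flip_deg > 180) stop("flip angle must be in (0, 180]")
  if (readout_ms <= 0) stop("readout duration must be positive")
  matrix_size <- rep_len(as.integer(matrix_size), 3L)
  if (any(matrix_size < 2L)) stop("matrix size must be >= 2")
  structure(list(TR = TR, TE = TE, flip_deg = flip_deg,
                 readout_ms = readout_ms, matrix_size = matrix_size,
                 voxel_mm = rep_len(as.numeric(voxel_mm), 3L)),
            class = "acq_spec")
}

#' @export
print.acq_spec <- function(x, ...) {
  cat(sprintf("acquisition: TR = %.4g ms, TE = %s ms, FA = %.4g deg\n",
              x$TR, paste(signif(x$TE, 4), collapse = "/"), x$flip_deg))
  cat(sprintf("  matrix %s, voxel %s mm, readout %.4g ms\n",
              paste(x$matrix_size, collapse = "x"),
              paste(signif(x$voxel_mm, 4), collapse = "x"), x$readout_ms))
  invisible(x)
}

#' Relaxation correction factor lambda
#'
#' Scales an acquired steady-state sodium signal relative to fully relaxed
#' magnetization:
#' \deqn{\lambda = \frac{1 - e^{-TR/T_1}}{1 - \cos(FA)\, e^{-TR/T_1}}
#'   \left( f\, e^{-TE/T_{2s}} + (1 - f)\, e^{-TE/T_{2l}} \right)}
#' with `f` the fast fraction. Dividing measured intensities by
#' \eqn{\lambda} removes T1 saturation and the transverse decay accrued at
#' the echo time, so that gels or tissues with different relaxation times
#' become comparable on one calibration line.
#'
#' @param relax a [relax_times].
#' @param acq an [acq_spec] with a single TE.
#' @return Dimensionless scalar in `(0, 1]` for flip angles up to 90
#'   degrees.
#' @examples
#' lambda_factor(relax_times(37, 0.5, 15), acq_spec(60, 0.2, 80))
#' @export
lambda_factor <- function(relax, acq) {
  stopifnot(inherits(relax, "relax_times"), inherits(acq, "acq_spec"))
  if (length(acq$TE) != 1L) stop("lambda_factor requires a single TE")
  e1 <- exp(-acq$TR / relax$T1)
  long <- (1 - e1) / (1 - cos(acq$flip_deg * pi / 180) * e1)
  f <- relax$fast_fraction
  trans <- f * exp(-acq$TE / relax$T2s) + (1 - f) * exp(-acq$TE / relax$T2l)
  long * trans
}

# Steady-state longitudinal saturation term shared by lambda_factor and the
# T1 fit model.
sat_term <- function(TR, T1, flip_deg) {
  e1 <- exp(-TR / T1)
  (1 - e1) / (1 - cos(flip_deg * pi / 180) * e1)
}

new_fit_result <- function(estimate, amplitude, residual_norm, converged,
                           flags = character()) {
  structure(list(estimate = estimate, amplitude = amplitude,
                 residual_norm = residual_norm, converged = converged,
                 flags = flags),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  est <- unlist(x$estimate)
  cat("relaxation fit:", paste(sprintf("%s = %.4g", names(est), est),
                               collapse = ", "), "\n")
  cat(sprintf("  amplitude %.4g, residual norm %.4g, converged: %s\n",
              x$amplitude, x$residual_norm, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Bounded Levenberg-Marquardt with multiple starts; returns the best
# nls.lm fit or NULL if all starts fail.
multistart_lm <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

#' Fit sodium T1 from a multi-TR series
#'
#' Fits the spoiled steady-state saturation model
#' \eqn{S(TR) = A (1 - e^{-TR/T_1}) / (1 - \cos(FA) e^{-TR/T_1})} to
#' signals acquired at several repetition times. The flip-angle term is
#' retained so that the fitted T1 is self-consistent with the first factor
#' of [lambda_factor()].
#'
#' @param TR_ms repetition times, ms (at least 3 distinct values).
#' @param signal nonnegative signal intensities, same length.
#' @param flip_deg flip angle used for the series, degrees.
#' @return A `relax_fit` with `estimate$T1` and amplitude. Non-convergence
#'   or a non-identifiable (flat) series is flagged, not an error.
#' @export
fit_t1_mono <- function(TR_ms, signal, flip_deg = 80) {
  if (length(unique(TR_ms)) < 3L) stop("need >= 3 distinct TR values")
  if (length(signal) != length(TR_ms)) stop("TR and signal lengths differ")
  if (any(signal < 0)) stop("signals must be nonnegative")
  smax <- max(signal)
  if (smax <= 0 || stats::sd(signal) < 1e-12 * max(smax, 1)) {
    return(new_fit_result(list(T1 = NA_real_), NA_real_, 0, FALSE,
                          "non-identifiable: constant signal"))
  }
  resid_fn <- function(p) {
    p["A"] * sat_term(TR_ms, p["T1"], flip_deg) - signal
  }
  span <- range(TR_ms)
  starts <- lapply(exp(seq(log(span[1] / 2), log(span[2] * 2), length.out = 3)),
                   function(t1) c(A = smax, T1 = t1))
  fit <- multistart_lm(resid_fn, starts,
                       lower = c(A = 0, T1 = 1e-3),
                       upper = c(A = 100 * smax, T1 = 100 * span[2]))
  if (is.null(fit)) {
    return(new_fit_result(list(T1 = NA_real_), NA_real_, Inf, FALSE,
                          "optimizer failure"))
  }
  p <- stats::coef(fit)
  flags <- character()
  conv <- fit$info %in% 1:4
  if (!conv) flags <- "did not converge"
  if (p["T1"] >= 99 * span[2]) {
    conv <- FALSE
    flags <- c(flags, "non-identifiable: T1 at bound (series too flat)")
  }
  new_fit_result(list(T1 = unname(p["T1"])), unname(p["A"]),
                 sqrt(fit$deviance), conv, flags)
}

#' Fit biexponential sodium T2 from a multi-TE series
#'
#' Fits \eqn{S(TE) = A (f e^{-TE/T_{2s}} + (1-f) e^{-TE/T_{2l}})} with the
#' constraint \eqn{T_{2s} \le T_{2l}} and \eqn{f \in [0,1]}. The fast
#' fraction can be fixed (default free) to the quadrupolar 0.6 value.
#'
#' @param TE_ms echo times, ms (at least 5 distinct values when `f` is
#'   free, spanning both decay scales).
#' @param signal signal intensities, same length.
#' @param fix_fraction if not `NULL`, fix the fast fraction at this value
#'   and fit only `A`, `T2s`, `T2l`.
#' @return A `relax_fit` with `estimate$T2s`, `estimate$T2l`,
#'   `estimate$fast_fraction`. A collapse of the two components (equal
#'   T2s/T2l or a boundary fraction) is flagged as effectively
#'   monoexponential.
#' @export
fit_t2_biexp <- function(TE_ms, signal, fix_fraction = NULL) {
  n_par <- if (is.null(fix_fraction)) 4L else 3L
  if (length(unique(TE_ms)) < max(n_par + 1L, 5L))
    stop("need >= ", max(n_par + 1L, 5L), " distinct TE values")
  if (length(signal) != length(TE_ms)) stop("TE and signal lengths differ")
  if (!is.null(fix_fraction) &&
      (fix_fraction < 0 || fix_fraction > 1))
    stop("fix_fraction must lie in [0, 1]")
  smax <- max(abs(signal))
  te_pos <- TE_ms[TE_ms > 0]
  tlo <- max(min(te_pos) / 10, 1e-4)
  thi <- max(TE_ms) * 10
  model <- function(p) {
    f <- if (is.null(fix_fraction)) p["f"] else fix_fraction
    p["A"] * (f * exp(-TE_ms / p["T2s"]) + (1 - f) * exp(-TE_ms / p["T2l"]))
  }
  resid_fn <- function(p) model(p) - signal
  grid <- exp(seq(log(tlo * 2), log(thi / 2), length.out = 3))
  starts <- list()
  for (ts in grid[1:2]) for (tl in grid[2:3]) {
    if (tl <= ts) next
    p0 <- c(A = smax, T2s = ts, T2l = tl)
    if (is.null(fix_fraction)) p0 <- c(p0, f = 0.5)
    starts <- c(starts, list(p0))
  }
  lower <- c(A = 0, T2s = tlo, T2l = tlo)
  upper <- c(A = 100 * smax, T2s = thi, T2l = thi)
  if (is.null(fix_fraction)) {
    lower <- c(lower, f = 0); upper <- c(upper, f = 1)
  }
  fit <- multistart_lm(resid_fn, starts, lower, upper)
  if (is.null(fit)) {
    return(new_fit_result(list(T2s = NA_real_, T2l = NA_real_,
                               fast_fraction = NA_real_),
                          NA_real_, Inf, FALSE, "optimizer failure"))
  }
  p <- stats::coef(fit)
  # enforce the T2s <= T2l labelling convention
  f <- if (is.null(fix_fraction)) unname(p["f"]) else fix_fraction
  t2s <- unname(p["T2s"]); t2l <- unname(p["T2l"])
  if (t2s > t2l) { tmp <- t2s; t2s <- t2l; t2l <- tmp; f <- 1 - f }
  flags <- character()
  if (t2l / t2s < 1.05 || f < 0.01 || f > 0.99)
    flags <- "effectively monoexponential"
  new_fit_result(list(T2s = t2s, T2l = t2l, fast_fraction = f),
                 unname(p["A"]), sqrt(fit$deviance), fit$info %in% 1:4,
                 flags)
}
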