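#' IDEAL-style water/fat separation from multi-echo complex data
#'
#' Per voxel, estimates the B0 field-map offset and solves the linear
#' single-peak water/fat system from three or more complex echoes. The
#' offset is found by a coarse grid search over candidate frequencies
#' (robust against water/fat swaps) refined by parabolic interpolation of
#' the residual around the grid minimum; the field map is then
#' Gaussian-smoothed and the water/fat amplitudes re-solved at the
#' smoothed offset. The water fraction is
#' computed from the separated magnitudes.
#'
#' @param echoes list of complex [volume_map]s, one per echo.
#' @param te_ms echo times, ms (distinct, same length as `echoes`).
#' @param fat_shift_ppm single-peak fat chemical shift, ppm.
#' @param field_T main field strength, Tesla.
#' @param psi_range_hz search interval for the field offset, Hz.
#' @param psi_step_hz grid step of the coarse search, Hz.
#' @param smooth_fwhm_mm field-map smoothing FWHM, mm (0 disables).
#' @param mask optional logical array restricting the computation; voxels
#'   outside are returned invalid.
#' @param signal_floor relative magnitude floor below which a voxel is
#'   considered empty and flagged invalid.
#' @return A `waterfat_result`: list with `water`, `fat` (magnitude
#'   [volume_map]s), `field_hz`, `wf` (water fraction in `[0, 1]`, `NA`
#'   where empty), `residual`, `n_flagged`.
#' @export
ideal_waterfat <- function(echoes, te_ms, fat_shift_ppm = -3.4, field_T = 7,
                           psi_range_hz = c(-150, 150), psi_step_hz = 10,
                           smooth_fwhm_mm = 10, mask = NULL,
                           signal_floor = 0.02) {
  if (length(echoes) < 3L) stop("need >= 3 echoes")
  if (length(te_ms) != length(echoes)) stop("one TE per echo required")
  if (anyDuplicated(te_ms)) stop("TEs must be distinct")
  d <- dim(echoes[[1]])
  vox <- voxel_mm(echoes[[1]])
  ne <- length(echoes)
  S <- vapply(echoes, function(e) as.complex(unclass(e)), complex(prod(d)))
  mag <- sqrt(rowSums(Mod(S)^2))
  keep <- mag > signal_floor * max(mag)
  if (!is.null(mask)) keep <- keep & as.logical(mask)
  idx <- which(keep)
  Sk <- S[idx, , drop = FALSE]

  fat_hz <- fat_shift_ppm * 1e-6 * 42.577478518e6 * field_T
  te_s <- te_ms * 1e-3
  B <- cbind(rep(1 + 0i, ne), exp(2i * pi * fat_hz * te_s))  # ne x 2
  # least-squares solve matrix for the demodulated system (fixed in psi)
  BtB_inv_Bt <- solve(Conj(t(B)) %*% B, Conj(t(B)))           # 2 x ne

  res_at <- function(psi) {
    Dm <- Sk * matrix(exp(-2i * pi * psi * te_s), nrow(Sk), ne, byrow = TRUE)
    Wf <- Dm %*% t(BtB_inv_Bt)                                # V x 2
    fitted <- Wf %*% t(B)
    rowSums(Mod(Dm - fitted)^2)
  }
  grid <- seq(psi_range_hz[1], psi_range_hz[2], by = psi_step_hz)
  res_grid <- vapply(grid, res_at, numeric(length(idx)))
  best <- max.col(-res_grid, ties.method = "first")
  psi <- grid[best]
  # parabolic refinement within one grid cell (residual is smooth in psi)
  interior <- best > 1L & best < length(grid)
  ii <- which(interior)
  if (length(ii)) {
    n <- length(idx)
    rm_ <- res_grid[ii + n * (best[ii] - 2L)]
    r0 <- res_grid[ii + n * (best[ii] - 1L)]
    rp <- res_grid[ii + n * best[ii]]
    denom <- rm_ - 2 * r0 + rp
    delta <- ifelse(denom > 0, 0.5 * (rm_ - rp) / denom, 0)
    psi[ii] <- psi[ii] + pmin(pmax(delta, -1), 1) * psi_step_hz
  }

  field <- array(NA_real_, d)
  field[idx] <- psi
  if (smooth_fwhm_mm > 0 && length(idx)) {
    field <- unclass(gaussian_smooth(volume_map(field, vox), smooth_fwhm_mm))
  }
  psi_final <- field[idx]
  Wf <- solve_wf(Sk, psi_final, te_s, B, BtB_inv_Bt)
  resid <- res_psi_vec(Sk, psi_final, te_s, B, BtB_inv_Bt)

  water <- array(NA_real_, d); fat <- array(NA_real_, d)
  wfmap <- array(NA_real_, d); rr <- array(NA_real_, d)
  water[idx] <- Mod(Wf[, 1]); fat[idx] <- Mod(Wf[, 2])
  tot <- Mod(Wf[, 1]) + Mod(Wf[, 2])
  wfv <- ifelse(tot > 0, Mod(Wf[, 1]) / tot, NA_real_)
  wfmap[idx] <- pmin(pmax(wfv, 0), 1)
  rr[idx] <- resid
  # non-convergent voxels: residual out of proportion to the signal
  flagged <- resid > 0.25 * rowSums(Mod(Sk)^2)
  structure(list(water = volume_map(water, vox),
                 fat = volume_map(fat, vox),
                 field_hz = volume_map(field, vox),
                 wf = volume_map(wfmap, vox),
                 residual = volume_map(rr, vox),
                 n_flagged = sum(flagged),
                 n_empty = prod(d) - length(idx)),
            class = "waterfat_result")
}

# water/fat complex amplitudes at per-voxel offsets psi
solve_wf <- function(Sk, psi, te_s, B, BtB_inv_Bt) {
  ne <- length(te_s)
  Dm <- Sk * exp(-2i * pi * outer(psi, te_s))
  Dm %*% t(BtB_inv_Bt)
}

res_psi_vec <- function(Sk, psi, te_s, B, BtB_inv_Bt) {
  Dm <- Sk * exp(-2i * pi * outer(psi, te_s))
  Wf <- Dm %*% t(BtB_inv_Bt)
  rowSums(Mod(Dm - Wf %*% t(B))^2)
}

#' @export
print.waterfat_result <- function(x, ...) {
  cat("water/fat separation:\n")
  wf <- x$wf[!is.na(x$wf)]
  cat(sprintf("  WF over %d voxels: median %.3f [%.3f, %.3f]; %d flagged, %d empty\n",
              length(wf), stats::median(wf), min(wf), max(wf),
              x$n_flagged, x$n_empty))
  invisible(x)
}

#' Extracellular volume fraction from pre/post-contrast T1
#'
#' Normalizes the contrast-induced relaxation-rate change in each voxel by
#' the mean change in a reference muscle ROI of known ECV:
#' \deqn{ECV = ECV_{ref} \frac{R_{1,post} - R_{1,pre}}
#'   {\overline{R_{1,post,ref} - R_{1,pre,ref}}}}
#' The contrast relaxivity and dose cancel in the ratio. Values are
#' clipped to `[0, 1]` with counts recorded.
#'
#' @param t1_pre,t1_post T1 [volume_map]s in ms (positive where valid).
#' @param muscle_mask logical array marking the reference muscle ROI.
#' @param ecv_ref ECV of the reference tissue (pectoral muscle default
#'   0.12).
#' @return ECV [volume_map]; attributes `n_clipped_low`/`n_clipped_high`
#'   count clipped voxels and `muscle_dr1` records the reference
#'   denominator (1/ms).
#' @export
compute_ecv <- function(t1_pre, t1_post, muscle_mask, ecv_ref = 0.12) {
  if (!identical(dim(t1_pre), dim(t1_post)))
    stop("T1 map grids differ")
  if (ecv_ref <= 0 || ecv_ref >= 1) stop("ecv_ref must be in (0, 1)")
  muscle_mask <- as.logical(muscle_mask)
  if (!any(muscle_mask)) stop("muscle ROI is empty")
  pre <- unclass(t1_pre); post <- unclass(t1_post)
  ok <- !is.na(pre) & !is.na(post) & pre > 0 & post > 0
  dr1 <- array(NA_real_, dim(pre))
  dr1[ok] <- 1 / post[ok] - 1 / pre[ok]
  ref <- mean(dr1[muscle_mask & ok], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0)
    stop("no reference uptake: muscle Delta-R1 is not positive")
  ecv <- ecv_ref * dr1 / ref
  n_lo <- sum(ecv < 0, na.rm = TRUE)
  n_hi <- sum(ecv > 1, na.rm = TRUE)
  ecv[!is.na(ecv) & ecv < 0] <- 0
  ecv[!is.na(ecv) & ecv > 1] <- 1
  out <- rewrap(ecv, t1_pre)
  attr(out, "n_clipped_low") <- n_lo
  attr(out, "n_clipped_high") <- n_hi
  attr(out, "muscle_dr1") <- ref
  out
}

#' Percent signal enhancement over a dynamic series
#'
#' `100 * (S(t) - S0) / S0` with `S0` the mean ROI signal over the
#' baseline time points acquired before contrast injection.
#'
#' @param series list of [volume_map]s (or 3D arrays), one per time point.
#' @param roi logical mask.
#' @param n_baseline number of pre-injection time points (>= 1).
#' @return Numeric vector of percent enhancement, one value per time
#'   point.
#' @export
enhancement_curve <- function(series, roi, n_baseline = 4) {
  if (n_baseline < 1) stop("need >= 1 baseline time point")
  if (length(series) < n_baseline) stop("series shorter than baseline")
  roi <- as.logical(roi)
  means <- vapply(series, function(v) mean(unclass(v)[roi], na.rm = TRUE),
                  numeric(1))
  s0 <- mean(means[seq_len(n_baseline)])
  if (!is.finite(s0) || s0 <= 0) stop("baseline signal must be positive")
  100 * (means - s0) / s0
}
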