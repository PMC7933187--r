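#' Default tissue parameters of the breast digital phantom
#'
#' Per-label ground truth used by [make_breast_phantom()]: intracellular
#' sodium concentration, extracellular volume fraction, water fraction and
#' pre-contrast proton T1 for fat, fibroglandular tissue, tumor and
#' pectoral muscle. The stored TSC of each label follows from the
#' three-compartment model with `C_EC` = 140 mM and a fat-compartment
#' sodium concentration of 10 mM; the tumor values (C_IC 30 mM, ECV 0.25,
#' WF 0.9) sit in the range reported for malignant breast lesions, and
#' muscle is the ECV reference tissue at 0.12.
#'
#' @param c_ec_mM extracellular sodium concentration, mM.
#' @param c_fat_mM fat-compartment sodium concentration, mM.
#' @return data.frame with one row per label.
#' @export
breast_tissue_params <- function(c_ec_mM = 140, c_fat_mM = 10) {
  p <- data.frame(
    label = 1:4,
    name = c("fat", "fibroglandular", "tumor", "muscle"),
    c_ic_mM = c(10, 15, 30, 12),
    ecv = c(0.02, 0.10, 0.25, 0.12),
    wf = c(0.05, 0.85, 0.90, 0.80),
    t1_pre_ms = c(600, 1600, 1700, 1400))
  p$tsc_mM <- p$ecv * c_ec_mM + (p$wf - p$ecv) * p$c_ic_mM +
    (1 - p$wf) * c_fat_mM
  p
}

#' Simulate a breast-like multinuclear acquisition with known truth
#'
#' Builds a half-ellipsoid breast (fat shell around a fibroglandular core
#' with an embedded tumor sphere) resting on a pectoral muscle slab, then
#' forward-simulates every pipeline input:
#' \itemize{
#'   \item sodium image: truth TSC times the lambda factor, blurred by the
#'     acquisition PSF, modulated by a smooth B1 bias, Rician noise;
#'   \item multi-echo complex GRE: single-peak water/fat signal model at
#'     the configured chemical shift with a smooth field map and complex
#'     Gaussian noise, on a proton grid `upsample` times finer;
#'   \item pre/post-contrast T1 maps: per-label baseline T1, with the
#'     post-contrast relaxation rate increased in proportion to the label
#'     ECV (the muscle label carries `ecv_ref` exactly, anchoring Eq.-style
#'     normalization);
#'   \item the muscle ROI mask.
#' }
#'
#' @param params per-label truth, as [breast_tissue_params()]; must
#'   include fat, fibroglandular, tumor and muscle rows.
#' @param acq sodium [acq_spec] (matrix, voxel, TR/TE/FA, readout).
#' @param tissue_relax sodium [relax_times] shared by all tissue labels.
#' @param upsample proton grid refinement factor relative to the sodium
#'   grid.
#' @param snr sodium SNR: mean noiseless signal over the body divided by
#'   the Rician channel SD (`noise_sigma` overrides).
#' @param noise_sigma explicit sodium channel SD, or `NULL`.
#' @param proton_snr SNR of the multi-echo GRE magnitude.
#' @param t1_noise_ms Gaussian SD added to the T1 maps, ms.
#' @param te_ms proton echo times, ms.
#' @param fat_shift_ppm fat chemical shift, ppm.
#' @param field_T main field strength, Tesla.
#' @param ecv_ref ECV assigned to the muscle reference label.
#' @param c_ec_mM,c_fat_mM compartment concentrations, mM.
#' @param b1 sodium B1 bias descriptor (list: `type`, `strength`).
#' @param use_psf blur the sodium image with the acquisition PSF.
#' @param seed integer seed.
#' @return List with `sodium`, `b1`, `sigma`, `echoes` (list of complex
#'   [volume_map]s), `te_ms`, `field_hz` (true field map), `t1_pre`,
#'   `t1_post`, `muscle_mask`, `truth` ([phantom_truth] on the proton
#'   grid), `labels_sodium` (labels block-reduced to the sodium grid),
#'   and the acquisition/relaxation objects used.
#' @export
make_breast_phantom <- function(params = breast_tissue_params(),
                                acq = acq_spec(),
                                tissue_relax = relax_times(),
                                upsample = 2L,
                                snr = 20, noise_sigma = NULL,
                                proton_snr = 50,
                                t1_noise_ms = 20,
                                te_ms = c(2.04, 2.24, 2.44, 2.64),
                                fat_shift_ppm = -3.4, field_T = 7,
                                ecv_ref = 0.12,
                                c_ec_mM = 140, c_fat_mM = 10,
                                b1 = list(type = "quadratic", strength = 0.15),
                                use_psf = TRUE,
                                seed = 1L) {
  need <- c("fat", "fibroglandular", "tumor", "muscle")
  if (!all(need %in% params$name))
    stop("params must include labels: ", paste(need, collapse = ", "),
         " (the muscle label anchors the ECV reference)")
  params$ecv[params$name == "muscle"] <- ecv_ref
  params$tsc_mM <- params$ecv * c_ec_mM + (params$wf - params$ecv) *
    params$c_ic_mM + (1 - params$wf) * c_fat_mM

  ds <- acq$matrix_size
  upsample <- as.integer(upsample)
  dp <- ds * upsample
  vox_p <- acq$voxel_mm / upsample

  # --- geometry on the fine (proton) grid -------------------------------
  g <- coord_grids(dp)
  labels <- array(0L, dp)
  z_slab <- c(round(0.06 * dp[3]), round(0.16 * dp[3]))
  labels[g$z >= z_slab[1] & g$z <= z_slab[2] &
           abs(g$x - (dp[1] + 1) / 2) < 0.42 * dp[1] &
           abs(g$y - (dp[2] + 1) / 2) < 0.42 * dp[2]] <- 4L
  ctr <- c((dp[1] + 1) / 2, (dp[2] + 1) / 2, z_slab[2])
  semi <- c(0.36 * dp[1], 0.36 * dp[2], 0.62 * dp[3])
  ell <- function(s) ((g$x - ctr[1]) / (semi[1] * s))^2 +
    ((g$y - ctr[2]) / (semi[2] * s))^2 +
    ((g$z - ctr[3]) / (semi[3] * s))^2 <= 1 & g$z >= ctr[3]
  breast <- ell(1)
  labels[breast & labels == 0L] <- 1L                   # fat shell
  core <- ell(0.72)
  labels[core & labels == 1L] <- 2L                     # fibroglandular
  tum_ctr <- ctr + c(0.12 * dp[1], 0, 0.22 * dp[3])
  tum <- sphere_mask(g, tum_ctr, 0.09 * min(dp))
  labels[tum & labels == 2L] <- 3L                      # tumor

  truth <- phantom_truth(labels, params, vox_p, c_ec_mM, c_fat_mM, seed)
  labels_sodium <- block_mode(labels, upsample)

  # --- sodium forward model (sodium grid) -------------------------------
  conc <- array(0, ds)
  tsc_by_label <- c(0, params$tsc_mM[order(params$label)])
  conc[] <- tsc_by_label[labels_sodium + 1L]
  relax_by_label <- stats::setNames(rep(list(tissue_relax), 4L),
                                    as.character(1:4))
  bias <- b1_bias_field(ds, acq$voxel_mm, b1$type, b1$strength, seed)
  if (is.null(noise_sigma)) {
    noise_sigma <- mean(conc[labels_sodium > 0L]) *
      lambda_factor(tissue_relax, acq) / snr
  }
  sodium <- forward_sodium(conc, labels_sodium, relax_by_label, acq, bias,
                           noise_sigma, seed, use_psf,
                           psf_relax = tissue_relax)

  # --- multi-echo proton forward model (proton grid) --------------------
  wf_map <- unclass(label_map(truth, "wf"))
  rho <- array(0, dp); rho[labels > 0L] <- 100
  water <- rho * wf_map
  fat <- rho * (1 - wf_map)
  fat_hz <- fat_shift_ppm * 1e-6 * 42.577478518e6 * field_T
  field_hz <- 30 * (g$x - (dp[1] + 1) / 2) / dp[1]     # smooth, +/-15 Hz
  rng <- local_rng(seed + 1L)
  p_sigma <- mean(rho[labels > 0L]) / proton_snr / sqrt(2)
  echoes <- lapply(te_ms, function(te) {
    s <- (water + fat * exp(2i * pi * fat_hz * te * 1e-3)) *
      exp(2i * pi * field_hz * te * 1e-3)
    s <- s + complex(real = array(rng$rnorm(prod(dp), sd = p_sigma), dp),
                     imaginary = array(rng$rnorm(prod(dp), sd = p_sigma), dp))
    volume_map(array(s, dp), vox_p)
  })

  # --- T1 maps (proton grid) --------------------------------------------
  t1_by_label <- c(NA_real_, params$t1_pre_ms[order(params$label)])
  t1_pre <- array(t1_by_label[labels + 1L], dp)
  ecv_by_label <- c(0, params$ecv[order(params$label)])
  ecv_map <- array(ecv_by_label[labels + 1L], dp)
  dr1_ref <- 1 / 1000 - 1 / 1400        # muscle uptake scale, 1/ms
  r1_post <- 1 / t1_pre + dr1_ref * ecv_map / ecv_ref
  t1_post <- 1 / r1_post
  if (t1_noise_ms > 0) {
    t1_pre <- t1_pre + array(rng$rnorm(prod(dp), sd = t1_noise_ms), dp)
    t1_post <- t1_post + array(rng$rnorm(prod(dp), sd = t1_noise_ms), dp)
  }

  list(sodium = sodium, b1 = bias, sigma = noise_sigma,
       echoes = echoes, te_ms = te_ms,
       field_hz = volume_map(field_hz, vox_p),
       t1_pre = volume_map(t1_pre, vox_p),
       t1_post = volume_map(t1_post, vox_p),
       muscle_mask = labels == 4L,
       truth = truth, labels_sodium = labels_sodium,
       acq = acq, tissue_relax = tissue_relax, upsample = upsample,
       fat_shift_ppm = fat_shift_ppm, field_T = field_T,
       ecv_ref = ecv_ref)
}
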