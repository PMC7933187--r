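#' Ground truth description of a simulated phantom
#'
#' Bundles the integer label volume with the per-label tissue parameters
#' the simulator used, so recovery experiments can compare pipeline output
#' against exact truth. Construction asserts the three-compartment
#' consistency of every label: stored TSC must equal
#' `ECV*C_EC + (WF - ECV)*C_IC + (1 - WF)*C_fat` and `0 <= ECV <= WF <= 1`.
#'
#' @param labels integer 3D array of compartment labels (0 = background).
#' @param params data.frame with one row per label: `label`, `name`,
#'   `tsc_mM` and (for tissue-model labels) `c_ic_mM`, `ecv`, `wf`;
#'   optionally relaxation and T1 columns.
#' @param voxel_mm voxel size, mm.
#' @param c_ec_mM extracellular sodium concentration, mM.
#' @param c_fat_mM sodium concentration of the fat compartment, mM.
#' @param seed integer seed the phantom was generated with.
#' @return A `phantom_truth` object.
#' @export
phantom_truth <- function(labels, params, voxel_mm, c_ec_mM = 140,
                          c_fat_mM = 10, seed = NA_integer_) {
  stopifnot(is.data.frame(params), "label" %in% names(params),
            "tsc_mM" %in% names(params))
  if (all(c("c_ic_mM", "ecv", "wf") %in% names(params))) {
    full <- !is.na(params$ecv)
    p <- params[full, ]
    if (any(p$ecv < 0 | p$ecv > p$wf | p$wf > 1))
      stop("per-label parameters must satisfy 0 <= ECV <= WF <= 1")
    if (any(p$c_ic_mM < 0)) stop("C_IC must be nonnegative")
    model_tsc <- p$ecv * c_ec_mM + (p$wf - p$ecv) * p$c_ic_mM +
      (1 - p$wf) * c_fat_mM
    if (any(abs(model_tsc - p$tsc_mM) > 1e-9))
      stop("per-label TSC inconsistent with the three-compartment model")
  }
  structure(list(labels = labels, params = params,
                 voxel_mm = rep_len(as.numeric(voxel_mm), 3L),
                 c_ec_mM = c_ec_mM, c_fat_mM = c_fat_mM, seed = seed),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s voxels, %d labels, seed %s\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$params), format(x$seed)))
  print(x$params, row.names = FALSE)
  invisible(x)
}

# Map of a per-label quantity onto the label grid (background -> fill).
label_map <- function(truth, column, fill = 0) {
  vals <- rep(fill, max(truth$labels) + 1L)
  vals[truth$params$label + 1L] <- truth$params[[column]]
  arr <- array(vals[truth$labels + 1L], dim = dim(truth$labels))
  volume_map(arr, truth$voxel_mm)
}

#' Logical mask of one labelled compartment
#' @param truth a [phantom_truth].
#' @param name label name as in `truth$params$name`.
#' @return Logical 3D array.
#' @export
truth_mask <- function(truth, name) {
  lab <- truth$params$label[truth$params$name == name]
  if (!length(lab)) stop("no label named '", name, "'")
  truth$labels == lab
}

# --- geometry helpers (voxel-index coordinates) ---------------------------

coord_grids <- function(d) {
  list(x = outer_axis(seq_len(d[1]), d, 1),
       y = outer_axis(seq_len(d[2]), d, 2),
       z = outer_axis(seq_len(d[3]), d, 3))
}

sphere_mask <- function(g, centre, radius) {
  (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2 <= radius^2
}

cylinder_mask <- function(g, centre_xy, radius, z_range) {
  (g$x - centre_xy[1])^2 + (g$y - centre_xy[2])^2 <= radius^2 &
    g$z >= z_range[1] & g$z <= z_range[2]
}

# Place n gel centres on one or two rings in the transverse plane.
ring_centres <- function(d, n, ring_frac = 0.30) {
  ctr <- (d[1:2] + 1) / 2
  one_ring <- function(m, frac, phase = 0) {
    ang <- 2 * pi * (seq_len(m) - 1) / max(m, 1) + phase
    r <- frac * min(d[1:2])
    cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
  }
  if (n <= 6) return(one_ring(n, ring_frac))
  n_out <- ceiling(n / 2)
  rbind(one_ring(n_out, ring_frac),
        one_ring(n - n_out, ring_frac * 0.5, phase = pi / max(n - n_out, 1)))
}

# Smooth multiplicative B1 bias field in (0, 1.2].
# type "quadratic": deterministic radial droop 1 -> 1 - strength;
# type "random": Gaussian-smoothed seeded random field with the same range;
# type "flat": identically 1.
b1_bias_field <- function(d, voxel_mm, type = "quadratic", strength = 0.15,
                          seed = 1L) {
  d <- rep_len(as.integer(d), 3L)
  if (type == "flat" || strength == 0) {
    return(volume_map(array(1, d), voxel_mm))
  }
  if (type == "quadratic") {
    g <- coord_grids(d)
    ctr <- (d + 1) / 2
    r2 <- ((g$x - ctr[1]) / (d[1] / 2))^2 + ((g$y - ctr[2]) / (d[2] / 2))^2 +
      ((g$z - ctr[3]) / (d[3] / 2))^2
    b <- 1 - strength * r2 / 3
  } else if (type == "random") {
    rng <- local_rng(seed)
    raw <- array(rng$rnorm(prod(d)), dim = d)
    b <- unclass(gaussian_smooth(volume_map(raw, voxel_mm),
                                 8 * mean(voxel_mm)))
    b <- (b - min(b)) / max(max(b) - min(b), 1e-12)  # -> [0,1]
    b <- 1 - strength + strength * b
  } else {
    stop("unknown B1 bias type '", type, "'")
  }
  volume_map(b, voxel_mm)
}

# Seed-local RNG: draws do not disturb (and are not disturbed by) the
# caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = function(n, ...) draw(stats::rnorm, n, ...))
}

#' Add Rician noise to a noiseless magnitude image
#'
#' Magnitude MRI noise: the noiseless signal is taken as the real channel,
#' independent Gaussian noise of standard deviation `sigma` is added to
#' both quadratures, and the magnitude is returned.
#'
#' @param x noiseless [volume_map] (nonnegative).
#' @param sigma Gaussian noise SD per channel, image units.
#' @param seed integer seed.
#' @return Noisy [volume_map].
#' @export
add_rician_noise <- function(x, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  rng <- local_rng(seed)
  n <- length(x)
  re <- unclass(x) + array(rng$rnorm(n, sd = sigma), dim = dim(x))
  im <- array(rng$rnorm(n, sd = sigma), dim = dim(x))
  rewrap(sqrt(re^2 + im^2), x)
}

# Relaxation-time classes for the agar gels. The published supplement with
# the measured gel values is not bundled; these are realistic defaults for
# saline/agar sodium phantoms (more agar -> shorter, more biexponential).
#' Relaxation times of the simulated agar gel classes
#' @param agar_percent one of 0, 3, 4, 8.
#' @return A [relax_times].
#' @export
agar_relax <- function(agar_percent) {
  switch(as.character(agar_percent),
         "0" = relax_times(T1 = 55, T2s = 35, T2l = 35, fast_fraction = 0.6),
         "3" = relax_times(T1 = 35, T2s = 5,  T2l = 25, fast_fraction = 0.6),
         "4" = relax_times(T1 = 32, T2s = 3.5, T2l = 20, fast_fraction = 0.6),
         "8" = relax_times(T1 = 28, T2s = 2,  T2l = 14, fast_fraction = 0.6),
         stop("no relaxation class for ", agar_percent, "% agar"))
}

# Shared forward model: per-voxel lambda weighting of the concentration
# map (each label with its own relaxation times), a single acquisition
# PSF blur of the weighted map, multiplicative B1 bias, Rician noise.
forward_sodium <- function(conc, labels, relax_by_label, acq, b1, sigma,
                           seed, use_psf = TRUE, psf_relax = NULL) {
  d <- dim(conc)
  img <- array(0, d)
  for (lab in names(relax_by_label)) {
    sel <- labels == as.integer(lab)
    img[sel] <- conc[sel] * lambda_factor(relax_by_label[[lab]], acq)
  }
  if (use_psf) {
    if (is.null(psf_relax)) psf_relax <- relax_by_label[[1]]
    psf <- compute_psf(d, acq, psf_relax)
    img <- unclass(apply_psf(volume_map(img, acq$voxel_mm), psf))
  }
  img <- img * unclass(b1)
  add_rician_noise(volume_map(img, acq$voxel_mm), sigma, seed)
}

#' Simulate the calibration phantom
#'
#' Cylindrical saline bath containing agar gel spheres of known sodium
#' concentration, imaged with the sodium protocol: per-voxel concentration
#' times the lambda factor of the local relaxation class, blurred by the
#' acquisition PSF, modulated by a smooth B1 bias, with Rician noise.
#'
#' @param concentrations_mM gel concentrations, mM (all > 0).
#' @param relax [relax_times] shared by all gels (3% agar class).
#' @param acq sodium [acq_spec]; sets matrix and voxel size.
#' @param bath_mM concentration of the surrounding saline bath, mM.
#' @param bath_relax [relax_times] of the bath.
#' @param noise_sigma Rician channel SD in image units, or `NULL` to set
#'   it from `snr`.
#' @param snr mean noiseless gel signal over the gel ROIs divided by the
#'   channel SD; used when `noise_sigma` is `NULL`.
#' @param b1 B1 bias descriptor: list with `type` ("quadratic", "random",
#'   "flat") and `strength`.
#' @param gel_radius_frac gel sphere radius as a fraction of the matrix.
#' @param use_psf blur with the acquisition PSF (disable for degenerate
#'   forward-model checks).
#' @param seed integer seed.
#' @return List with `image` (noisy sodium [volume_map]), `truth`
#'   ([phantom_truth]), `b1` (the bias field), `sigma` (channel SD used).
#' @export
make_calibration_phantom <- function(concentrations_mM = c(25, 50, 75, 100, 125),
                                     relax = agar_relax(3),
                                     acq = acq_spec(),
                                     bath_mM = 50,
                                     bath_relax = relax_times(55, 50, 50, 0.6),
                                     noise_sigma = NULL, snr = 30,
                                     b1 = list(type = "quadratic", strength = 0.15),
                                     gel_radius_frac = 0.08,
                                     use_psf = TRUE,
                                     seed = 1L) {
  if (!length(concentrations_mM) || any(concentrations_mM <= 0))
    stop("concentrations must be nonempty and positive")
  d <- acq$matrix_size
  g <- coord_grids(d)
  n <- length(concentrations_mM)
  radius <- gel_radius_frac * min(d)
  centres <- ring_centres(d, n)
  if (any(centres[, 1] - radius < 2 | centres[, 1] + radius > d[1] - 1 |
          centres[, 2] - radius < 2 | centres[, 2] + radius > d[2] - 1))
    stop("geometry error: requested gels do not fit in the matrix")
  labels <- array(0L, d)
  bath <- cylinder_mask(g, (d[1:2] + 1) / 2, 0.45 * min(d[1:2]),
                        c(round(0.15 * d[3]), round(0.85 * d[3])))
  labels[bath] <- 1L
  zc <- (d[3] + 1) / 2
  for (i in seq_len(n)) {
    m <- sphere_mask(g, c(centres[i, ], zc), radius)
    if (any(labels[m] > 1L))
      stop("geometry error: gel regions overlap")
    labels[m] <- i + 1L
  }
  params <- data.frame(
    label = c(1L, seq_len(n) + 1L),
    name = c("bath", paste0("gel", seq_len(n))),
    tsc_mM = c(bath_mM, concentrations_mM),
    c_ic_mM = NA_real_, ecv = NA_real_, wf = NA_real_)
  truth <- phantom_truth(labels, params, acq$voxel_mm, seed = seed)
  conc <- unclass(label_map(truth, "tsc_mM"))
  relax_by_label <- c(stats::setNames(list(bath_relax), "1"),
                      stats::setNames(rep(list(relax), n),
                                      as.character(seq_len(n) + 1L)))
  bias <- b1_bias_field(d, acq$voxel_mm, b1$type, b1$strength, seed)
  if (is.null(noise_sigma)) {
    gel_signal <- mean(conc[labels > 1L]) * lambda_factor(relax, acq)
    noise_sigma <- gel_signal / snr
  }
  img <- forward_sodium(conc, labels, relax_by_label, acq, bias,
                        noise_sigma, seed, use_psf, psf_relax = relax)
  list(image = img, truth = truth, b1 = bias, sigma = noise_sigma)
}

#' Default gel set of the validation phantom
#'
#' Three 140 mM gels with 0/4/8% agar relaxation classes plus seven of
#' the 3% agar calibration gels, matching the validation layout.
#'
#' @return data.frame with `concentration_mM`, `agar_percent`.
#' @export
validation_gel_specs <- function() {
  data.frame(
    concentration_mM = c(140, 140, 140, 25, 50, 75, 100, 125, 50, 100),
    agar_percent = c(0, 4, 8, rep(3, 7)))
}

#' Simulate the validation phantom
#'
#' Gels with individual concentrations and relaxation classes, inserted
#' directly into the coil with no liquid bath, otherwise imaged exactly as
#' the calibration phantom. Each relaxation class is blurred with its own
#' PSF.
#'
#' @param gel_specs data.frame with columns `concentration_mM` and either
#'   `agar_percent` (mapped through [agar_relax()]) or list-column `relax`.
#' @param acq,noise_sigma,snr,b1,gel_radius_frac,use_psf,seed as in
#'   [make_calibration_phantom()].
#' @param psf_relax [relax_times] class used for the single acquisition
#'   PSF of the forward blur (default the 3% agar class).
#' @return List with `image`, `truth`, `b1`, `sigma`, and `relax_by_gel`
#'   (list of [relax_times] per gel label).
#' @export
make_validation_phantom <- function(gel_specs = validation_gel_specs(),
                                    acq = acq_spec(),
                                    noise_sigma = NULL, snr = 30,
                                    b1 = list(type = "quadratic", strength = 0.15),
                                    gel_radius_frac = 0.08,
                                    use_psf = TRUE,
                                    psf_relax = agar_relax(3),
                                    seed = 1L) {
  if (!nrow(gel_specs)) stop("geometry error: empty gel list")
  if (any(gel_specs$concentration_mM <= 0))
    stop("concentrations must be positive")
  relaxes <- if (!is.null(gel_specs$relax)) gel_specs$relax
             else lapply(gel_specs$agar_percent, agar_relax)
  d <- acq$matrix_size
  g <- coord_grids(d)
  n <- nrow(gel_specs)
  radius <- gel_radius_frac * min(d)
  centres <- ring_centres(d, n)
  if (any(centres < radius + 2) ||
      any(centres[, 1] > d[1] - radius - 1) ||
      any(centres[, 2] > d[2] - radius - 1))
    stop("geometry error: requested gels do not fit in the matrix")
  labels <- array(0L, d)
  zc <- (d[3] + 1) / 2
  for (i in seq_len(n)) {
    m <- sphere_mask(g, c(centres[i, ], zc), radius)
    if (any(labels[m] > 0L)) stop("geometry error: gel regions overlap")
    labels[m] <- i
  }
  params <- data.frame(label = seq_len(n),
                       name = paste0("gel", seq_len(n)),
                       tsc_mM = gel_specs$concentration_mM,
                       c_ic_mM = NA_real_, ecv = NA_real_, wf = NA_real_)
  truth <- phantom_truth(labels, params, acq$voxel_mm, seed = seed)
  conc <- unclass(label_map(truth, "tsc_mM"))
  relax_by_label <- stats::setNames(relaxes, as.character(seq_len(n)))
  bias <- b1_bias_field(d, acq$voxel_mm, b1$type, b1$strength, seed)
  if (is.null(noise_sigma)) {
    lam <- vapply(relaxes, function(r) lambda_factor(r, acq), numeric(1))
    noise_sigma <- mean(gel_specs$concentration_mM * lam) / snr
  }
  img <- forward_sodium(conc, labels, relax_by_label, acq, bias,
                        noise_sigma, seed, use_psf, psf_relax = psf_relax)
  list(image = img, truth = truth, b1 = bias, sigma = noise_sigma,
       relax_by_gel = relaxes, psf_relax = psf_relax)
}

#' Simulate a uniform-phantom B1 reference image
#'
#' A large uniform cylinder filling the field of view, imaged with the
#' same B1 bias as a companion phantom; used by [b1_normalize()].
#'
#' @param acq sodium [acq_spec].
#' @param b1_field the bias [volume_map] returned by a phantom generator.
#' @param noise_sigma Rician channel SD.
#' @param seed integer seed.
#' @return A [volume_map].
#' @export
make_b1_reference <- function(acq, b1_field, noise_sigma = 0, seed = 2L) {
  d <- acq$matrix_size
  g <- coord_grids(d)
  supp <- cylinder_mask(g, (d[1:2] + 1) / 2, 0.48 * min(d[1:2]),
                        c(2, d[3] - 1))
  img <- array(0, d)
  img[supp] <- 100
  img <- img * unclass(b1_field)
  add_rician_noise(volume_map(img, acq$voxel_mm), noise_sigma, seed)
}
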