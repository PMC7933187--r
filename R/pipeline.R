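#' Pipeline configuration
#'
#' All tunable parameters of the quantification pipeline with their
#' standard defaults: C_EC 140 mM, muscle ECV reference 0.12, tissue
#' sodium relaxation T1 = 37 ms, T2s = 0.5 ms, T2l = 15 ms with a 60:40
#' fast/slow split, sodium protocol TR = 60 ms, TE = 0.2 ms, FA = 80
#' degrees, fat threshold WF < 0.10, fibroglandular display threshold
#' WF > 0.50, ICV identifiability floor 0.05.
#'
#' @param sodium_acq sodium [acq_spec].
#' @param tissue_relax tissue [relax_times].
#' @param c_ec_mM extracellular sodium concentration, mM.
#' @param c_fat_mM fat sodium concentration in mM, or the string
#'   `"estimate"` to apply the WF < `fat_wf_threshold` rule.
#' @param ecv_ref reference (pectoral muscle) ECV.
#' @param fat_wf_threshold WF below which a voxel is fat.
#' @param display_wf_threshold WF above which a voxel is fibroglandular.
#' @param icv_floor identifiability floor on ICV.
#' @param deconv_iterations Richardson-Lucy iterations.
#' @param smoothing_fwhm_mm B1-reference smoothing FWHM, mm.
#' @param te_ms proton multi-echo TEs, ms.
#' @param fat_shift_ppm single-peak fat chemical shift, ppm.
#' @param field_T main field strength, Tesla.
#' @param seed integer seed for any stochastic component.
#' @return A `naquant_config` list.
#' @export
naquant_config <- function(sodium_acq = acq_spec(),
                           tissue_relax = relax_times(),
                           c_ec_mM = 140,
                           c_fat_mM = "estimate",
                           ecv_ref = 0.12,
                           fat_wf_threshold = 0.10,
                           display_wf_threshold = 0.50,
                           icv_floor = 0.05,
                           deconv_iterations = 10,
                           smoothing_fwhm_mm = 15,
                           te_ms = c(2.04, 2.24, 2.44, 2.64),
                           fat_shift_ppm = -3.4,
                           field_T = 7,
                           seed = 1L) {
  structure(list(sodium_acq = sodium_acq, tissue_relax = tissue_relax,
                 c_ec_mM = c_ec_mM, c_fat_mM = c_fat_mM, ecv_ref = ecv_ref,
                 fat_wf_threshold = fat_wf_threshold,
                 display_wf_threshold = display_wf_threshold,
                 icv_floor = icv_floor,
                 deconv_iterations = deconv_iterations,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 te_ms = te_ms, fat_shift_ppm = fat_shift_ppm,
                 field_T = field_T, seed = as.integer(seed)),
            class = "naquant_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly: nested acquisition and
#' relaxation objects are flattened to plain lists and rebuilt through
#' their constructors on read.
#'
#' @param config a [naquant_config].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a [naquant_config].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$sodium_acq <- unclass(x$sodium_acq)
  x$tissue_relax <- unclass(x$tissue_relax)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sodium_acq <- do.call(acq_spec, x$sodium_acq)
  x$tissue_relax <- do.call(relax_times, x$tissue_relax)
  do.call(naquant_config, x)
}

check_same_grid <- function(a, b, name_a, name_b) {
  if (!identical(dim(a), dim(b)))
    stop("grid mismatch between ", name_a, " (",
         paste(dim(a), collapse = "x"), ") and ", name_b, " (",
         paste(dim(b), collapse = "x"), ")")
  if (max(abs(voxel_mm(a) - voxel_mm(b))) > 1e-6)
    stop("voxel-size mismatch between ", name_a, " and ", name_b)
  invisible(TRUE)
}

#' Run the full quantification pipeline
#'
#' Orchestrates water/fat separation, sodium correction (B1
#' normalization, PSF deconvolution, lambda correction, calibration),
#' ECV computation and the three-compartment inversion, writing every
#' intermediate map, a JSON provenance report and optional ROI CSVs.
#'
#' Inputs may be given in memory (as the objects produced by
#' [make_breast_phantom()]) or as NIfTI paths; maps must be mutually
#' co-registered — grids are asserted, no registration is performed. The
#' proton-resolution WF and ECV maps are block-averaged to the sodium
#' grid before inversion.
#'
#' @param inputs list with elements `sodium`, `b1_reference`, `echoes`
#'   (list of complex volumes), `t1_pre`, `t1_post`, `muscle_mask`;
#'   each a [volume_map]/array or a NIfTI path. `calibration` must be a
#'   `calibration_curve` or a data.frame with `concentration_mM` and
#'   `signal` columns.
#' @param config a [naquant_config].
#' @param rois optional named list of logical masks on the sodium grid
#'   for CSV reporting.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return Invisibly, a list with the `compartment_maps`, the
#'   intermediate maps (`wf_proton`, `ecv_proton`, `tsc`, `corrected`),
#'   `c_fat_mM` used, the calibration, clip/flag counts and the ROI
#'   statistics table.
#' @export
run_pipeline <- function(inputs, config = naquant_config(), rois = NULL,
                         out_dir = NULL) {
  load_vol <- function(x) if (is.character(x)) read_map(x) else x
  if (is.null(inputs$calibration)) stop("missing calibration")
  cal <- inputs$calibration
  if (is.data.frame(cal)) cal <- fit_calibration(cal$concentration_mM,
                                                 cal$signal)
  sodium <- load_vol(inputs$sodium)
  b1_ref <- load_vol(inputs$b1_reference)
  echoes <- lapply(inputs$echoes, load_vol)
  t1_pre <- load_vol(inputs$t1_pre)
  t1_post <- load_vol(inputs$t1_post)
  muscle <- inputs$muscle_mask
  if (is.character(muscle)) muscle <- unclass(read_map(muscle)) > 0.5

  check_same_grid(sodium, b1_ref, "sodium", "b1_reference")
  for (i in seq_along(echoes))
    check_same_grid(echoes[[1]], echoes[[i]], "echo 1", paste("echo", i))
  check_same_grid(t1_pre, t1_post, "t1_pre", "t1_post")
  check_same_grid(echoes[[1]], t1_pre, "echoes", "t1_pre")
  dp <- dim(t1_pre); ds <- dim(sodium)
  factor <- unique(dp %/% ds)
  if (length(factor) != 1L || any(dp != ds * factor))
    stop("proton grid ", paste(dp, collapse = "x"),
         " is not an integer multiple of the sodium grid ",
         paste(ds, collapse = "x"),
         "; resample or harmonize the inputs first")

  # proton side
  wfres <- ideal_waterfat(echoes, config$te_ms, config$fat_shift_ppm,
                          config$field_T)
  ecv_p <- compute_ecv(t1_pre, t1_post, muscle, config$ecv_ref)
  wf_s <- block_average(wfres$wf, factor)
  ecv_s <- block_average(ecv_p, factor)

  # sodium side
  acq <- config$sodium_acq
  corrected <- b1_normalize(sodium, b1_ref, config$smoothing_fwhm_mm)
  psf <- compute_psf(dim(sodium), acq, config$tissue_relax)
  corrected <- deconvolve(corrected, psf, config$deconv_iterations)
  tsc <- signal_to_tsc(corrected, cal, config$tissue_relax, acq)

  c_fat <- config$c_fat_mM
  if (identical(c_fat, "estimate"))
    c_fat <- as.numeric(estimate_cfat(tsc, wf_s, config$fat_wf_threshold))
  cm <- invert_model(tsc, wf_s, ecv_s, config$c_ec_mM, c_fat,
                     config$icv_floor)

  roi_tab <- NULL
  if (!is.null(rois)) {
    roi_tab <- do.call(rbind, lapply(names(rois), function(nm) {
      rows <- lapply(c(tsc = "tsc", ecv = "ecv", icv = "icv",
                       c_ic = "c_ic"), function(fld)
        roi_stats(cm[[fld]], rois[[nm]]))
      data.frame(roi_name = nm,
                 quantity = names(rows),
                 mean = vapply(rows, `[[`, numeric(1), "mean"),
                 sd = vapply(rows, `[[`, numeric(1), "sd"),
                 n = vapply(rows, `[[`, numeric(1), "n"))
    }))
    rownames(roi_tab) <- NULL
  }

  counts <- list(tsc_clipped = attr(tsc, "n_clipped"),
                 ecv_clipped_low = attr(ecv_p, "n_clipped_low"),
                 ecv_clipped_high = attr(ecv_p, "n_clipped_high"),
                 waterfat_flagged = wfres$n_flagged,
                 inversion_invalid = cm$n_invalid,
                 c_ic_negative = cm$n_negative)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_map(cm$tsc, file.path(out_dir, "tsc.nii"))
    write_map(wf_s, file.path(out_dir, "wf.nii"))
    write_map(cm$ecv, file.path(out_dir, "ecv.nii"))
    write_map(cm$icv, file.path(out_dir, "icv.nii"))
    write_map(cm$c_ic, file.path(out_dir, "c_ic.nii"))
    write_map(wfres$wf, file.path(out_dir, "wf_proton.nii"))
    write_map(ecv_p, file.path(out_dir, "ecv_proton.nii"))
    prov <- list(
      package = "naquant",
      version = as.character(utils::packageVersion("naquant")),
      config = yaml::as.yaml(c(unclass(config)[!vapply(config, is.object,
                                                       logical(1))],
                               list(sodium_acq = unclass(config$sodium_acq),
                                    tissue_relax =
                                      unclass(config$tissue_relax)))),
      calibration = list(slope = cal$slope, intercept = cal$intercept,
                         r_squared = cal$r_squared),
      c_fat_mM = c_fat,
      counts = counts)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(roi_tab))
      utils::write.csv(roi_tab, file.path(out_dir, "roi_stats.csv"),
                       row.names = FALSE)
  }

  invisible(list(compartments = cm, wf_proton = wfres, ecv_proton = ecv_p,
                 wf = wf_s, ecv = ecv_s, tsc = tsc, corrected = corrected,
                 calibration = cal, c_fat_mM = c_fat, counts = counts,
                 roi_stats = roi_tab))
}

#' Calibrate from a simulated calibration phantom
#'
#' Runs the correction chain (B1 normalization, deconvolution, per-gel
#' lambda correction) on a calibration phantom image and fits the
#' calibration line through the per-gel mean corrected signals.
#'
#' @param phantom list from [make_calibration_phantom()].
#' @param b1_reference uniform-phantom [volume_map] (defaults to a
#'   simulated one sharing the phantom's bias field).
#' @param config a [naquant_config]; its acquisition must match the
#'   phantom's.
#' @param relax [relax_times] of the gels.
#' @param roi_erode one-voxel erosions applied to each gel ROI so means
#'   are taken over gel interiors, away from partial-volume edges.
#' @return A `calibration_curve`.
#' @export
calibrate_from_phantom <- function(phantom,
                                   b1_reference = NULL,
                                   config = naquant_config(),
                                   relax = agar_relax(3),
                                   roi_erode = 1) {
  acq <- config$sodium_acq
  if (is.null(b1_reference))
    b1_reference <- make_b1_reference(acq, phantom$b1)
  corrected <- b1_normalize(phantom$image, b1_reference,
                            config$smoothing_fwhm_mm)
  psf <- compute_psf(dim(phantom$image), acq, relax)
  corrected <- deconvolve(corrected, psf, config$deconv_iterations)
  lam <- lambda_factor(relax, acq)
  gels <- phantom$truth$params[phantom$truth$params$name != "bath", ]
  sig <- vapply(gels$label, function(l)
    roi_stats(corrected, erode_mask(phantom$truth$labels == l,
                                    roi_erode))$mean / lam, numeric(1))
  fit_calibration(gels$tsc_mM, sig)
}

#' Recover per-gel TSC from a simulated validation phantom
#'
#' Full sodium chain on a validation phantom: B1 normalization,
#' PSF deconvolution with the acquisition PSF, then per-gel relaxation
#' correction with each gel's own (measured) relaxation times and
#' inversion of the calibration line.
#'
#' @param phantom list from [make_validation_phantom()].
#' @param cal a `calibration_curve`.
#' @param b1_reference uniform-phantom [volume_map] (simulated if `NULL`).
#' @param config a [naquant_config].
#' @param roi_erode one-voxel erosions applied to each gel ROI.
#' @param psf_relax [relax_times] class defining the deconvolution PSF
#'   (default the 3% agar class, as for calibration).
#' @return data.frame per gel: `name`, `true_mM`, `measured_mM`,
#'   `sd_mM`, `rel_error`.
#' @export
quantify_validation_phantom <- function(phantom, cal, b1_reference = NULL,
                                        config = naquant_config(),
                                        roi_erode = 1,
                                        psf_relax = agar_relax(3)) {
  acq <- config$sodium_acq
  if (is.null(b1_reference))
    b1_reference <- make_b1_reference(acq, phantom$b1)
  corrected <- b1_normalize(phantom$image, b1_reference,
                            config$smoothing_fwhm_mm)
  psf <- compute_psf(dim(phantom$image), acq, psf_relax)
  corrected <- deconvolve(corrected, psf, config$deconv_iterations)
  gels <- phantom$truth$params
  out <- lapply(seq_len(nrow(gels)), function(i) {
    rl <- phantom$relax_by_gel[[i]]
    tsc <- signal_to_tsc(corrected, cal, rl, acq)
    st <- roi_stats(tsc, erode_mask(phantom$truth$labels == gels$label[i],
                                    roi_erode))
    data.frame(name = gels$name[i], true_mM = gels$tsc_mM[i],
               measured_mM = st$mean, sd_mM = st$sd,
               rel_error = (st$mean - gels$tsc_mM[i]) / gels$tsc_mM[i])
  })
  do.call(rbind, out)
}
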