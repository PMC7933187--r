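#' Mean uncertainty of a swept output
#'
#' The half-width of the output interval relative to a reference value,
#' in percent: `100 * (max - min) / (2 * c0)`. This is the statistic
#' reported in the error-propagation tables alongside each parameter
#' sweep.
#'
#' @param values output values across the sweep (nonempty).
#' @param c0 reference value (> 0): either the output at the central,
#'   unperturbed parameter value or the centre of the output interval.
#' @return Percent mean uncertainty (>= 0).
#' @examples
#' mean_uncertainty(c(30.6, 28.8, 26.8, 24.8, 22.9), 26.8)  # ~14.4
#' @export
mean_uncertainty <- function(values, c0) {
  if (!length(values)) stop("values must be nonempty")
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be positive")
  100 * (max(values) - min(values)) / (2 * c0)
}

#' Assemble the pipeline state consumed by parameter sweeps
#'
#' Captures the stage outputs a sweep needs so that only the stages
#' downstream of the swept parameter are recomputed: the corrected
#' (B1-normalized, deconvolved) sodium signal and calibration for
#' relaxation sweeps; the ECV map and its reference for `ECV_ref` sweeps;
#' the compartment scalars for `C_EC`/`C_fat` sweeps.
#'
#' @param signal corrected sodium signal [volume_map].
#' @param cal a `calibration_curve`.
#' @param acq sodium [acq_spec].
#' @param relax tissue [relax_times] (central values).
#' @param wf water-fraction [volume_map] on the sodium grid.
#' @param ecv ECV [volume_map] on the sodium grid.
#' @param ecv_ref reference-tissue ECV used to produce `ecv`.
#' @param c_ec_mM,c_fat_mM central compartment concentrations, mM.
#' @param icv_floor identifiability floor for the inversion.
#' @return A `quant_state` list.
#' @export
quant_state <- function(signal, cal, acq, relax, wf, ecv, ecv_ref = 0.12,
                        c_ec_mM = 140, c_fat_mM = 10, icv_floor = 0.05) {
  structure(list(signal = signal, cal = cal, acq = acq, relax = relax,
                 wf = wf, ecv = ecv, ecv_ref = ecv_ref,
                 c_ec_mM = c_ec_mM, c_fat_mM = c_fat_mM,
                 icv_floor = icv_floor),
            class = "quant_state")
}

sweepable <- c("C_EC", "C_fat", "ECV_ref", "T1", "T2s", "T2l",
               "fast_fraction")

#' Sweep one model parameter and tabulate ROI outputs
#'
#' Deterministic error propagation: one parameter is varied over a
#' strictly monotone grid while all others stay at their central values,
#' and only the pipeline stages downstream of that parameter are
#' recomputed (lambda correction and TSC for relaxation parameters; ECV
#' scaling and inversion for `ECV_ref`; inversion alone for `C_EC` and
#' `C_fat`). ROI means of TSC, ECV and C_IC are reported per value
#' together with their mean uncertainties.
#'
#' @param state a [quant_state].
#' @param parameter one of `"C_EC"`, `"C_fat"`, `"ECV_ref"`, `"T1"`,
#'   `"T2s"`, `"T2l"`, `"fast_fraction"`.
#' @param values strictly monotone parameter grid containing the central
#'   value.
#' @param roi logical mask on the sodium grid.
#' @param c0_convention `"central_value"` (reference output at the
#'   unperturbed parameter, the tabulated convention) or
#'   `"interval_center"` (centre of the output interval).
#' @return A `sensitivity_table`: data.frame of per-value ROI means with
#'   attributes `parameter`, `mean_uncertainty` (named percent vector),
#'   `c0`, `c0_convention`.
#' @export
sweep_parameter <- function(state, parameter, values, roi,
                            c0_convention = c("central_value",
                                              "interval_center")) {
  stopifnot(inherits(state, "quant_state"))
  c0_convention <- match.arg(c0_convention)
  if (!parameter %in% sweepable)
    stop("unknown parameter '", parameter, "'; expected one of ",
         paste(sweepable, collapse = ", "))
  dv <- diff(values)
  if (length(values) < 2L || !(all(dv > 0) || all(dv < 0)))
    stop("values must be strictly monotone")

  eval_at <- function(v) {
    relax <- state$relax
    ecv <- state$ecv
    c_ec <- state$c_ec_mM
    c_fat <- state$c_fat_mM
    if (parameter %in% c("T1", "T2s", "T2l", "fast_fraction")) {
      rl <- unclass(relax)
      rl[[c(T1 = "T1", T2s = "T2s", T2l = "T2l",
            fast_fraction = "fast_fraction")[parameter]]] <- v
      relax <- do.call(relax_times, rl)
    } else if (parameter == "ECV_ref") {
      # Eq.-style normalization is linear in the reference ECV
      ecv <- rewrap(unclass(ecv) * v / state$ecv_ref, ecv)
    } else if (parameter == "C_EC") {
      c_ec <- v
    } else if (parameter == "C_fat") {
      c_fat <- v
    }
    tsc <- signal_to_tsc(state$signal, state$cal, relax, state$acq)
    cm <- invert_model(tsc, state$wf, ecv, c_ec, c_fat, state$icv_floor)
    c(tsc_mM = roi_stats(cm$tsc, roi)$mean,
      ecv = roi_stats(cm$ecv, roi)$mean,
      c_ic_mM = roi_stats(cm$c_ic, roi)$mean)
  }
  rows <- t(vapply(values, eval_at, numeric(3)))
  tab <- data.frame(value = values, rows)

  central <- switch(parameter,
                    C_EC = state$c_ec_mM, C_fat = state$c_fat_mM,
                    ECV_ref = state$ecv_ref, T1 = state$relax$T1,
                    T2s = state$relax$T2s, T2l = state$relax$T2l,
                    fast_fraction = state$relax$fast_fraction)
  i0 <- which.min(abs(values - central))
  outs <- c("tsc_mM", "ecv", "c_ic_mM")
  c0 <- vapply(outs, function(cl) {
    if (c0_convention == "central_value") tab[[cl]][i0]
    else (max(tab[[cl]]) + min(tab[[cl]])) / 2
  }, numeric(1))
  mu <- vapply(outs, function(cl) mean_uncertainty(tab[[cl]], c0[[cl]]),
               numeric(1))
  structure(tab, parameter = parameter, central_value = central,
            c0 = c0, c0_convention = c0_convention,
            mean_uncertainty = mu,
            class = c("sensitivity_table", "data.frame"))
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("sensitivity sweep of %s (central %.4g, c0 = %s)\n",
              attr(x, "parameter"), attr(x, "central_value"),
              attr(x, "c0_convention")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  mu <- attr(x, "mean_uncertainty")
  cat("mean uncertainty:",
      paste(sprintf("%s +/- %.1f%%", names(mu), mu), collapse = ", "), "\n")
  invisible(x)
}

#' Write a sensitivity table as CSV with a provenance header
#'
#' Header lines (prefixed `#`) record the swept parameter, the c0
#' convention and the mean uncertainties, followed by the per-value table.
#'
#' @param x a `sensitivity_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(x, path) {
  mu <- attr(x, "mean_uncertainty")
  hdr <- c(sprintf("# parameter: %s", attr(x, "parameter")),
           sprintf("# central_value: %.10g", attr(x, "central_value")),
           sprintf("# c0_convention: %s", attr(x, "c0_convention")),
           sprintf("# mean_uncertainty_pct: %s",
                   paste(sprintf("%s=%.6g", names(mu), mu), collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Published error-propagation table columns
#'
#' The printed input/output columns of the reported error-propagation
#' tables (lesion ROI of the first patient): the C_EC and muscle-ECV
#' sweeps, and the sodium relaxation-time sweeps. Used to reproduce the
#' tabulated mean uncertainties with [mean_uncertainty()].
#'
#' @return Named list of data.frames: `cec` (`c_ec_mM`, `lesion_cic_mM`),
#'   `ecv_ref` (`muscle_ecv`, `lesion_ecv`, `lesion_cic_mM`), and
#'   `relaxation` (`parameter`, `value_ms`, `lesion_tsc_mM`,
#'   `lesion_cic_mM`).
#' @export
reported_sweep_tables <- function() {
  dir <- system.file("extdata", package = "naquant", mustWork = TRUE)
  list(
    cec = utils::read.csv(file.path(dir, "reported_sweep_cec.csv")),
    ecv_ref = utils::read.csv(file.path(dir, "reported_sweep_ecvref.csv")),
    relaxation = utils::read.csv(file.path(dir,
                                           "reported_sweep_relaxation.csv")))
}
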