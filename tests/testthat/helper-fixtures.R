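# Shared fixtures: small grids keep the default run fast.

small_acq <- function(n = 32) acq_spec(matrix_size = n, voxel_mm = 2.8)

small_config <- function(n = 32) naquant_config(sodium_acq = small_acq(n))

# protocol sodium acquisition settings on a compact grid
tissue_acq <- function(n = 32) acq_spec(TR = 60, TE = 0.2, flip_deg = 80,
                                        matrix_size = n, voxel_mm = 2.8)

# independent closed-form evaluation of the relaxation correction factor,
# written out long-hand so it cannot share a bug with lambda_factor()
lambda_oracle <- function(T1, T2s, T2l, f, TR, TE, FA_deg) {
  E1 <- exp(-TR / T1)
  sat <- (1 - E1) / (1 - cos(FA_deg / 180 * pi) * E1)
  sat * (f * exp(-TE / T2s) + (1 - f) * exp(-TE / T2l))
}

# complex multi-echo voxel set for the single-peak water/fat model
waterfat_echoes <- function(W, F, psi_hz, te_ms = c(2.04, 2.24, 2.44, 2.64),
                            d = c(2, 2, 2), field_T = 7,
                            fat_shift_ppm = -3.4) {
  fat_hz <- fat_shift_ppm * 1e-6 * 42.577478518e6 * field_T
  lapply(te_ms, function(t) {
    s <- (W + F * exp(2i * pi * fat_hz * t * 1e-3)) *
      exp(2i * pi * psi_hz * t * 1e-3)
    volume_map(array(s, d), 1.4)
  })
}

# random but mutually consistent compartment maps for inversion tests
random_truth_maps <- function(d = c(6, 6, 6), seed = 1, c_ec = 140,
                              c_fat = 10) {
  set.seed(seed)
  n <- prod(d)
  wf <- array(runif(n, 0.3, 1), d)
  ecv <- array(runif(n, 0, 0.6), d) * wf      # 0 <= ECV <= WF
  cic <- array(runif(n, 0, 60), d)
  tsc <- ecv * c_ec + (wf - ecv) * cic + (1 - wf) * c_fat
  list(tsc = volume_map(tsc, 2.8), wf = volume_map(wf, 2.8),
       ecv = volume_map(ecv, 2.8), cic = cic,
       c_ec = c_ec, c_fat = c_fat)
}
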