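test_that("b1 normalization inverts a known multiplicative bias", {
  d <- c(16, 16, 16)
  acq <- acq_spec(matrix_size = 16)
  truth <- volume_map(array(runif(prod(d), 50, 100), d), 2.8)
  bias <- naquant:::b1_bias_field(16, 2.8, "quadratic", 0.2)
  biased <- volume_map(unclass(truth) * unclass(bias), 2.8)
  # reference is the bias itself: smoothing disabled gives the exact pair
  out <- b1_normalize(biased, bias, smoothing_fwhm_mm = 0)
  scale <- mean(unclass(bias))
  expect_lt(max(abs(out / scale - truth) / truth), 1e-6)
})

test_that("uniform reference leaves the image unchanged up to scale", {
  d <- c(8, 8, 8)
  img <- volume_map(array(runif(prod(d)), d), 2.8)
  ref <- volume_map(array(3, d), 2.8)
  out <- b1_normalize(img, ref, smoothing_fwhm_mm = 10)
  expect_equal(unclass(out), unclass(img), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("zero regions of the reference are flagged invalid", {
  d <- c(12, 12, 12)
  img <- volume_map(array(1, d), 2.8)
  ref_arr <- array(1, d)
  ref_arr[1:6, 1:6, 1:6] <- 0
  out <- b1_normalize(img, volume_map(ref_arr, 2.8), smoothing_fwhm_mm = 0)
  expect_true(all(is.na(out[1:6, 1:6, 1:6])))
  expect_true(all(!is.na(out[7:12, , ])))
  expect_gt(attr(out, "n_invalid"), 0)
  expect_error(b1_normalize(img, volume_map(array(0, d), 2.8), 0), "zero")
})

test_that("PSF has unit-voxel width without decay and broadens with it", {
  acq <- acq_spec(readout_ms = 10, matrix_size = 32)
  nodecay <- compute_psf(32, acq, relax_times(37, 1e5, 1e6, 0.6))
  k <- nodecay$kernel
  ctr <- which(k == max(k), arr.ind = TRUE)[1, ]
  expect_equal(unname(ctr), c(17, 17, 17))
  expect_gt(max(k) / sum(abs(k)), 0.99)   # a discrete delta

  tissue <- compute_psf(32, acq, relax_times(37, 0.5, 15, 0.6))
  expect_true(all(psf_fwhm(tissue) > 1))
  # halving the short T2 must not concentrate more kernel mass near the
  # centre (blur does not shrink); measured at TE = 0 where the fast
  # component is not already attenuated before the readout starts
  near_mass <- function(t2s) {
    p <- compute_psf(32, acq_spec(TE = 0, readout_ms = 10,
                                  matrix_size = 32),
                     relax_times(37, t2s, 15, 0.6))
    k <- p$kernel / sum(p$kernel)
    sum(k[16:18, 16:18, 16:18])
  }
  masses <- vapply(c(2, 1, 0.5, 0.25), near_mass, numeric(1))
  expect_true(all(diff(masses) <= 1e-9))
})

test_that("PSF DC gain equals the k-space origin weight and 1D profile
          matches a brute-force transform of the same weighting", {
  relax <- relax_times(37, 0.5, 15, 0.6)
  acq <- acq_spec(TE = 0.2, readout_ms = 10, matrix_size = 64)
  psf <- compute_psf(c(64, 1, 1), acq, relax)
  w0 <- 0.6 * exp(-0.2 / 0.5) + 0.4 * exp(-0.2 / 15)
  expect_equal(sum(psf$kernel), w0, tolerance = 1e-10)
  expect_equal(max(psf$kernel), psf$kernel[33, 1, 1])

  # independent 1D oracle: direct DFT sum over the same weighted k-grid
  n <- 64
  kidx <- c(0:(n / 2 - 1), -(n / 2):-1)
  t_k <- 0.2 + 10 * abs(kidx) / (n / 2)
  w <- 0.6 * exp(-t_k / 0.5) + 0.4 * exp(-t_k / 15)
  prof <- vapply(0:(n - 1), function(x)
    Re(sum(w * exp(2i * pi * kidx * x / n))) / n, numeric(1))
  prof <- prof[c((n / 2 + 1):n, 1:(n / 2))]  # centre the peak
  expect_equal(as.vector(psf$kernel), prof, tolerance = 1e-10)
})

test_that("domain errors of PSF construction and deconvolution", {
  acq <- acq_spec(matrix_size = 16)
  expect_error(compute_psf(16, acq_spec(readout_ms = 1e-12 - 1),
                           relax_times()), "readout|positive")
  psf <- compute_psf(16, acq, relax_times())
  img <- volume_map(array(1, c(16, 16, 16)), 2.8)
  expect_error(deconvolve(img, psf, iterations = 0), "iterations")
  bad <- psf
  bad$kernel[1, 1, 1] <- -sum(abs(psf$kernel))
  expect_error(deconvolve(img, bad, 5), "negative mass")
})

test_that("delta-kernel Richardson-Lucy is the identity", {
  acq <- acq_spec(matrix_size = 16)
  delta <- compute_psf(16, acq, relax_times(37, 1e5, 1e6, 0.6))
  img <- volume_map(array(runif(16^3, 1, 2), c(16, 16, 16)), 2.8)
  out <- deconvolve(img, delta, 5)
  expect_equal(unclass(out), unclass(img), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("restoration reduces RMSE on a constructed blur pair and
          conserves flux", {
  acq <- acq_spec(matrix_size = 32)
  psf <- compute_psf(32, acq, relax_times(37, 0.5, 15, 0.6))
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  truth <- array(0, c(32, 32, 32))
  truth[(g$x - 16)^2 + (g$y - 16)^2 + (g$z - 16)^2 <= 36] <- 100
  truth <- volume_map(truth, 2.8)
  blurred <- apply_psf(truth, psf)
  restored <- deconvolve(blurred, psf, 10)
  rmse <- function(a) sqrt(mean((unclass(a) - unclass(truth))^2))
  expect_lt(rmse(restored), rmse(blurred))
  expect_lt(abs(sum(restored) - sum(blurred)) / sum(blurred), 0.01)
  expect_true(all(restored >= 0))
})

test_that("calibration line fitting matches exact and minimal cases", {
  cal <- fit_calibration(c(25, 50, 75, 100, 125),
                         c(50, 100, 150, 200, 250))
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  two <- fit_calibration(c(30, 90), c(10, 40))
  expect_equal(two$slope, 0.5, tolerance = 1e-12)
  expect_equal(two$intercept, -5, tolerance = 1e-12)
  expect_equal(two$r_squared, 1)
  expect_error(fit_calibration(c(50, 50), c(1, 2)), "distinct")
})

test_that("signal_to_tsc inverts the forward signal map and clips floor", {
  relax <- relax_times()
  acq <- acq_spec()
  lam <- lambda_factor(relax, acq)
  cal <- fit_calibration(c(0, 100), c(3, 3 + 100 * 1.7))  # slope 1.7, int 3
  sig <- volume_map(array((1.7 * 140 + 3) * lam, c(4, 4, 4)), 2.8)
  tsc <- signal_to_tsc(sig, cal, relax, acq)
  expect_equal(unclass(tsc), array(140, c(4, 4, 4)), tolerance = 1e-9,
               ignore_attr = TRUE)

  zero <- signal_to_tsc(volume_map(array(0, c(4, 4, 4)), 2.8), cal,
                        relax, acq)
  expect_true(all(zero == 0))
  expect_equal(attr(zero, "n_clipped"), 64)
  bad <- cal; bad$slope <- -1
  expect_error(signal_to_tsc(sig, bad, relax, acq), "slope")
})

test_that("TSC is invariant to a shared gain on calibration and image", {
  relax <- relax_times(); acq <- acq_spec()
  lam <- lambda_factor(relax, acq)
  conc <- c(25, 50, 75, 100, 125)
  gain <- 3.7
  cal1 <- fit_calibration(conc, conc * 0.8)
  cal2 <- fit_calibration(conc, conc * 0.8 * gain)
  img <- volume_map(array(0.8 * 60 * lam, c(3, 3, 3)), 2.8)
  img_gained <- volume_map(unclass(img) * gain, 2.8)
  t1 <- signal_to_tsc(img, cal1, relax, acq)
  t2 <- signal_to_tsc(img_gained, cal2, relax, acq)
  expect_equal(unclass(t1), unclass(t2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("lambda correction then un-correction is the identity", {
  relax <- relax_times(32, 0.5, 16, 0.6)
  acq <- acq_spec()
  lam <- lambda_factor(relax, acq)
  x <- runif(100, 0, 150)
  expect_equal((x / lam) * lam, x, tolerance = 1e-12)
})
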