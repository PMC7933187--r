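test_that("phantom truth enforces the three-compartment consistency", {
  lab <- array(1L, c(2, 2, 2))
  good <- data.frame(label = 1L, name = "tumor", c_ic_mM = 30, ecv = 0.25,
                     wf = 0.9,
                     tsc_mM = 0.25 * 140 + 0.65 * 30 + 0.1 * 10)
  expect_equal(good$tsc_mM, 55.5)   # worked example of the voxel model
  tr <- phantom_truth(lab, good, 2.8)
  expect_s3_class(tr, "phantom_truth")

  bad <- good; bad$tsc_mM <- 50
  expect_error(phantom_truth(lab, bad, 2.8), "inconsistent")
  rev <- good; rev$ecv <- 0.95
  expect_error(phantom_truth(lab, rev, 2.8), "ECV <= WF")
})

test_that("noiseless unblurred calibration gels are proportional to
          concentration", {
  acq <- small_acq(32)
  ph <- make_calibration_phantom(c(25, 50, 75, 100, 125), acq = acq,
                                 noise_sigma = 0,
                                 b1 = list(type = "flat", strength = 0),
                                 use_psf = FALSE, seed = 1)
  gels <- ph$truth$params[ph$truth$params$name != "bath", ]
  means <- vapply(gels$label, function(l)
    mean(ph$image[ph$truth$labels == l]), numeric(1))
  expect_equal(means / means[1], 1:5, tolerance = 1e-12)
})

test_that("phantom generation is bit-for-bit reproducible by seed", {
  acq <- small_acq(24)
  a <- make_calibration_phantom(acq = acq, snr = 30, seed = 7)
  b <- make_calibration_phantom(acq = acq, snr = 30, seed = 7)
  expect_identical(unclass(a$image), unclass(b$image))
  c <- make_calibration_phantom(acq = acq, snr = 30, seed = 8)
  expect_false(identical(unclass(a$image), unclass(c$image)))

  p1 <- make_breast_phantom(acq = small_acq(16), upsample = 2L, seed = 3)
  p2 <- make_breast_phantom(acq = small_acq(16), upsample = 2L, seed = 3)
  expect_identical(unclass(p1$sodium), unclass(p2$sodium))
  expect_identical(unclass(p1$echoes[[2]]), unclass(p2$echoes[[2]]))
  expect_identical(unclass(p1$t1_post), unclass(p2$t1_post))
})

test_that("Rician noise matches a Monte-Carlo estimate of its mean", {
  x <- volume_map(array(100, c(24, 24, 24)), 1)
  y <- add_rician_noise(x, sigma = 2, seed = 7)
  set.seed(1)
  oracle <- mean(sqrt((100 + rnorm(2e5, 0, 2))^2 + rnorm(2e5, 0, 2)^2))
  se <- 2 / sqrt(length(y))
  expect_lt(abs(mean(y) - oracle), 6 * se)
  # noise floor: the Rician mean exceeds the noiseless signal
  expect_gt(mean(y), 100)
})

test_that("forward model is linear: doubling concentrations doubles the
          noiseless image", {
  acq <- small_acq(24)
  a <- make_calibration_phantom(c(25, 50), acq = acq, bath_mM = 50,
                                noise_sigma = 0, seed = 2)
  b <- make_calibration_phantom(c(50, 100), acq = acq, bath_mM = 100,
                                noise_sigma = 0, seed = 2)
  expect_equal(unclass(b$image), 2 * unclass(a$image), tolerance = 1e-12)
})

test_that("validation gels of equal concentration differ only by their
          lambda ratio", {
  acq <- tissue_acq(32)
  specs <- data.frame(concentration_mM = c(140, 140, 140),
                      agar_percent = c(0, 4, 8))
  ph <- make_validation_phantom(specs, acq = acq, noise_sigma = 0,
                                b1 = list(type = "flat", strength = 0),
                                use_psf = FALSE, seed = 1)
  means <- vapply(1:3, function(l) mean(ph$image[ph$truth$labels == l]),
                  numeric(1))
  lams <- vapply(list(agar_relax(0), agar_relax(4), agar_relax(8)),
                 function(r) lambda_factor(r, acq), numeric(1))
  expect_equal(means / means[1], lams / lams[1], tolerance = 1e-12)
})

test_that("phantom geometry errors are raised", {
  expect_error(make_validation_phantom(data.frame(concentration_mM =
                                                    numeric(0),
                                                  agar_percent = numeric(0)),
                                       acq = small_acq(16)), "empty gel")
  expect_error(make_calibration_phantom(rep(50, 5), acq = small_acq(8),
                                        gel_radius_frac = 0.45),
               "geometry")
  expect_error(make_calibration_phantom(c(-5, 10), acq = small_acq(16)),
               "positive")
})

test_that("breast phantom honours its stated truth and degenerate limits", {
  ph <- make_breast_phantom(acq = small_acq(16), upsample = 2L,
                            noise_sigma = 0,
                            b1 = list(type = "flat", strength = 0),
                            use_psf = FALSE, t1_noise_ms = 0,
                            proton_snr = Inf, seed = 1)
  # noiseless, no blur, flat bias: sodium image equals lambda * truth TSC
  lam <- lambda_factor(relax_times(), small_acq(16))
  tsc_lab <- c(0, ph$truth$params$tsc_mM)
  expected <- array(tsc_lab[ph$labels_sodium + 1L], dim(ph$sodium)) * lam
  expect_equal(unclass(ph$sodium), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # tumor label truth follows the three-compartment identity
  tum <- ph$truth$params[ph$truth$params$name == "tumor", ]
  expect_equal(tum$tsc_mM,
               tum$ecv * 140 + (tum$wf - tum$ecv) * tum$c_ic_mM +
                 (1 - tum$wf) * 10, tolerance = 1e-12)
  # muscle label carries the reference ECV that anchors the T1 model
  mus <- ph$truth$params[ph$truth$params$name == "muscle", ]
  expect_equal(mus$ecv, 0.12)
  expect_true(any(ph$muscle_mask))

  p <- breast_tissue_params()
  expect_error(make_breast_phantom(params = p[p$name != "muscle", ],
                                   acq = small_acq(16)),
               "muscle")
})
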