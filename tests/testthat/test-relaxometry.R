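test_that("lambda factor matches the independent closed-form oracle", {
  # fibroglandular tissue values under the sodium protocol
  expect_equal(lambda_factor(relax_times(37, 0.5, 15, 0.6),
                             acq_spec(60, 0.2, 80)),
               lambda_oracle(37, 0.5, 15, 0.6, 60, 0.2, 80),
               tolerance = 1e-12)
  expect_equal(lambda_factor(relax_times(37, 0.5, 15, 0.6),
                             acq_spec(60, 0.2, 80)), 0.662,
               tolerance = 1e-3)
  # central relaxation values of the error-propagation table
  expect_equal(lambda_factor(relax_times(32, 0.5, 16, 0.6),
                             acq_spec(60, 0.2, 80)),
               lambda_oracle(32, 0.5, 16, 0.6, 60, 0.2, 80),
               tolerance = 1e-12)
  expect_equal(lambda_factor(relax_times(32, 0.5, 16, 0.6),
                             acq_spec(60, 0.2, 80)), 0.693,
               tolerance = 1e-3)
})

test_that("lambda reaches 1 in the fully-relaxed, zero-TE limit", {
  lam <- lambda_factor(relax_times(37, 0.5, 15, 0.6),
                       acq_spec(TR = 37 * 200, TE = 0, flip_deg = 90))
  expect_equal(lam, 1, tolerance = 1e-12)
})

test_that("lambda is monotone in TR, TE and both T2 components", {
  base <- function(TR = 60, TE = 0.2, T2s = 0.5, T2l = 15)
    lambda_factor(relax_times(37, T2s, T2l, 0.6),
                  acq_spec(TR, TE, 80))
  trs <- seq(10, 200, length.out = 15)
  expect_true(all(diff(vapply(trs, function(x) base(TR = x),
                              numeric(1))) > 0))
  tes <- seq(0, 3, length.out = 15)
  expect_true(all(diff(vapply(tes, function(x) base(TE = x),
                              numeric(1))) < 0))
  t2s <- seq(0.2, 5, length.out = 15)
  expect_true(all(diff(vapply(t2s, function(x) base(T2s = x),
                              numeric(1))) > 0))
  t2l <- seq(5, 40, length.out = 15)
  expect_true(all(diff(vapply(t2l, function(x) base(T2l = x),
                              numeric(1))) > 0))
})

test_that("relaxation-time containers reject unphysical values", {
  expect_error(relax_times(T1 = -1), "T1")
  expect_error(relax_times(T2s = 0), "positive")
  expect_error(relax_times(T2s = 20, T2l = 10), "exceed")
  expect_error(relax_times(fast_fraction = 1.2), "fast_fraction")
  expect_error(acq_spec(TR = 0), "TR")
  expect_error(acq_spec(flip_deg = 190), "flip")
  expect_error(lambda_factor(relax_times(), acq_spec(TE = c(1, 2))),
               "single TE")
})

test_that("monoexponential T1 fit recovers truth and flags degeneracy", {
  TRs <- c(10, 25, 50, 100, 200, 300)
  sat <- function(TR, T1, fa) {
    e <- exp(-TR / T1)
    (1 - e) / (1 - cos(fa * pi / 180) * e)
  }
  sig <- 5 * sat(TRs, 37, 80)
  fit <- fit_t1_mono(TRs, sig, 80)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate$T1 - 37) / 37, 1e-3)
  expect_lt(abs(fit$amplitude - 5) / 5, 1e-3)

  flat <- fit_t1_mono(TRs, rep(3, 6), 80)
  expect_false(flat$converged)
  expect_match(flat$flags, "non-identifiable")
  expect_error(fit_t1_mono(c(10, 10, 10), c(1, 1, 1)), "distinct")
})

test_that("noisy T1 recovery is accurate in the median", {
  TRs <- c(10, 25, 50, 100, 200, 300)
  e <- exp(-TRs / 37)
  sig <- 5 * (1 - e) / (1 - cos(80 * pi / 180) * e)
  set.seed(202)
  t1s <- replicate(300, {
    noisy <- pmax(sig + rnorm(length(sig), sd = max(sig) / 50), 0)
    fit_t1_mono(TRs, noisy, 80)$estimate$T1
  })
  expect_lt(abs(stats::median(t1s) - 37) / 37, 0.05)
})

test_that("biexponential T2 fit recovers all parameters noiselessly", {
  TEs <- exp(seq(log(0.1), log(60), length.out = 12))
  sig <- 10 * (0.6 * exp(-TEs / 0.5) + 0.4 * exp(-TEs / 15))
  fit <- fit_t2_biexp(TEs, sig)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate$T2s - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$estimate$T2l - 15) / 15, 0.01)
  expect_lt(abs(fit$estimate$fast_fraction - 0.6), 0.01)
})

test_that("monoexponential input drives the fraction to a boundary", {
  TEs <- exp(seq(log(0.1), log(60), length.out = 12))
  fit <- fit_t2_biexp(TEs, 10 * exp(-TEs / 5))
  expect_match(fit$flags, "monoexponential")
  expect_error(fit_t2_biexp(c(1, 2, 3), c(3, 2, 1)), "distinct")
})

test_that("noisy biexponential recovery with the fraction fixed at 0.6", {
  TEs <- exp(seq(log(0.1), log(60), length.out = 12))
  sig <- 10 * (0.6 * exp(-TEs / 0.5) + 0.4 * exp(-TEs / 15))
  set.seed(203)
  est <- replicate(200, {
    noisy <- sig + rnorm(length(sig), sd = max(sig) / 30)
    f <- fit_t2_biexp(TEs, noisy, fix_fraction = 0.6)
    c(f$estimate$T2s, f$estimate$T2l)
  })
  expect_lt(abs(stats::median(est[1, ]) - 0.5) / 0.5, 0.10)
  expect_lt(abs(stats::median(est[2, ]) - 15) / 15, 0.10)
})

test_that("simulate-then-fit is a fixed point of the T2 model", {
  TEs <- exp(seq(log(0.1), log(60), length.out = 12))
  sig <- 10 * (0.6 * exp(-TEs / 0.5) + 0.4 * exp(-TEs / 15))
  f1 <- fit_t2_biexp(TEs, sig)
  resim <- f1$amplitude *
    (f1$estimate$fast_fraction * exp(-TEs / f1$estimate$T2s) +
       (1 - f1$estimate$fast_fraction) * exp(-TEs / f1$estimate$T2l))
  f2 <- fit_t2_biexp(TEs, resim)
  expect_lt(abs(f2$estimate$T2s - f1$estimate$T2s), 1e-4)
  expect_lt(abs(f2$estimate$T2l - f1$estimate$T2l), 1e-3)
})
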