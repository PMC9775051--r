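# Multi-exponential reconvolution: the convolution model, the fitter and
# its parameter-recovery properties.

delta_irf <- function(n = 512L, dt = 0.02, at = 1L) {
  counts <- numeric(n); counts[at] <- 1
  decay_curve(counts, channel_width = dt)
}

test_that("convolution with a delta IRF reproduces the pure exponential", {
  n <- 512L; dt <- 0.02
  irf <- delta_irf(n, dt)
  tc <- (seq_len(n) - 0.5) * dt
  m <- convolve_model(irf, amplitudes = 100, lifetimes = 1.5)
  pure <- 100 * exp(-tc / 1.5)
  expect_equal(m, pure, tolerance = 1e-9)
  # +1 channel shift translates the model by exactly one channel
  m_shift <- convolve_model(irf, 100, 1.5, shift = dt)
  expect_equal(m_shift[-1], m[-n], tolerance = 1e-9)
})

test_that("total model counts match the analytic integral", {
  # decay fully contained in the window: total = sum(alpha_j tau_j)/dt
  n <- 4096L; dt <- 0.01
  tc <- (seq_len(n) - 0.5) * dt
  irf_e <- dnorm(tc, 0.5, 0.04) * dt
  irf <- decay_curve(irf_e, channel_width = dt)
  alpha <- c(800, 300); tau <- c(0.4, 2.0); base <- 1.5
  m <- convolve_model(irf, alpha, tau, baseline = base)
  expect_equal(sum(m), sum(alpha * tau) / dt + base * n, tolerance = 1e-3)
})

test_that("mismatched channel grids are rejected", {
  irf <- delta_irf(512L)
  expect_error(convolve_model(irf, 1, 1, n_channels = 400L), "grids differ")
  d <- decay_curve(rep(10, 512), channel_width = 0.04)
  expect_error(fit_decay(d, irf), "share the channel grid")
})

test_that("single-exponential lifetime is recovered within 2%", {
  fx <- single_exp_decay(tau = 2, peak = 1e4, seed = 3)
  fit <- fit_decay(fx$decay, fx$irf, n_components = 1L)
  expect_true(fit$converged)
  expect_lt(abs(fit$lifetimes - 2) / 2, 0.02)
  # well-populated window: reduced chi-square near 1 (a long empty tail
  # depresses it under the 1/max(y,1) weighting convention)
  fx2 <- single_exp_decay(tau = 2, peak = 1e4, n = 1024L, dt = 0.01, seed = 4)
  fit2 <- fit_decay(fx2$decay, fx2$irf, n_components = 1L)
  expect_gt(fit2$chi2_reduced, 0.8)
  expect_lt(fit2$chi2_reduced, 1.3)
  expect_lt(abs(fit2$lifetimes - 2) / 2, 0.02)
})

test_that("two lifetimes with equal integral fractions are recovered within 10%", {
  n <- 2048L; dt <- 0.02
  tc <- (seq_len(n) - 0.5) * dt
  irf_e <- dnorm(tc, 0.5, 0.1 / 2.3548) * dt
  irf <- decay_curve(irf_e / max(irf_e) * 1e4, channel_width = dt)
  # equal integral fractions: alpha1*tau1 = alpha2*tau2
  alpha <- c(6, 1) * 1000; tau <- c(0.5, 3.0)
  m <- pmax(convolve_model(irf, alpha, tau), 0)
  m <- m / max(m) * 1e4
  set.seed(11)
  decay <- decay_curve(rpois(n, m), channel_width = dt, wavelength = 450)
  fit <- fit_decay(decay, irf, n_components = 2L)
  expect_lt(abs(fit$lifetimes[1] - 0.5) / 0.5, 0.10)
  expect_lt(abs(fit$lifetimes[2] - 3.0) / 3.0, 0.10)
})

test_that("noiseless self-fit recovers its own parameters almost exactly", {
  fx <- single_exp_decay(tau = 1.2, peak = 5e3, noise = FALSE)
  fit <- fit_decay(fx$decay, fx$irf, n_components = 1L)
  expect_lt(fit$chi2_reduced, 1e-4)
  expect_lt(abs(fit$lifetimes - 1.2) / 1.2, 1e-3)
})

test_that("median lifetime error over 20 seeded replicates stays below 2%", {
  errs <- vapply(1:20, function(s) {
    fx <- single_exp_decay(tau = 2, peak = 1e4, n = 1024L, dt = 0.04, seed = s)
    fit <- fit_decay(fx$decay, fx$irf, n_components = 1L)
    abs(fit$lifetimes - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("fits are invariant to uniform count rescaling up to amplitude scale", {
  fx <- single_exp_decay(tau = 1.5, peak = 8e3, seed = 5)
  f1 <- fit_decay(fx$decay, fx$irf, n_components = 1L)
  d4 <- decay_curve(fx$decay$counts * 4, channel_width = fx$decay$channel_width,
                    wavelength = 450)
  f4 <- fit_decay(d4, fx$irf, n_components = 1L)
  # invariance holds up to the Poisson weight floor in near-empty channels
  expect_equal(f4$lifetimes, f1$lifetimes, tolerance = 0.01)
  expect_equal(f4$amplitudes / f1$amplitudes, 4, tolerance = 0.01)
})

test_that("a redundant component does not worsen the reduced chi-square", {
  fx <- single_exp_decay(tau = 2, peak = 1e4, seed = 8)
  f1 <- fit_decay(fx$decay, fx$irf, n_components = 1L)
  f2 <- fit_decay(fx$decay, fx$irf, n_components = 2L)
  expect_lt(f2$chi2_reduced, f1$chi2_reduced * 1.05)
})

test_that("deconvolved model decay has the analytic value, integral and shape", {
  fit <- structure(list(amplitudes = c(300, 700), lifetimes = c(0.5, 2),
                        n_components = 2L), class = "multiexp_fit")
  tg <- seq(0, 50, by = 0.001)
  d <- model_decay_noiseless(fit, tg)
  expect_equal(d[1], 1000, tolerance = 1e-2)
  expect_equal(sum(d) * 0.001, 300 * 0.5 + 700 * 2, tolerance = 1e-2)
  expect_true(all(diff(d) < 0))
})

test_that("IRF width estimate matches the generating FWHM", {
  tr <- small_truth(irf_fwhm = 0.12)
  ds <- generate_dataset(tr)
  expect_equal(irf_fwhm_estimate(ds$irf), 0.12, tolerance = 0.05)
})
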