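# Headline TDFS observables: nu(0), nu(inf), delta_nu, tau_r.

make_band <- function(peak_nu, delta = 3500, gamma = 0.2, n = 60) {
  # band specified in wavenumber, emitted as a wavelength-domain spectrum
  nu <- seq(peak_nu - 2.2 * delta, peak_nu + 2.2 * delta, length.out = n)
  data.frame(wavelength = sort(1e7 / nu),
             intensity = lognormal_eval(sort(nu, decreasing = TRUE),
                                        1, peak_nu, delta, gamma))
}

test_that("time-zero estimate reproduces the reference-solvent construction", {
  # polar absorption at 27000, reference Stokes difference 4000 -> 23000
  abs_polar <- make_band(27000)
  abs_ref <- make_band(28500)
  em_ref <- make_band(24500)
  expect_equal(estimate_time_zero(abs_polar, abs_ref, em_ref), 23000,
               tolerance = 1e-3)
  # polar == reference absorption -> nu(0) equals the reference emission peak
  expect_equal(estimate_time_zero(abs_ref, abs_ref, em_ref), 24500,
               tolerance = 1e-3)
  # common shift of all three spectra moves nu(0) by the polar term only
  shift_band <- function(b, d) {
    nu <- 1e7 / b$wavelength + d
    data.frame(wavelength = 1e7 / nu, intensity = b$intensity)
  }
  v1 <- estimate_time_zero(shift_band(abs_polar, 500), abs_ref, em_ref)
  expect_equal(v1, 23500, tolerance = 0.05)
  v2 <- estimate_time_zero(abs_polar, shift_band(abs_ref, 500),
                           shift_band(em_ref, 500))
  expect_equal(v2, 23000, tolerance = 0.1)
})

test_that("edge-peaked spectra are rejected for time-zero estimation", {
  ramp <- data.frame(wavelength = seq(400, 500, 5),
                     intensity = seq(1, 2, length.out = 21))
  expect_error(estimate_time_zero(ramp, make_band(25000), make_band(22000)),
               "abs_polar")
})

test_that("nu(inf) extrapolation recovers an exact single exponential", {
  t <- seq(0.05, 12, length.out = 60)
  nu <- 21000 + 2800 * exp(-t / 2)
  rf <- extrapolate_nu_inf(t, nu)
  expect_lt(abs(rf$nu_inf - 21000), 1)
  expect_equal(rf$nu0_fit, 23800, tolerance = 1e-2)
  expect_false(rf$incomplete)
})

test_that("truncation within one relaxation time raises the incomplete flag", {
  t <- seq(0.05, 2, length.out = 30)       # window = 1 x tau
  nu <- 21000 + 2800 * exp(-t / 2)
  expect_warning(rf <- extrapolate_nu_inf(t, nu), "incomplete relaxation")
  expect_true(rf$incomplete)
})

test_that("non-relaxing series are rejected", {
  t <- seq(0.05, 10, length.out = 30)
  expect_error(extrapolate_nu_inf(t, 21000 + 100 * (1 - exp(-t / 2))),
               "non-decreasing")
  set.seed(1)
  flat <- 21000 + rnorm(30, 0, 0.5)
  res <- tryCatch(extrapolate_nu_inf(t, flat), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "non-decreasing")
  } else {
    expect_lt(sum(res$components$A), 5)    # zero-amplitude fit
  }
})

test_that("the overall shift is nu0 - nu_inf with a non-positive flag", {
  expect_equal(overall_shift(25000, 22000), 3000)
  expect_warning(z <- overall_shift(22000, 22000), "non-positive")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))
})

test_that("relaxation time: closed forms and numeric agreement", {
  # single component: tau_r = tau exactly (analytic), within 1% numerically
  t <- exp(seq(log(0.001), log(12), length.out = 200))
  comp <- data.frame(A = 3000, tau = 1)
  rt <- relaxation_time(t, 21000 + 3000 * exp(-t), 21000, comp)
  expect_equal(rt$tau_r, 1)
  expect_lt(abs(rt$tau_r_numeric - 1), 0.01)
  # equal-amplitude pair: tau_r = sum(a tau) = 2.0
  comp2 <- data.frame(A = c(1500, 1500), tau = c(1, 3))
  nu2 <- 21000 + 1500 * exp(-t) + 1500 * exp(-t / 3)
  rt2 <- relaxation_time(t, nu2, 21000, comp2)
  expect_equal(rt2$tau_r, 2.0)
  expect_lt(abs(rt2$tau_r_numeric - 2) / 2, 0.01)
  expect_error(relaxation_time(t, nu2, 21000, comp2, delta_nu = -1),
               "positive")
})

test_that("tau_r is invariant under a common additive shift of the series", {
  t <- exp(seq(log(0.01), log(15), length.out = 80))
  comp <- data.frame(A = c(1000, 2000), tau = c(0.5, 2.5))
  nu <- 21000 + 1000 * exp(-t / 0.5) + 2000 * exp(-t / 2.5)
  r0 <- relaxation_time(t, nu, 21000, comp)
  r1 <- relaxation_time(t, nu + 500, 21500, comp)
  expect_equal(r1$tau_r, r0$tau_r)
  expect_equal(r1$tau_r_numeric, r0$tau_r_numeric, tolerance = 1e-9)
})

test_that("the correlation function starts at 1 and stays in [0, 1]", {
  t <- seq(0, 10, by = 0.1)
  nu <- 21000 + 2500 * (0.4 * exp(-t / 0.5) + 0.6 * exp(-t / 3))
  C <- correlation_function(nu, 21000, nu[1] - 21000)
  expect_equal(C[1], 1)
  expect_true(all(C >= 0 & C <= 1 + 1e-12))
  expect_true(all(diff(C) < 0))
})
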