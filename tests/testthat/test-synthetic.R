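# Synthetic-data generator: closed-form nu(t), surface construction,
# Poisson statistics, reproducibility.

test_that("true_nu follows the closed multi-exponential form", {
  tr1 <- ground_truth(nu_inf = 22000, delta_nu = 3000,
                      components = list(a = 1, tau = 1), lifetime = 4,
                      n_channels = 4096L)
  # independent closed form: 22000 + 3000 * exp(-1)
  expect_equal(true_nu(1, tr1), 22000 + 3000 * exp(-1), tolerance = 1e-12)
  expect_equal(true_nu(0, tr1), 25000)
  expect_lt(abs(true_nu(1e4, tr1) - 22000), 1e-6)

  tr2 <- small_truth()
  t <- seq(0, 10, by = 0.1)
  nu <- true_nu(t, tr2)
  expect_true(all(diff(nu) < 0))          # strictly decreasing
  expect_equal(nu[1], 24000)
  expect_error(true_nu(-0.1, tr2), "non-negative")
})

test_that("ground truth validates amplitudes, positivity and window", {
  expect_error(ground_truth(components = list(a = c(0.6, 0.5),
                                              tau = c(1, 2))), "sum to 1")
  expect_error(ground_truth(delta_nu = -5), "delta_nu")
  expect_warning(ground_truth(lifetime = 50), "5x")
  expect_warning(ground_truth(peak_counts = 50), "unstable")
})

test_that("noiseless TRES surface peaks at true_nu and decays with the lifetime", {
  tr <- small_truth(gamma = -0.3)
  tg <- c(0, 0.2, 1, 3, 8)
  surf <- generate_tres_surface(tr, tg)
  nu_grid <- surf$wavenumbers
  dnu_res <- max(abs(diff(nu_grid)))
  peaks <- true_nu(tg, tr)
  for (i in seq_along(tg)) {
    am <- nu_grid[which.max(surf$surface[i, ])]
    expect_lt(abs(am - peaks[i]), dnu_res)
  }
  # fixed-shape band: the full band integral scales as the population decay
  # (needs wavelengths that cover the whole moving band)
  tr_wide <- small_truth(gamma = -0.3, wavelengths = seq(320, 700, by = 5))
  sw <- generate_tres_surface(tr_wide, tg)
  tot <- apply(sw$surface, 1L, function(y) {
    n <- length(sw$wavenumbers)
    sum((y[-1] + y[-n]) * diff(sw$wavenumbers)) / 2
  })
  expect_equal(tot / tot[1], exp(-tg / tr_wide$lifetime), tolerance = 0.005)

  # symmetric limit: gamma = 0 slice is a Gaussian of FWHM delta
  tr0 <- small_truth(gamma = 0)
  s0 <- generate_tres_surface(tr0, 0)
  gauss <- exp(-log(2) * (2 * (s0$wavenumbers - 24000) / tr0$delta)^2)
  expect_equal(s0$surface[1, ], gauss, tolerance = 1e-12)
})

test_that("optional width drift broadens the band over time", {
  tr <- small_truth(width_drift = 200)          # +200 cm^-1 per ns
  tg <- c(0, 5)
  s <- generate_tres_surface(tr, tg)
  fwhm_of <- function(y) {
    f <- fit_lognormal(s$wavenumbers, y)
    f$delta * ifelse(f$gamma == 0, 1, sinh(f$gamma) / f$gamma)
  }
  expect_gt(fwhm_of(s$surface[2, ]) / fwhm_of(s$surface[1, ]), 1.1)
  # default truth keeps the shape constant
  s0 <- generate_tres_surface(small_truth(), tg)
  f1 <- fit_lognormal(s0$wavenumbers, s0$surface[1, ])
  f2 <- fit_lognormal(s0$wavenumbers, s0$surface[2, ])
  expect_equal(f2$delta, f1$delta, tolerance = 1e-3)
})

test_that("dataset generation is bit-reproducible and integer-valued", {
  tr <- small_truth(seed = 42)
  d1 <- generate_dataset(tr)
  d2 <- generate_dataset(tr)
  expect_identical(d1, d2)
  for (d in d1$decays) {
    expect_true(all(d$counts >= 0))
    expect_identical(d$counts, round(d$counts))
  }
  expect_identical(as.numeric(names(d1$decays)), tr$wavelengths)
  # different seed changes the draw
  d3 <- generate_dataset(small_truth(seed = 43))
  expect_false(identical(d1$decays[[1]]$counts, d3$decays[[1]]$counts))
})

test_that("channel counts are Poisson around the noiseless model", {
  tr <- small_truth(n_channels = 256L, channel_width = 0.08,
                    wavelengths = c(440, 480), peak_counts = 2000)
  noiseless <- generate_dataset(tr, noise = FALSE)
  nrep <- 100
  acc <- 0
  for (r in seq_len(nrep))
    acc <- acc + generate_dataset(small_truth(
      n_channels = 256L, channel_width = 0.08, wavelengths = c(440, 480),
      peak_counts = 2000, seed = r))$decays[[1]]$counts
  m <- acc / nrep
  e <- noiseless$decays[[1]]$counts
  se <- sqrt(pmax(e, 1e-12) / nrep)
  bright <- e > 50
  z <- (m[bright] - e[bright]) / se[bright]
  expect_lt(mean(abs(z) > 3), 0.01)      # ~0.3% expected beyond 3 SE
  expect_lt(abs(mean(z)), 0.5)
})

test_that("steady-state spectrum peaks between the unrelaxed and relaxed maxima", {
  tr <- small_truth()
  ds <- generate_dataset(tr, noise = FALSE)
  ss <- ds$steady_state
  pk <- ss$wavelength[which.max(ss$intensity)]
  expect_gt(pk, 1e7 / (tr$nu_inf + tr$delta_nu))   # redder than nu(0)
  expect_lt(pk, 1e7 / tr$nu_inf)                   # bluer than nu(inf)
})

test_that("GP pairs invert the generalized polarization with Poisson noise", {
  nl <- generate_gp_pair(0, 1000, noise = FALSE)
  expect_equal(nl[["I440"]], nl[["I490"]])
  expect_equal(generate_gp_pair(1, 1000, noise = FALSE)[["I490"]], 0)
  p <- generate_gp_pair(0.3, 1e6, seed = 7)
  expect_lt(abs(compute_gp(p[["I440"]], p[["I490"]]) - 0.3), 0.01)
  expect_error(generate_gp_pair(1.2, 100), "\\[-1, 1\\]")
  expect_identical(generate_gp_pair(0.3, 1e4, seed = 5),
                   generate_gp_pair(0.3, 1e4, seed = 5))
})

test_that("toy trajectories are seeded and validated", {
  t1 <- toy_bilayer(n_frames = 3, seed = 9)
  t2 <- toy_bilayer(n_frames = 3, seed = 9)
  expect_identical(t1, t2)
  expect_error(generate_toy_trajectory(0, list(a = list(count = 1)),
                                       c(10, 10, 10)), "0 frames")
  # mirrored group puts mass at both +20 and -20
  z <- t1$frames[[1]]$xyz[t1$groups$PO4, 3]
  expect_gt(sum(z > 10), 50)
  expect_gt(sum(z < -10), 50)
})
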