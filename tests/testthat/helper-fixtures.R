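# Shared fixtures: a reduced synthetic experiment that keeps unit tests
# fast (fewer channels / lower counts than the full study conditions).

small_truth <- function(seed = 1L, ...) {
  args <- list(
    nu_inf = 21000, delta_nu = 3000,
    components = list(a = c(0.5, 0.5), tau = c(0.5, 2.5)),
    lifetime = 3, delta = 3000, gamma = -0.3,
    irf_fwhm = 0.1, channel_width = 0.02, n_channels = 1024L,
    peak_counts = 5000, wavelengths = seq(400, 540, by = 10), seed = seed)
  args[names(list(...))] <- list(...)
  do.call(ground_truth, args)
}

# single-exponential TCSPC pair (decay + Gaussian IRF) with known lifetime
single_exp_decay <- function(tau = 2, peak = 1e4, n = 2048L, dt = 0.02,
                             irf_fwhm = 0.1, t0 = 0.5, seed = 1L,
                             noise = TRUE) {
  tc <- (seq_len(n) - 0.5) * dt
  irf_e <- dnorm(tc, t0, irf_fwhm / (2 * sqrt(2 * log(2)))) * dt
  irf <- decay_curve(irf_e / max(irf_e) * peak, channel_width = dt)
  m <- pmax(convolve_model(irf, amplitudes = 1, lifetimes = tau), 0)
  m <- m / max(m) * peak
  counts <- if (noise) { set.seed(seed); rpois(n, m) } else m
  list(decay = decay_curve(counts, channel_width = dt, wavelength = 450),
       irf = irf, expectation = m)
}

toy_bilayer <- function(n_frames = 20, seed = 1L, box = c(60, 60, 100)) {
  generate_toy_trajectory(
    n_frames,
    groups = list(
      PO4 = list(count = 200, mean_z = 20, sd_z = 2),
      Ca  = list(count = 60,  mean_z = 18, sd_z = 3),
      W   = list(count = 400, uniform = TRUE)),
    box = box, lipids_per_leaflet = 64L, seed = seed)
}
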