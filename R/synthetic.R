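# Synthetic TDFS data with known ground truth.
#
# The generator produces exactly the objects the measurement chain produces
# (per-wavelength TCSPC histograms, an IRF histogram, a steady-state
# spectrum), from a fully specified ground truth, so that every downstream
# stage can be validated against known parameter values.

#' Ground truth for a synthetic TDFS experiment
#'
#' Specifies the emitting state completely: the relaxed emission maximum
#' `nu_inf`, the overall dynamic Stokes shift `delta_nu`, the normalized
#' multi-exponential relaxation `components` so that the time-dependent peak
#' position is
#' \deqn{\nu(t) = \nu_\infty + \Delta\nu \sum_i a_i e^{-t/\tau_i},}
#' a single population (intensity) lifetime, a log-normal band shape held
#' fixed in time, and the instrument settings (Gaussian IRF FWHM, TCSPC
#' channel width and count, peak counts, detection wavelengths).
#'
#' @param nu_inf fully relaxed emission maximum (cm^-1)
#' @param delta_nu overall dynamic Stokes shift (cm^-1), > 0
#' @param components data.frame or list with `a` (amplitudes, summing to 1)
#'   and `tau` (ns) of the spectral relaxation
#' @param lifetime population decay lifetime (ns)
#' @param delta,gamma log-normal band width (cm^-1) and asymmetry
#' @param irf_fwhm Gaussian IRF full width at half maximum (ns)
#' @param channel_width TCSPC channel width (ns)
#' @param n_channels number of TCSPC channels
#' @param peak_counts expected counts in the brightest channel of the
#'   brightest decay
#' @param wavelengths detection wavelengths (nm)
#' @param t0 position of the IRF maximum within the window (ns)
#' @param width_drift linear band-width change (cm^-1 per ns); 0 keeps the
#'   lineshape constant in time (the default model), nonzero values are for
#'   robustness tests of the analysis chain
#' @param seed root seed for all random generation
#' @return object of class `"tdfs_truth"`
#' @examples
#' tr <- ground_truth()
#' true_nu(c(0, 1, 5), tr)
#' @export
ground_truth <- function(nu_inf = 21000, delta_nu = 3000,
                         components = list(a = c(0.5, 0.5), tau = c(0.5, 2.5)),
                         lifetime = 4, delta = 3000, gamma = -0.3,
                         irf_fwhm = 0.1, channel_width = 0.01,
                         n_channels = 4096L, peak_counts = 1e4,
                         wavelengths = seq(400, 540, by = 10),
                         t0 = 0.5, width_drift = 0, seed = 1L) {
  a <- as.numeric(components$a); tau <- as.numeric(components$tau)
  stopifnot(delta_nu > 0, all(tau > 0), lifetime > 0, delta > 0,
            irf_fwhm > 0, channel_width > 0, n_channels > 0,
            length(a) == length(tau), all(wavelengths > 0))
  if (abs(sum(a) - 1) > 1e-12)
    stop("relaxation amplitudes must sum to 1 (got ", sum(a), ")")
  window <- n_channels * channel_width
  if (window < 5 * max(tau, lifetime))
    warning("TCSPC window (", window, " ns) covers less than 5x the slowest ",
            "time constant; tails will be truncated")
  if (peak_counts < 100)
    warning("peak_counts < 100: decay fits will be unstable")
  structure(list(
    nu_inf = nu_inf, delta_nu = delta_nu, a = a, tau = tau,
    lifetime = lifetime, delta = delta, gamma = gamma,
    irf_fwhm = irf_fwhm, channel_width = channel_width,
    n_channels = as.integer(n_channels), peak_counts = peak_counts,
    wavelengths = sort(wavelengths), t0 = t0, width_drift = width_drift,
    seed = as.integer(seed)
  ), class = "tdfs_truth")
}

#' @export
print.tdfs_truth <- function(x, ...) {
  cat("Synthetic TDFS ground truth\n")
  cat(sprintf("  nu(0) = %.0f, nu(inf) = %.0f, delta_nu = %.0f cm^-1\n",
              x$nu_inf + x$delta_nu, x$nu_inf, x$delta_nu))
  cat(sprintf("  relaxation: %s  (tau_r = %.3f ns)\n",
              paste(sprintf("%.2f x %.2f ns", x$a, x$tau), collapse = " + "),
              sum(x$a * x$tau)))
  cat(sprintf("  lifetime %.2f ns; band delta %.0f cm^-1, gamma %.2f\n",
              x$lifetime, x$delta, x$gamma))
  cat(sprintf("  %d channels x %.4g ns; IRF FWHM %.3f ns; %d wavelengths\n",
              x$n_channels, x$channel_width, x$irf_fwhm, length(x$wavelengths)))
  invisible(x)
}

#' True time-dependent emission maximum
#'
#' @param t times (ns), non-negative
#' @param truth a [ground_truth()] object
#' @return \eqn{\nu(t) = \nu_\infty + \Delta\nu \sum_i a_i e^{-t/\tau_i}} in cm^-1
#' @export
true_nu <- function(t, truth) {
  if (any(t < 0)) stop("t must be non-negative")
  truth$nu_inf + truth$delta_nu *
    colSums(truth$a * exp(-outer(1 / truth$tau, t)))
}

#' Noiseless TRES surface implied by a ground truth
#'
#' The surface is the product of the population decay and the moving band,
#' \eqn{S(\nu, t) = e^{-t/\tau_{fl}}\, L(\nu;\ \nu(t), \Delta, \gamma)},
#' evaluated on the wavenumber grid \eqn{\nu = 10^7/\lambda} implied by the
#' detection wavelengths.
#'
#' @param truth a [ground_truth()] object
#' @param time_grid sorted non-negative times (ns)
#' @return a `"tres"` object (see [reconstruct_tres()]) with no slice fits
#' @export
generate_tres_surface <- function(truth, time_grid) {
  stopifnot(!is.unsorted(time_grid), all(time_grid >= 0))
  nu_grid <- sort(nm_to_wavenumber(truth$wavelengths))
  peaks <- true_nu(time_grid, truth)
  widths <- truth_width(truth, time_grid)
  surf <- vapply(seq_along(time_grid), function(k) {
    exp(-time_grid[k] / truth$lifetime) *
      lognormal_eval(nu_grid, 1, peaks[k], widths[k], truth$gamma)
  }, numeric(length(nu_grid)))
  new_tres(times = time_grid, wavenumbers = nu_grid, surface = t(surf),
           wavelengths = rev(truth$wavelengths))
}

# Gaussian IRF histogram expectation on channel centers (unit area in counts)
irf_expectation <- function(truth) {
  tc <- (seq_len(truth$n_channels) - 0.5) * truth$channel_width
  sigma <- fwhm_to_sigma(truth$irf_fwhm)
  stats::dnorm(tc, mean = truth$t0, sd = sigma) * truth$channel_width
}

# band width at time t (constant unless a linear drift is requested)
truth_width <- function(truth, t) {
  pmax(truth$delta + (truth$width_drift %||% 0) * t, 1)
}

# Ideal (unconvolved) decay of one wavelength on the channel grid, t from 0:
# the band evaluated at a fixed nu while its peak (and optionally width)
# move in time, vectorized over the channel grid
ideal_decay <- function(truth, wavelength) {
  tc <- (seq_len(truth$n_channels) - 0.5) * truth$channel_width
  nu <- nm_to_wavenumber(wavelength)
  w <- truth_width(truth, tc)
  peaks <- true_nu(tc, truth)
  g <- truth$gamma
  band <- if (g == 0) {
    exp(-log(2) * (2 * (nu - peaks) / w)^2)
  } else {
    alpha <- 2 * g * (nu - peaks) / w
    out <- numeric(length(tc))
    ok <- alpha > -1
    out[ok] <- exp(-log(2) * (log1p(alpha[ok]) / g)^2)
    out
  }
  exp(-tc / truth$lifetime) * band
}

#' Generate a complete synthetic TCSPC dataset
#'
#' Builds, for every detection wavelength, the expected TCSPC histogram:
#' the ideal decay sampled from the noiseless TRES surface at that
#' wavelength's wavenumber, convolved with a Gaussian IRF, globally scaled so
#' the brightest channel of the brightest decay has expectation
#' `peak_counts`, then Poisson-sampled.  Each wavelength uses a deterministic
#' child stream of the root seed, so regeneration is bit-reproducible.  The
#' steady-state spectrum is the time integral of the noiseless surface,
#' mapped back to a per-wavelength intensity through the \eqn{\lambda^2}
#' Jacobian (switchable).
#'
#' @param truth a [ground_truth()] object
#' @param noise Poisson-sample the decays? (`FALSE` returns expectations)
#' @param convolve_irf convolve with the IRF? (`FALSE` gives the ideal,
#'   deconvolved decays, used for oracle checks)
#' @param noisy_irf Poisson-sample the IRF histogram as well?
#' @param jacobian apply the per-wavelength/per-wavenumber Jacobian when
#'   constructing the steady-state spectrum
#' @return object of class `"tdfs_dataset"`: list with `decays` (list of
#'   [decay_curve()]), `irf`, `steady_state` (data.frame wavelength/intensity),
#'   and `truth`
#' @export
generate_dataset <- function(truth, noise = TRUE, convolve_irf = TRUE,
                             noisy_irf = FALSE, jacobian = TRUE) {
  stopifnot(inherits(truth, "tdfs_truth"))
  dt <- truth$channel_width
  irf_e <- irf_expectation(truth)
  irf_n <- irf_e / sum(irf_e)
  n <- truth$n_channels

  ideal <- lapply(truth$wavelengths, function(wl) ideal_decay(truth, wl))
  model <- if (convolve_irf) {
    lapply(ideal, function(d) pmax(conv_open(irf_n, d), 0))
  } else ideal
  scale <- truth$peak_counts / max(vapply(model, max, numeric(1)))
  expect <- lapply(model, function(m) m * scale)

  decays <- vector("list", length(truth$wavelengths))
  for (k in seq_along(truth$wavelengths)) {
    e <- expect[[k]]
    counts <- if (noise) {
      set.seed(child_seed(truth$seed, k))
      stats::rpois(n, e)
    } else e
    decays[[k]] <- decay_curve(counts, channel_width = dt,
                               wavelength = truth$wavelengths[k])
  }
  names(decays) <- as.character(truth$wavelengths)

  irf_counts <- irf_e / max(irf_e) * truth$peak_counts
  if (noisy_irf) {
    set.seed(child_seed(truth$seed, 0L))
    irf_counts <- stats::rpois(n, irf_counts)
  }
  irf <- decay_curve(irf_counts, channel_width = dt, wavelength = NA_real_)

  tc <- (seq_len(n) - 0.5) * dt
  ss_int <- vapply(ideal, function(d) trapz_int(tc, d), numeric(1)) * scale
  if (jacobian) ss_int <- ss_int * 1e7 / truth$wavelengths^2
  steady_state <- data.frame(wavelength = truth$wavelengths,
                             intensity = ss_int)

  structure(list(decays = decays, irf = irf, steady_state = steady_state,
                 truth = truth, jacobian = jacobian,
                 noise = noise, convolved = convolve_irf),
            class = "tdfs_dataset")
}

#' @export
print.tdfs_dataset <- function(x, ...) {
  cat(sprintf("Synthetic TDFS dataset: %d decays (%s nm), %d channels x %g ns\n",
              length(x$decays),
              paste(range(x$truth$wavelengths), collapse = "-"),
              x$truth$n_channels, x$truth$channel_width))
  cat(sprintf("  %s, %s; seed %d\n",
              if (x$noise) "Poisson noise" else "noiseless",
              if (x$convolved) "IRF-convolved" else "unconvolved",
              x$truth$seed))
  invisible(x)
}

#' Generate a noisy 440/490 nm intensity pair with known GP
#'
#' Inverts the generalized-polarization definition: for a target GP and a
#' total expected count, the two band intensities have Poisson expectations
#' `total (1 + GP)/2` and `total (1 - GP)/2`.
#'
#' @param gp_true target generalized polarization in \[-1, 1\]
#' @param total total expected counts across both bands
#' @param seed integer seed
#' @param noise Poisson-sample? (`FALSE` returns the expectations)
#' @return named numeric vector `c(I440 = , I490 = )`
#' @export
generate_gp_pair <- function(gp_true, total, seed = 1L, noise = TRUE) {
  if (abs(gp_true) > 1) stop("gp_true must lie in [-1, 1]")
  stopifnot(total > 0)
  e440 <- total * (1 + gp_true) / 2
  e490 <- total * (1 - gp_true) / 2
  if (!noise) return(c(I440 = e440, I490 = e490))
  set.seed(as.integer(seed))
  c(I440 = stats::rpois(1, e440), I490 = stats::rpois(1, e490))
}
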