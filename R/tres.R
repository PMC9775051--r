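# Time-resolved emission spectra: reconstruction from fitted decays and the
# steady-state spectrum, per-slice log-normal fitting, and extraction of the
# time course of the emission maximum.

new_tres <- function(times, wavenumbers, surface, wavelengths = NULL,
                     fits = NULL) {
  stopifnot(!is.unsorted(times), !is.unsorted(wavenumbers),
            nrow(surface) == length(times),
            ncol(surface) == length(wavenumbers))
  structure(list(times = times, wavenumbers = wavenumbers, surface = surface,
                 wavelengths = wavelengths, fits = fits),
            class = "tres")
}

#' @export
print.tres <- function(x, ...) {
  cat(sprintf("TRES: %d times (%.4g-%.4g ns) x %d wavenumbers (%.0f-%.0f cm^-1)%s\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              if (is.null(x$fits)) "" else ", with per-slice log-normal fits"))
  invisible(x)
}

#' Default TRES time grid
#'
#' Log-spaced from a fraction of a TCSPC channel to several times the
#' slowest decay component, which brackets both the unrelaxed and the fully
#' relaxed spectrum.
#'
#' @param channel_width TCSPC channel width (ns)
#' @param max_lifetime slowest lifetime present (ns)
#' @param n number of grid points
#' @return sorted time vector (ns)
#' @export
tres_time_grid <- function(channel_width, max_lifetime, n = 100L) {
  exp(seq(log(0.1 * channel_width), log(5 * max_lifetime), length.out = n))
}

#' Reconstruct time-resolved emission spectra
#'
#' Combines per-wavelength decays with the steady-state spectrum:
#' \deqn{S(\lambda, t) = I_{ss}(\lambda)\, \frac{d_\lambda(t)}{\int_0^\infty d_\lambda(t)\,dt},}
#' where \eqn{d_\lambda} is the noiseless deconvolved decay, so that the time
#' integral of every reconstructed wavelength reproduces the steady-state
#' intensity by construction.  The wavelength axis is converted to
#' wavenumber (\eqn{\nu = 10^7/\lambda}); with `jacobian = TRUE` intensities
#' are converted from per-wavelength to per-wavenumber via the
#' \eqn{\lambda^2/10^7} factor (standard spectroscopic practice).
#'
#' `fits` may be a list of [fit_decay()] results (decays are represented
#' analytically, normalization \eqn{\sum_j \alpha_j\tau_j}) or a list of
#' noiseless [decay_curve()] objects (decays interpolated linearly,
#' normalization by trapezoid on their own grid) for oracle checks.
#'
#' @param fits list of `multiexp_fit` or `decay_curve` objects, each carrying
#'   its emission wavelength
#' @param steady_state data.frame with columns `wavelength` (nm) and
#'   `intensity`
#' @param time_grid positive times (ns); default [tres_time_grid()]
#' @param jacobian apply the per-wavelength to per-wavenumber Jacobian
#' @return a `"tres"` object (surface rows = times, columns = wavenumbers
#'   ascending)
#' @export
reconstruct_tres <- function(fits, steady_state, time_grid = NULL,
                             jacobian = TRUE) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(c("wavelength", "intensity") %in% names(steady_state)))
  wl <- vapply(fits, function(f) f$wavelength, numeric(1))
  if (anyNA(wl)) stop("every fit must carry its emission wavelength")
  if (any(wl < min(steady_state$wavelength) - 1e-9) ||
      any(wl > max(steady_state$wavelength) + 1e-9))
    stop("wavelength ", wl[which(wl < min(steady_state$wavelength) |
                                   wl > max(steady_state$wavelength))][1],
         " nm lies outside the steady-state spectrum support")
  if (is.null(time_grid)) {
    cw <- vapply(fits, function(f) f$channel_width, numeric(1))[1]
    window <- max(vapply(fits, function(f)
      length(f$counts) * f$channel_width, numeric(1)))
    # longest lifetime that carries weight (>1% of the integrated decay);
    # degenerate canceling pairs must not stretch the grid
    taumax <- max(unlist(lapply(fits, function(f) {
      if (!inherits(f, "multiexp_fit")) return(window / 10)
      contrib <- abs(f$amplitudes * f$lifetimes)
      f$lifetimes[contrib > 0.01 * sum(contrib)]
    })))
    time_grid <- tres_time_grid(cw, min(taumax, window / 5))
  }
  stopifnot(!is.unsorted(time_grid), all(time_grid > 0))

  iss <- stats::approx(steady_state$wavelength, steady_state$intensity,
                       xout = wl)$y

  dmat <- vapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    if (inherits(f, "multiexp_fit")) {
      d <- model_decay_noiseless(f, time_grid)
      norm <- sum(f$amplitudes * f$lifetimes)
    } else if (inherits(f, "decay_curve")) {
      tc <- decay_times(f)
      d <- stats::approx(tc, f$counts, xout = time_grid, rule = 2)$y
      norm <- trapz_int(tc, f$counts)
    } else stop("fits must be multiexp_fit or decay_curve objects")
    if (norm <= 0)
      stop("non-positive decay integral at wavelength ", wl[k], " nm")
    iss[k] * d / norm
  }, numeric(length(time_grid)))

  nu <- unname(nm_to_wavenumber(wl))
  if (jacobian) dmat <- sweep(dmat, 2L, wl^2 / 1e7, `*`)
  ord <- order(nu)
  # a multi-exponential representation of a rising (red-edge) decay can dip
  # below zero near t = 0; clip to keep the surface physical
  new_tres(times = time_grid, wavenumbers = nu[ord],
           surface = pmax(dmat[, ord, drop = FALSE], 0),
           wavelengths = unname(wl[ord]))
}

#' Time course of the TRES maxima
#'
#' Fits every time slice of a TRES with the asymmetric log-normal lineshape
#' and reports the fitted peak position \eqn{\nu(t)} with its standard
#' error.  The discrete argmax of each slice is carried along as a
#' grid-quantized cross-check.
#'
#' @param tres a [reconstruct_tres()] or [generate_tres_surface()] result
#' @return object of class `"solvation_response"`: data.frame with columns
#'   `time`, `nu`, `nu_se`, `argmax`, `flagged`, holding the slice fits as an
#'   attribute
#' @export
tres_maxima <- function(tres) {
  stopifnot(inherits(tres, "tres"))
  fits <- lapply(seq_along(tres$times), function(i)
    fit_lognormal(tres$wavenumbers, tres$surface[i, ]))
  out <- data.frame(
    time = tres$times,
    nu = vapply(fits, `[[`, numeric(1), "nu_p"),
    nu_se = vapply(fits, `[[`, numeric(1), "nu_p_se"),
    argmax = tres$wavenumbers[apply(tres$surface, 1L, which.max)],
    flagged = vapply(fits, `[[`, logical(1), "flagged")
  )
  attr(out, "fits") <- fits
  class(out) <- c("solvation_response", "data.frame")
  out
}

#' @export
print.solvation_response <- function(x, ...) {
  cat(sprintf("Solvation response nu(t): %d points, %.4g-%.4g ns, %.0f -> %.0f cm^-1\n",
              nrow(x), min(x$time), max(x$time), x$nu[1], x$nu[nrow(x)]))
  if (any(x$flagged))
    cat(sprintf("  %d slice(s) flagged (edge peak)\n", sum(x$flagged)))
  invisible(x)
}

#' @export
plot.tres <- function(x, times = NULL, ...) {
  idx <- if (is.null(times)) unique(round(seq(1, length(x$times), length.out = 6)))
  else vapply(times, function(t) which.min(abs(x$times - t)), integer(1))
  cols <- grDevices::hcl.colors(length(idx), "viridis")
  graphics::matplot(x$wavenumbers, t(x$surface[idx, , drop = FALSE]),
                    type = "l", lty = 1, col = cols,
                    xlab = expression(tilde(nu) ~ (cm^-1)),
                    ylab = "intensity", ...)
  graphics::legend("topleft", legend = sprintf("%.3g ns", x$times[idx]),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
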