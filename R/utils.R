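# Internal helpers shared across modules.

#' Convert wavelength (nm) to wavenumber (cm^-1) and back
#'
#' The two units are related by \eqn{\nu = 10^7/\lambda} with \eqn{\lambda}
#' in nm and \eqn{\nu} in cm\eqn{^{-1}}; the transform is its own inverse.
#'
#' @param wavelength wavelengths in nm
#' @param wavenumber wavenumbers in cm^-1
#' @return numeric vector in the other unit
#' @export
nm_to_wavenumber <- function(wavelength) {
  stopifnot(all(wavelength > 0))
  1e7 / wavelength
}

#' @rdname nm_to_wavenumber
#' @export
wavenumber_to_nm <- function(wavenumber) {
  stopifnot(all(wavenumber > 0))
  1e7 / wavenumber
}

# trapezoidal integral on an arbitrary grid
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Deterministic child seed for stream `k` derived from a root seed.
# Derivation: (root * 2654435761 + k) mod (2^31 - 1), the Knuth
# multiplicative hash reduced into the valid set.seed range.
child_seed <- function(root, k) {
  as.integer((as.numeric(root) %% 65536 * 2654435761 + k) %% (2^31 - 1))
}

# Gauss FWHM <-> sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Covariance of least-squares parameters from a residual function.
# resid_fn returns weighted residuals (r_i * sqrt(w_i)); covariance is
# (J'J)^-1 for chi-square weights (absolute Poisson errors).
ls_covariance <- function(resid_fn, par, rel_step = 1e-5) {
  r0 <- resid_fn(par)
  p <- length(par)
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    h <- rel_step * max(abs(par[j]), 1e-8)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(cov)) {
    warning("singular covariance; omitted")
    return(NULL)
  }
  dimnames(cov) <- list(names(par), names(par))
  cov
}

`%||%` <- function(a, b) if (is.null(a)) b else a
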