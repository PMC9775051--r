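#' Asymmetric log-normal lineshape
#'
#' Evaluates the Siano-Metzler asymmetric log-normal band shape that is the
#' standard model for broad solvatochromic emission bands,
#' \deqn{I(\nu) = h \exp\left[-\ln 2 \left(\frac{\ln(1+\alpha)}{\gamma}\right)^2\right],
#'   \qquad \alpha = \frac{2\gamma(\nu - \nu_p)}{\Delta},}
#' which is zero wherever \eqn{\alpha \le -1}.  In the symmetric limit
#' \eqn{\gamma \to 0} it reduces to a Gaussian of FWHM \eqn{\Delta}.
#' The FWHM of the general shape is \eqn{\Delta \sinh(\gamma)/\gamma}.
#'
#' @param nu wavenumbers (cm^-1) at which to evaluate
#' @param h peak height (arbitrary intensity units)
#' @param nu_p peak position (cm^-1)
#' @param delta width parameter (cm^-1), equal to the FWHM when `gamma = 0`
#' @param gamma asymmetry (dimensionless); negative values put the long tail
#'   on the low-wavenumber (red) side, typical of emission spectra
#' @return intensity at each `nu`
#' @examples
#' nu <- seq(18000, 26000, by = 50)
#' plot(nu, lognormal_eval(nu, 1, 22000, 3000, -0.3), type = "l")
#' @export
lognormal_eval <- function(nu, h, nu_p, delta, gamma) {
  stopifnot(h > 0, delta > 0)
  if (gamma == 0) {
    return(h * exp(-log(2) * (2 * (nu - nu_p) / delta)^2))
  }
  alpha <- 2 * gamma * (nu - nu_p) / delta
  out <- numeric(length(nu))
  ok <- alpha > -1
  out[ok] <- h * exp(-log(2) * (log1p(alpha[ok]) / gamma)^2)
  out
}

# FWHM of the asymmetric log-normal
lognormal_fwhm <- function(delta, gamma) {
  if (gamma == 0) return(delta)
  delta * sinh(gamma) / gamma
}

#' Fit a log-normal lineshape to one spectral slice
#'
#' Least-squares fit of [lognormal_eval()] to intensities on a wavenumber
#' grid, with a deterministic initialization from the empirical peak, the
#' interpolated half-maximum crossings and their asymmetry: for this shape
#' the ratio of the red/blue half-widths at half maximum equals
#' \eqn{e^{\gamma}}, which gives the starting asymmetry directly.
#'
#' @param nu wavenumber grid (cm^-1), any order
#' @param intensity intensities at `nu`
#' @param weights optional fitting weights (1/sigma^2); default uniform
#' @return object of class `"lognormal_fit"`: list with `h`, `nu_p`, `delta`,
#'   `gamma`, `nu_p_se` (standard error of the peak position), `covariance`,
#'   `flagged` (TRUE when the empirical maximum sits on the grid edge, so
#'   `nu_p` is an extrapolation), `fitted`, `rss`.
#' @export
fit_lognormal <- function(nu, intensity, weights = NULL) {
  stopifnot(length(nu) == length(intensity))
  if (length(nu) < 5L) stop("need at least 5 points to fit a log-normal")
  ord <- order(nu)
  nu <- unname(nu[ord]); y <- unname(intensity[ord])
  w <- if (is.null(weights)) rep(1, length(y)) else weights[ord]
  imax <- which.max(y)
  if (imax == 1L || imax == length(y)) {
    flagged <- TRUE
  } else flagged <- FALSE
  if (!flagged && (imax < 2L || imax > length(y) - 1L))
    stop("need at least one point on each side of the maximum")

  init <- lognormal_init(nu, y, imax)
  par <- c(h = init$h, nu_p = init$nu_p, delta = init$delta, gamma = init$gamma)
  resid_fn <- function(p) {
    d <- max(p[["delta"]], 1e-6)
    (lognormal_eval(nu, max(p[["h"]], 1e-12), p[["nu_p"]], d, p[["gamma"]]) - y) *
      sqrt(w)
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  fit <- minpack.lm::nls.lm(
    par, fn = resid_fn,
    lower = c(0, min(nu) - 3 * init$delta, 1e-3, -3),
    upper = c(Inf, max(nu) + 3 * init$delta, Inf, 3),
    control = ctl)
  p <- fit$par
  cov <- ls_covariance(resid_fn, unlist(p))
  n <- length(y); npar <- 4L
  rss <- sum(fit$fvec^2)
  # absolute parameter errors: scale (J'J)^-1 by residual variance when
  # weights are relative (the common case for reconstructed TRES slices)
  nu_p_se <- if (!is.null(cov)) {
    s2 <- rss / max(n - npar, 1L)
    sqrt(pmax(cov["nu_p", "nu_p"] * s2, 0))
  } else NA_real_
  structure(list(
    h = p[["h"]], nu_p = p[["nu_p"]], delta = p[["delta"]], gamma = p[["gamma"]],
    nu_p_se = nu_p_se, covariance = cov, flagged = flagged,
    fitted = lognormal_eval(nu, p[["h"]], p[["nu_p"]], p[["delta"]], p[["gamma"]]),
    nu = nu, rss = rss, converged = fit$info %in% 1:4
  ), class = "lognormal_fit")
}

# Deterministic starting values from the empirical peak and half-max crossings.
lognormal_init <- function(nu, y, imax) {
  h0 <- y[imax]; nup0 <- nu[imax]
  half <- h0 / 2
  # interpolated half-maximum crossings on each side (fall back to the span)
  left <- right <- NA_real_
  if (imax > 1L) {
    below <- which(y[seq_len(imax - 1L)] < half)
    if (length(below)) {
      i <- max(below)
      left <- nu[i] + (half - y[i]) / (y[i + 1L] - y[i]) * (nu[i + 1L] - nu[i])
    }
  }
  if (imax < length(y)) {
    below <- which(y[(imax + 1L):length(y)] < half)
    if (length(below)) {
      i <- imax + min(below)
      right <- nu[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (nu[i] - nu[i - 1L])
    }
  }
  wl <- if (is.finite(left)) nup0 - left else (nup0 - min(nu)) / 2
  wr <- if (is.finite(right)) right - nup0 else (max(nu) - nup0) / 2
  wl <- max(wl, 1e-3); wr <- max(wr, 1e-3)
  gamma0 <- log(wr / wl)
  gamma0 <- max(min(gamma0, 2), -2)
  fwhm0 <- wl + wr
  delta0 <- if (abs(gamma0) < 1e-6) fwhm0 else fwhm0 * gamma0 / sinh(gamma0)
  list(h = h0, nu_p = nup0, delta = delta0, gamma = gamma0)
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("Log-normal lineshape fit\n")
  cat(sprintf("  peak   nu_p  = %.1f cm^-1 (se %.2f)%s\n", x$nu_p,
              x$nu_p_se, if (x$flagged) "  [edge peak: extrapolated]" else ""))
  cat(sprintf("  height h     = %.4g\n", x$h))
  cat(sprintf("  width  delta = %.1f cm^-1 (FWHM %.1f)\n", x$delta,
              lognormal_fwhm(x$delta, x$gamma)))
  cat(sprintf("  asym   gamma = %.3f\n", x$gamma))
  invisible(x)
}

#' @export
coef.lognormal_fit <- function(object, ...) {
  c(h = object$h, nu_p = object$nu_p, delta = object$delta, gamma = object$gamma)
}
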