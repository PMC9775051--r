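# TCSPC decay container and multi-exponential reconvolution fitting.

#' TCSPC decay histogram
#'
#' @param counts per-channel photon counts (non-negative)
#' @param channel_width channel width (ns)
#' @param wavelength emission wavelength (nm); `NA` for an IRF
#' @param t0_channel optional alignment reference channel
#' @return object of class `"decay_curve"`
#' @export
decay_curve <- function(counts, channel_width, wavelength = NA_real_,
                        t0_channel = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty decay curve")
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(channel_width > 0)
  structure(list(counts = counts, channel_width = channel_width,
                 wavelength = wavelength,
                 t0_channel = t0_channel %||% which.max(counts)),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("TCSPC decay%s: %d channels x %g ns, %.4g total counts\n",
              if (is.na(x$wavelength)) " (IRF)" else
                sprintf(" at %g nm", x$wavelength),
              length(x$counts), x$channel_width, sum(x$counts)))
  invisible(x)
}

# channel center times (ns), zero-based window
decay_times <- function(decay) {
  (seq_along(decay$counts) - 0.5) * decay$channel_width
}

#' Estimate the FWHM of a measured IRF histogram
#'
#' Interpolated half-maximum crossing width, in ns.
#'
#' @param irf a [decay_curve()]
#' @return FWHM in ns
#' @export
irf_fwhm_estimate <- function(irf) {
  stopifnot(inherits(irf, "decay_curve"))
  y <- irf$counts
  tc <- decay_times(irf)
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- right <- NA_real_
  if (imax > 1L) {
    i <- max(which(y[seq_len(imax - 1L)] < half))
    left <- tc[i] + (half - y[i]) / (y[i + 1L] - y[i]) * (tc[i + 1L] - tc[i])
  }
  if (imax < length(y)) {
    i <- imax + min(which(y[(imax + 1L):length(y)] < half))
    right <- tc[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) *
      (tc[i] - tc[i - 1L])
  }
  if (!is.finite(left) || !is.finite(right))
    stop("cannot locate IRF half-maximum crossings")
  right - left
}

# linear ("open") convolution truncated to the data length; FFT with
# power-of-two padding (mixed-radix FFTs degrade badly at awkward lengths)
conv_open <- function(irf, d) {
  n <- length(d)
  m <- 2^ceiling(log2(2 * n))
  Re(stats::fft(stats::fft(c(irf, numeric(m - length(irf)))) *
                  stats::fft(c(d, numeric(m - n))), inverse = TRUE))[seq_len(n)] / m
}

# IRF shifted by a fractional number of channels via linear interpolation
shift_irf <- function(irf, shift_channels) {
  if (shift_channels == 0) return(irf)
  idx <- seq_along(irf)
  out <- stats::approx(idx, irf, xout = idx - shift_channels,
                       yleft = 0, yright = 0)$y
  out
}

#' Reconvolved multi-exponential model decay
#'
#' Discrete convolution of the (area-normalized, sub-channel-shiftable) IRF
#' with \eqn{\sum_j \alpha_j e^{-t/\tau_j}} plus a constant baseline.  The
#' sub-channel shift is applied by linear interpolation of the IRF; the
#' model is causal apart from that interpolation support.
#'
#' @param irf a [decay_curve()] holding the instrument response
#' @param amplitudes amplitudes \eqn{\alpha_j} (counts scale; may be negative)
#' @param lifetimes lifetimes \eqn{\tau_j} (ns, positive)
#' @param shift IRF-decay offset (ns), positive delays the IRF
#' @param baseline constant background (counts per channel)
#' @param n_channels length of the output grid; defaults to the IRF length
#' @return numeric vector of model counts per channel
#' @export
convolve_model <- function(irf, amplitudes, lifetimes, shift = 0,
                           baseline = 0, n_channels = NULL) {
  stopifnot(inherits(irf, "decay_curve"), all(lifetimes > 0),
            length(amplitudes) == length(lifetimes))
  n <- n_channels %||% length(irf$counts)
  if (n != length(irf$counts))
    stop("IRF and decay channel grids differ (", length(irf$counts),
         " vs ", n, " channels)")
  dt <- irf$channel_width
  irf_n <- shift_irf(irf$counts / sum(irf$counts), shift / dt)
  tc <- (seq_len(n) - 0.5) * dt
  d <- colSums(amplitudes * exp(-outer(1 / lifetimes, tc)))
  conv_open(irf_n, d) + baseline
}

#' Fit a TCSPC decay by iterative reconvolution
#'
#' Minimizes the Pearson chi-square
#' \eqn{\chi^2 = \sum_i (y_i - m_i)^2 / \max(y_i, 1)}
#' over a multi-exponential reconvolution model (see [convolve_model()]).
#' Lifetimes and the IRF shift are optimized by Levenberg-Marquardt on a
#' variable-projection residual: at each step the amplitudes and baseline
#' are solved linearly.  Initialization is deterministic: a log-spaced
#' lifetime ladder spanning 0.1-10 times the background-corrected mean decay
#' time, amplitudes from non-negative least squares at those lifetimes.
#' Channels before the IRF onset (first channel above 1% of the IRF maximum)
#' are excluded from the fit.
#'
#' @param decay,irf [decay_curve()] objects on the same channel grid
#' @param n_components number of exponentials (1-4)
#' @param nonneg constrain amplitudes to be non-negative?  Default `FALSE`:
#'   negative pre-exponentials are physical at red emission wavelengths,
#'   where the relaxed state rises in
#' @param fit_shift,fit_baseline free the sub-channel IRF shift / baseline?
#' @param max_iter maximum Levenberg-Marquardt iterations
#' @return object of class `"multiexp_fit"`: `amplitudes`, `lifetimes`
#'   (ascending), `shift` (ns), `baseline`, `chi2_reduced`, `covariance`
#'   (over free parameters, `NULL` when singular), `converged`, `fitted`,
#'   `included` (channel mask), plus grid metadata
#' @export
fit_decay <- function(decay, irf, n_components = 3L, nonneg = FALSE,
                      fit_shift = TRUE, fit_baseline = TRUE,
                      max_iter = 100L) {
  stopifnot(inherits(decay, "decay_curve"), inherits(irf, "decay_curve"))
  if (length(decay$counts) != length(irf$counts) ||
      abs(decay$channel_width - irf$channel_width) > 1e-12)
    stop("decay and IRF must share the channel grid")
  if (n_components < 1L || n_components > 4L)
    stop("n_components must be between 1 and 4")
  y <- decay$counts
  if (sum(y) < 1000)
    warning("total counts < 1000: fit will be poorly determined")
  n <- length(y)
  dt <- decay$channel_width
  tc <- decay_times(decay)
  irf_n0 <- irf$counts / sum(irf$counts)
  onset <- which(irf$counts >= 0.01 * max(irf$counts))[1]
  include <- seq_len(n) >= onset
  w <- 1 / pmax(y, 1)
  sw <- sqrt(w[include])

  # --- deterministic initialization ---------------------------------------
  t_irf <- sum(irf$counts * tc) / sum(irf$counts)
  tbar <- max(sum(y * tc) / sum(y) - t_irf, 3 * dt)
  tau0 <- if (n_components == 1L) tbar else
    exp(seq(log(0.1 * tbar), log(10 * tbar), length.out = n_components))

  basis <- function(tau, shift) {
    irf_s <- shift_irf(irf_n0, shift / dt)
    B <- vapply(tau, function(tj) conv_open(irf_s, exp(-tc / tj)), numeric(n))
    if (fit_baseline) cbind(B, baseline = 1) else B
  }
  solve_linear <- function(tau, shift) {
    B <- basis(tau, shift)
    Bi <- B[include, , drop = FALSE] * sw
    yi <- y[include] * sw
    coefs <- tryCatch(qr.coef(qr(Bi), yi), error = function(e) NULL)
    if (is.null(coefs) || anyNA(coefs))
      coefs <- rep(0, ncol(B))
    if (nonneg) {
      nn <- pracma::lsqnonneg(Bi, yi)$x
      coefs <- nn
    }
    list(coefs = coefs, model = drop(B %*% coefs))
  }
  # amplitude init by NNLS at the ladder lifetimes (reported init scheme)
  init_amps <- pracma::lsqnonneg(basis(tau0, 0)[include, , drop = FALSE] * sw,
                                 y[include] * sw)$x

  theta0 <- c(log(tau0), if (fit_shift) 0)
  resid_fn <- function(theta) {
    tau <- exp(theta[seq_len(n_components)])
    shift <- if (fit_shift) theta[n_components + 1L] else 0
    sol <- solve_linear(tau, shift)
    (sol$model[include] - y[include]) * sw
  }
  lo <- c(rep(log(dt / 10), n_components), if (fit_shift) -20 * dt)
  hi <- c(rep(log(2 * n * dt), n_components), if (fit_shift) 20 * dt)
  ctl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-10,
                                    ptol = 1e-10)
  fit <- minpack.lm::nls.lm(theta0, fn = resid_fn, lower = lo, upper = hi,
                            control = ctl)
  converged <- fit$info %in% 1:4
  theta <- fit$par
  tau <- exp(theta[seq_len(n_components)])
  shift <- if (fit_shift) theta[n_components + 1L] else 0
  sol <- solve_linear(tau, shift)
  k <- n_components
  amps <- unname(sol$coefs[seq_len(k)])
  baseline <- if (fit_baseline) unname(sol$coefs[k + 1L]) else 0

  ord <- order(tau)
  tau <- tau[ord]; amps <- amps[ord]

  p_free <- k + k + as.integer(fit_shift) + as.integer(fit_baseline)
  chi2_red <- sum(((sol$model - y)^2 * w)[include]) / (sum(include) - p_free)

  # covariance over the physical free parameters
  par_full <- c(stats::setNames(amps, paste0("alpha", seq_len(k))),
                stats::setNames(log(tau), paste0("log_tau", seq_len(k))),
                if (fit_shift) c(shift = shift),
                if (fit_baseline) c(baseline = baseline))
  full_resid <- function(p) {
    a <- p[seq_len(k)]
    tt <- exp(p[k + seq_len(k)])
    sh <- if (fit_shift) p[["shift"]] else 0
    bl <- if (fit_baseline) p[["baseline"]] else 0
    m <- convolve_model(irf, a, tt, shift = sh, baseline = bl)
    (m[include] - y[include]) * sw
  }
  cov <- suppressWarnings(ls_covariance(full_resid, par_full))

  structure(list(
    amplitudes = amps, lifetimes = tau, shift = shift, baseline = baseline,
    chi2_reduced = chi2_red, covariance = cov, converged = converged,
    n_components = k, fitted = sol$model, included = include,
    counts = y, channel_width = dt, wavelength = decay$wavelength,
    init = list(tau = tau0, amplitudes = init_amps),
    message = fit$message
  ), class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("Multi-exponential reconvolution fit (%d components%s)\n",
              x$n_components,
              if (!x$converged) ", NOT CONVERGED" else ""))
  tab <- data.frame(alpha = x$amplitudes, tau_ns = x$lifetimes,
                    f = x$amplitudes * x$lifetimes /
                      sum(abs(x$amplitudes * x$lifetimes)))
  print(format(tab, digits = 4), row.names = FALSE)
  cat(sprintf("  shift %.4f ns, baseline %.3f, chi2_red = %.3f\n",
              x$shift, x$baseline, x$chi2_reduced))
  invisible(x)
}

#' @export
coef.multiexp_fit <- function(object, ...) {
  k <- object$n_components
  c(stats::setNames(object$amplitudes, paste0("alpha", seq_len(k))),
    stats::setNames(object$lifetimes, paste0("tau", seq_len(k))),
    shift = object$shift, baseline = object$baseline)
}

#' @export
residuals.multiexp_fit <- function(object, ...) {
  r <- (object$counts - object$fitted) / sqrt(pmax(object$counts, 1))
  r[!object$included] <- NA_real_
  r
}

#' Noiseless deconvolved model decay
#'
#' Evaluates the IRF-free analytic decay \eqn{\sum_j \alpha_j e^{-t/\tau_j}}
#' of a fitted model on an arbitrary time grid; this deconvolved
#' representation is what TRES reconstruction consumes.
#'
#' @param fit a [fit_decay()] result
#' @param time_grid times (ns)
#' @return intensity at each grid time
#' @export
model_decay_noiseless <- function(fit, time_grid) {
  stopifnot(inherits(fit, "multiexp_fit"))
  colSums(fit$amplitudes * exp(-outer(1 / fit$lifetimes, time_grid)))
}
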