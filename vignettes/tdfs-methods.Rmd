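---
title: "TDFS analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TDFS analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfs)
```

## The measurement and its model

A solvatochromic probe (Laurdan at the sn-1 carbonyl level of a bilayer,
in the use case this package was built around) is excited by a short
laser pulse. Its emission band then shifts to the red as the local
environment — hydration water and lipid headgroups — relaxes around the
excited-state dipole. Two numbers summarize the process: the overall
dynamic Stokes shift $\Delta\nu = \nu(0) - \nu(\infty)$ (how polar /
hydrated the environment is) and the integral relaxation time

$$\tau_r = \int_0^\infty \frac{\nu(t) - \nu(\infty)}{\Delta\nu}\,dt$$

(how mobile it is), where $\nu(t)$ is the emission-maximum position in
cm$^{-1}$.

The raw data are TCSPC histograms $y_\lambda(k)$ at emission wavelengths
$\lambda$ (the experimental arrangement sampled here: 400–540 nm in
10 nm steps), plus the instrument response function (IRF) and the
steady-state emission spectrum $I_{ss}(\lambda)$. The analysis chain:

1. Each decay is modeled as the IRF convolved with
   $\sum_j \alpha_j e^{-t/\tau_j}$ plus a baseline, minimizing the
   Pearson $\chi^2$ with weights $1/\max(y,1)$ (`fit_decay()`).
   Negative pre-exponentials are allowed by default: at red wavelengths
   the relaxed state *rises* in.
2. Time-resolved emission spectra (TRES) are reconstructed as
   $S(\lambda, t) = I_{ss}(\lambda)\, d_\lambda(t) / \int_0^\infty
   d_\lambda$, with $d_\lambda$ the deconvolved fitted decay
   (`reconstruct_tres()`). By construction the time integral returns the
   steady-state spectrum. The wavelength axis is converted to wavenumber
   with the $\lambda^2/10^7$ Jacobian applied to intensities (standard
   spectroscopic practice; a flag disables it).
3. Each time slice is fitted with the Siano–Metzler asymmetric
   log-normal, $h\exp[-\ln 2\,(\ln(1+\alpha)/\gamma)^2]$,
   $\alpha = 2\gamma(\nu - \nu_p)/\Delta$ — the standard band shape for
   broad emission spectra — and $\nu(t)$ is the fitted peak $\nu_p$, not
   the grid-quantized argmax (`tres_maxima()`; the argmax is carried as a
   cross-check).
4. $\nu(t)$ is fitted with an offset plus 1–3 exponentials;
   $\nu(\infty)$ is the offset, $\nu(0)$ the extrapolation to $t = 0$,
   and $\tau_r = \sum_i a_i \tau_i$ with normalized amplitudes
   (`extrapolate_nu_inf()`, `relaxation_time()`). The numeric
   cross-check (trapezoidal integral of the observed correlation decay
   plus analytic head and tail) is always reported alongside.

## Key parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `n_components` (decay fit) | 4 in `tdfs()`, 3 in `fit_decay()` | exponentials per decay |
| `t_min` | one IRF FWHM | start of the $\nu(t)$ analysis window (ns) |
| `min_intensity` | 0.005 | relative slice-intensity cutoff |
| `max_nu_components` | 3 | exponentials in the $\nu(t)$ fit |
| TRES grid | 100 points, log-spaced | $0.1\times$ channel width to $5\times$ slowest informative lifetime |
| lineshape | $\gamma$ free, $\Delta$ free | per-slice log-normal |

Three defaults deserve their rationale, because they came out of
systematic calibration against the synthetic generator (where the truth
is known):

**Four exponentials per decay in the pipeline.** Three is the customary
choice for Laurdan lifetime work, and `fit_decay()` keeps that default
for standalone use. TRES reconstruction, however, *differentiates* the
fitted decays in time: at each wavelength the true kinetics is a
continuum of rates (the band sweeps past the detection wavelength), and
a 3-exponential representation leaves a reproducible wiggle in
$\nu(t)$ around 0.1–3 ns that a 4-exponential fit reduces below the
photon noise. With three components the wiggle is large enough that the
parsimony-penalized model selection in step 4 starts fitting it.

**A global detector shift, estimated in two passes.** The sub-channel
IRF–decay offset is an instrument property, not a per-wavelength one. A
first pass fits every decay with a free shift; the median is then fixed
for the definitive fits. Leaving 15 independent shift parameters free
leaks correlated timing noise into the early-time TRES slices and biases
$\tau_r$ upward by several percent at the study conditions.

**The analysis window.** Below roughly one IRF width reconvolution
carries no information about the deconvolved decay, so the earliest TRES
slices are model extrapolation; likewise slices whose total intensity
has fallen below 0.5% of the maximum are extrapolations of tail fits.
Both are excluded from the $\nu(t)$ fit, and the fit weights slices by
their relative photon content. Lifetimes in the $\nu(t)$ fit are
restricted to [window start, window length/3]: slower components are
degenerate with the offset (they would masquerade as a shifted
$\nu(\infty)$), faster ones are unconstrained.

**$\nu(0)$.** The default is the $\nu(t)$ fit extrapolated to $t = 0$
(`nu0 = "fit"`), which is consistent and unbiased when nothing relaxes
faster than the IRF. When ultrafast relaxation is suspected, a
spectra-based estimate from the reference-solvent construction
(`estimate_time_zero()`: polar absorption minus the reference
absorption–emission gap) can be supplied; the package then reports the
"total" shift from the estimate while $\tau_r$ keeps integrating the
observed series, and the observed shift is reported separately — no
hidden choice between the two.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws, per wavelength, Poisson counts around the
IRF-convolved sample of a log-normal band whose peak relaxes as
$\nu(t) = \nu_\infty + \Delta\nu \sum a_i e^{-t/\tau_i}$, multiplied by
a single-exponential population decay. The defaults emulate the study
conditions used throughout the tests: $\Delta\nu = 3000$ cm$^{-1}$,
$\tau_r = 1.5$ ns (equal amplitudes at 0.5 and 2.5 ns), 4 ns lifetime,
band width 3000 cm$^{-1}$ with asymmetry $-0.3$, Gaussian IRF of 0.1 ns
FWHM, 4096 channels of 10 ps, peak 10⁴ counts, 15 wavelengths (400–540
nm). Peak counts per decay are not dictated by any published protocol;
10⁴ is a realistic overnight TCSPC acquisition. One root seed drives
per-wavelength child streams (a multiplicative-hash derivation), so
datasets are bit-reproducible.

Real data differ in ways the generator deliberately omits: no detector
afterpulsing, pile-up, dark counts or wavelength-dependent IRF; a single
population lifetime rather than wavelength-dependent intensity decays;
and a band shape held constant in time (a config flag allows a linear
width drift for robustness checks). Passing the end-to-end tests
therefore demonstrates the correctness and internal consistency of the
estimator chain — not immunity to instrument artifacts.

## Numerical choices

- Decay fitting uses variable projection: amplitudes and baseline solved
  linearly at each Levenberg–Marquardt step over (log-)lifetimes and
  shift. Initialization is deterministic — a log-spaced lifetime ladder
  spanning $0.1\times$–$10\times$ the background-corrected mean decay
  time, amplitudes by non-negative least squares — so fits are exactly
  reproducible. Channels before the IRF onset (1% of its maximum) are
  excluded.
- Convolutions run over power-of-two FFTs (mixed-radix FFTs degrade
  badly at awkward lengths).
- The log-normal fitter initializes from the empirical peak and the
  interpolated half-maximum crossings; for this band shape the ratio of
  the red/blue half-widths equals $e^\gamma$, giving the starting
  asymmetry in closed form. Slices whose empirical maximum sits on the
  grid edge are flagged and excluded from the $\nu(t)$ fit.
- $\nu(t)$ model selection (1–3 components) uses an AIC-type penalty on
  the weighted $\chi^2$; amplitudes are constrained non-negative
  (red-shifting response) by alternating an exact offset update with
  non-negative least squares, and numerically dead components are
  pruned.
- Degenerate inputs: a non-decreasing $\nu(t)$ series raises an error
  (nothing to extrapolate); incomplete relaxation (more than 2% of the
  fitted shift remaining at the window end) raises a flag; a
  non-positive Stokes shift is flagged, not silently returned.

## MD post-processing

Frames are centered by the circular mean of the reference group's
(by convention the phosphates') z coordinates over the periodic box, so
a membrane wrapped across the boundary centers identically to its
unwrapped copy. Number densities (nm$^{-3}$) come from per-frame
histograms normalized by the instantaneous bin volume, averaged over
frames, and symmetrized as $[\rho(z) + \rho(-z)]/2$ on bins mirrored
about the membrane center; the operation is idempotent and conserves
the per-group particle count exactly. Peak positions are refined sub-bin
by a parabola through the three bins around the maximum. Area per lipid
is $L_x L_y / n_{leaflet}$ per frame with a block-averaged standard
error (5 blocks by default) because frames are serially correlated.
Trajectory I/O uses multi-frame GRO text; running the simulations
themselves (force field, thermostats, etc.) is out of scope.

## Problem sizes used in the shipped tests

Unit tests run a reduced experiment (1024 channels of 20 ps, peak
5 × 10³ counts) so the whole suite stays fast; the end-to-end recovery
test and the acceptance script use the full study conditions above with
10 seeded replicates and assert median recovery of $\Delta\nu$ within 3%
and $\tau_r$ within 5% — the tolerances the estimator was designed to
meet at those conditions.

## Known limitations

- The per-slice peak uncertainties from the log-normal fits reflect
  slice-internal residuals, not the wavelength-correlated error of the
  reconstruction; the $\nu(t)$ fit therefore weights by photon content
  instead. The parametric bootstrap (`tdfs_uncertainty()`, 200 resamples
  by default) propagates decay-fit covariances and is the better
  uncertainty statement for $\Delta\nu$ and $\tau_r$.
- Multi-exponential decompositions of $\nu(t)$ are ill-posed; individual
  $(a_i, \tau_i)$ pairs should not be over-interpreted. $\Delta\nu$ and
  $\tau_r$ are the stable quantities, which is why the numeric-integral
  cross-check of $\tau_r$ is always reported.
- Relaxation faster than the IRF is invisible to the `"fit"` time-zero
  mode; use the spectra-based estimate when that matters.
- GP band integration defaults to ±5 nm around 440/490 nm; monochromator
  bandpasses differ between instruments, so compare GP values only
  within one convention.
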