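# tdfs — time-dependent fluorescence shift analysis of lipid membranes

`tdfs` analyses time-dependent fluorescence shift (TDFS) experiments on
solvatochromic membrane probes such as Laurdan, whose emission band
relaxes to the red as the hydrated lipid carbonyl environment reorganizes
around the excited fluorophore. The package takes raw time-correlated
single-photon counting (TCSPC) histograms and turns them into the two
headline observables of the method:

- the **overall dynamic Stokes shift** Δν = ν(0) − ν(∞), a measure of
  polarity/hydration at the probe's location, and
- the **integral relaxation time**

  τ_r = ∫₀^∞ [ν(t) − ν(∞)] / Δν dt,

  a measure of local mobility (larger τ_r = more rigid environment),

where ν(t) is the time course of the emission maximum (cm⁻¹). The chain
is the standard one in the solvation-dynamics literature:

1. **Reconvolution fitting** — each per-wavelength decay is fitted with a
   multi-exponential model convolved with the measured instrument response
   function (`fit_decay()`), minimizing a Pearson χ² with Poisson weights.
2. **TRES reconstruction** — the deconvolved decays are normalized to the
   steady-state emission spectrum, S(λ,t) = I_ss(λ) d_λ(t)/∫d_λ,
   giving time-resolved emission spectra on a wavenumber axis
   (`reconstruct_tres()`).
3. **Log-normal maxima** — every time slice is fitted with the asymmetric
   log-normal band shape to locate ν(t) (`fit_lognormal()`,
   `tres_maxima()`).
4. **Metrics** — ν(t) is fitted with an offset plus 1–3 exponentials;
   ν(∞) is the offset, ν(0) the extrapolation to t = 0 (or a supplied
   estimate, see `estimate_time_zero()`), and τ_r = Σ aᵢτᵢ
   (`extrapolate_nu_inf()`, `overall_shift()`, `relaxation_time()`).

Two companion modules cover the rest of a typical membrane-biophysics
study: Laurdan **generalized polarization**, GP = (I₄₄₀ − I₄₉₀)/(I₄₄₀ +
I₄₉₀) (`compute_gp()`, `gp_from_spectrum()`, `gp_table()`), and
**MD post-processing** of bilayer trajectories into membrane-centered,
symmetrized number-density profiles, ion peak statistics and
area-per-lipid series (`density_profile()`, `peak_stats()`,
`area_per_lipid()`).

Everything is testable without instrument data: `ground_truth()` +
`generate_dataset()` synthesize complete TCSPC datasets (log-normal band
with a multi-exponential peak shift, population decay, Gaussian IRF,
Poisson photon noise) with known Δν and τ_r, and
`generate_toy_trajectory()` builds bilayer trajectories with known
densities.

## Worked example

```r
library(tdfs)

truth <- ground_truth(seed = 1)       # the default synthetic experiment
truth
#> Synthetic TDFS ground truth
#>   nu(0) = 24000, nu(inf) = 21000, delta_nu = 3000 cm^-1
#>   relaxation: 0.50 x 0.50 ns + 0.50 x 2.50 ns  (tau_r = 1.500 ns)
#>   lifetime 4.00 ns; band delta 3000 cm^-1, gamma -0.30
#>   4096 channels x 0.01 ns; IRF FWHM 0.100 ns; 15 wavelengths

fit <- tdfs(generate_dataset(truth))  # full chain: fit, TRES, maxima, metrics
fit
#> Time-dependent fluorescence shift fit
#>   nu(0)    = 24018 cm^-1 (fit)
#>   nu(inf)  = 20991 cm^-1
#>   delta_nu = 3027 cm^-1
#>   tau_r    = 1.513 ns (numeric check 1.531 ns)
```

The recovered shift (3027 vs 3000 cm⁻¹) and relaxation time (1.513 vs
1.500 ns) are within about 1% of the generating values at a peak count of
10⁴ photons. `plot(fit)` shows ν(t) with its fit, `summary(fit)` the
relaxation components and per-wavelength reduced χ², `predict(fit, t)`
the fitted ν(t), and `tdfs_uncertainty(fit)` parametric-bootstrap
intervals. For file-based work, `run_pipeline()` reads decay/IRF ASCII
files plus a steady-state CSV and writes the ν(t) table, metrics and a
run manifest.

MD post-processing on a toy bilayer with known structure:

```r
tj <- generate_toy_trajectory(50,
  groups = list(PO4 = list(count = 300, mean_z = 20, sd_z = 2)),
  box = c(64, 64, 100), lipids_per_leaflet = 64L, seed = 3)
area_per_lipid(tj)
#> Area per lipid: 64.000 +/- 0.000 A^2 (0.6400 nm^2, 50 frames, 5 blocks)
peak_stats(density_profile(tj), "PO4")$position   # ~ +/-20 A
```

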