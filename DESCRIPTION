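Package: tdfs
Title: Time-Dependent Fluorescence Shift Analysis of Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of time-dependent fluorescence shift (TDFS) experiments
    on solvatochromic membrane probes such as Laurdan.  Fits time-correlated
    single-photon counting (TCSPC) decays by iterative reconvolution against a
    measured instrument response function, reconstructs time-resolved emission
    spectra (TRES) by normalisation to the steady-state spectrum, fits each
    time slice with an asymmetric log-normal lineshape, and converts the
    time course of the emission maximum into the overall dynamic Stokes shift
    and the integral relaxation time.  Also computes Laurdan generalized
    polarization from 440/490 nm intensities or band integrals, and
    post-processes bilayer molecular-dynamics trajectories into symmetrized
    number-density profiles, ion-peak statistics and area-per-lipid series.
    A fully parameterised synthetic-data generator (decays, spectra, toy
    trajectories) with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
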