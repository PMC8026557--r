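Package: voigtline
Title: Voigt Profile Lineshapes for Protein Folding Distributions and
    Quasielastic Neutron Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and approximate evaluation of the Voigt profile (the
    Gaussian-Lorentzian convolution lineshape) via a rapidly converging
    theta-like series, adaptive quadrature oracles, and a Faddeeva-function
    route; closed-form variance expressions for the Gaussian-dominance
    regime together with the divergence of the full-profile variance;
    symmetric Levy-stable densities by cosine-transform quadrature and the
    truncated Levy flight with its cutoff-length reading of the reciprocal
    line-damping parameter; and fitting engines that extract the
    line-damping parameter xi from empirical probability distributions
    (radius-of-gyration or dihedral-angle histograms) and from quasielastic
    neutron-scattering spectra convolved with a Gaussian instrument
    resolution. Seeded synthetic generators (two-state switching
    trajectories, overdamped circular diffusion, delta-plus-Lorentzian
    spectra) emulate the statistical structure of molecular-dynamics and
    neutron-scattering data so every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
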