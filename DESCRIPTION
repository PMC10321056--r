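Package: umbrellabind
Title: Umbrella-Sampling Free-Energy Profiles and Standard-State Binding
    Energies for Host-Guest Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating potentials of mean force from umbrella
    sampling along a cavity axis (binned WHAM with histogram-overlap
    diagnostics and block-averaged uncertainties), converting them into
    standard-state binding free energies with the cylindrical flat-bottom
    restraint correction, and analysing hydration shells and cavity
    wetting/de-wetting in host-guest trajectories.  Includes a seeded
    overdamped-Langevin (Brownian dynamics) generator of synthetic biased
    trajectories and pseudo-solvent frames with analytically known ground
    truth, plus fixed-charge 12-6 Lennard-Jones / buffered 14-7 pair-energy
    machinery for guest-host interaction profiles.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
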