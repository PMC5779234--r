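Package: smdwell
Title: Single-Molecule Dwell-Time Kinetics of Spliceosome E-Complex Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of colocalization single-molecule
    spectroscopy (CoSMoS) recordings of U1 snRNP and branchpoint bridging
    protein (BBP) binding to surface-tethered pre-mRNAs during spliceosome
    E-complex formation. Provides exact-stochastic (Gillespie) simulation of
    labeled-state binding schemes including a coupled two-channel U1/BBP
    model, frame sampling with photobleaching and surface background,
    extraction of dwell times with truncation bookkeeping, maximum-likelihood
    fitting of window-censored exponential and biexponential dwell-time
    densities with bootstrap uncertainties and likelihood-ratio model
    selection, probability-density histograms with binomial counting errors,
    photobleaching extrapolation across laser powers, two-channel
    colocalization analysis (E-complex lifetimes, conditional U1 lifetimes,
    randomized controls, disassembly-fate and assembly-order tallies), affine
    field-of-view registration, and splice-site/U1 snRNA base-pairing
    register scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
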