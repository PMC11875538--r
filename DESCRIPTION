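Package: lcfingerprint
Title: Conformational Fingerprinting of Immunoglobulin Light-Chain Ensembles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of weighted conformational ensembles of two-domain
    immunoglobulin light-chain homodimers. Computes bend and distance
    collective variables (elbow angle, inter-domain center-of-mass
    distances), classifies conformers into four quaternary states and
    estimates state populations with block-averaged errors, converts
    final metadynamics bias potentials to frame weights, builds weighted
    two-dimensional free-energy surfaces, computes weighted per-residue
    RMSF profiles and Ramachandran occupancies, back-calculates SAXS
    intensities with a coarse Debye model and compares them to
    experimental curves (scale fitting, reduced chi-square, Guinier
    radius of gyration, Kratky transform). A deterministic synthetic
    dumbbell-dimer generator provides ground-truth ensembles so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
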