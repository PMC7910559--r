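Package: hvgating
Title: Simulation and Analysis of Voltage-Gated Proton Channel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative electrophysiology of voltage-gated
    proton (Hv) channels. Provides a kinetic-scheme simulator that generates
    episodic voltage-clamp recordings (Boltzmann-activated, proton-selective
    currents with sigmoidal activation lag, multi-exponential deactivation
    tails, pH-gradient-coupled voltage dependence, ohmic leak, rundown and
    open-channel or closed-state block), a plain-text episodic trace format,
    the full measurement pipeline (leak subtraction, rundown correction,
    conductance-voltage curves with Boltzmann fits, activation time constants,
    reversal-potential and proton-selectivity analysis, limiting-slope gating
    charge, inhibition and kinetics ratios), the group comparison statistics
    used with such measurements, and a per-residue sequence-divergence mapping
    procedure (BLOSUM62 with affine gaps, smoothed 0-1 divergence scale,
    projection onto structural models) for chimera design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
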