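Package: nucfret
Title: Single-Particle FRET and Trajectory Analysis of Nucleosome
    Conformational States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-particle FRET (spFRET) measurements
    of nucleosome reorganization. Computes crosstalk-corrected proximity
    ratios from two-channel photon bursts, builds relative-frequency E_PR
    distributions, decomposes them into sums of Gaussian peaks with
    RMSD-based selection of the peak count, quantifies conformational
    subpopulations (low-, middle- and high-FRET states) as peak-area
    fractions, and aggregates replicate experiments. Also compares
    single-particle acceptor-intensity distributions between gel bands to
    infer complex stoichiometry, and analyses label-site coordinate
    trajectories: inter-label distance time series, Kabsch-superposition
    backbone RMSD, equilibration detection and equilibrium statistics.
    Seeded synthetic generators for photon bursts, particle intensities and
    mean-reverting distance trajectories stand in for the microscope and
    the molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
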