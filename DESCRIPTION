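Package: helipose
Title: Helical Parameters, Ligand Pose and Free-Energy Analysis for DNA-Intercalator Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing how planar intercalating ligands such as
    doxorubicin engage double-stranded DNA and G-quadruplex tetrads in molecular
    dynamics trajectories. Computes base, base-pair and tetrad reference frames
    and the full set of intra-pair and inter-pair helical parameters (rise,
    twist, roll, tilt, slide, shift; buckle, propeller, opening) with a
    mid-frame decomposition; tracks ligand pose through five collective
    variables (in-plane displacement, in-plane orientation, out-of-plane
    height, and sugar-moiety sidedness) and aggregates them into orientation
    density maps; classifies per-frame binding modes (terminal stacking,
    full or partial intercalation, groove embedding); locates torsional-stress
    hotspots along a duplex by sliding-window rise profiles with a permutation
    test for intercalation enrichment; and reconstructs one-dimensional
    potentials of mean force from umbrella-sampling window time series by the
    weighted histogram analysis method with bootstrap uncertainties. A
    synthetic-geometry generator builds idealized B-DNA duplexes, tetrad
    stacks, planted ligand poses, and exact samples from known potentials
    under harmonic biases for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
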