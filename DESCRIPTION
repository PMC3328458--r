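Package: duplexdyn
Title: Conformational Dynamics Analysis of B- and Z-DNA Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational dynamics of alternating
    d(GC)n DNA duplexes in B and Z form, with or without cytosine 5-methylation.
    Builds idealized B- and Z-form duplex models, generates synthetic coordinate
    trajectories and two-state torsion time series, computes backbone and
    glycosidic dihedrals and sugar-pucker pseudorotation, classifies BI/BII and
    alpha/gamma backbone substates with dwell-time and passage statistics,
    derives histogram-based (Boltzmann-inversion) free-energy profiles along the
    epsilon-zeta coordinate, computes base-pair and base-pair-step parameters,
    theoretical B-factors and RMSD via least-squares superposition, and performs
    MM/PBSA-style free-energy bookkeeping with per-component contrasts and
    two-sample tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
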