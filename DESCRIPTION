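Package: pmfkit
Title: Umbrella Sampling, WHAM and Dual-Level Free-Energy Surfaces for
    Covalent Inhibition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing potentials of mean force from umbrella
    sampling: harmonic-bias window generation on analytic energy surfaces
    via BAOAB Langevin dynamics, 1D and 2D weighted histogram analysis
    (WHAM), maximum-probability path tracing on 2D free-energy surfaces
    with perpendicular-coordinate integration, and dual-level (spline)
    energy corrections.  Includes a geometric descriptor suite for
    covalent-inhibition trajectories: Buergi-Dunitz and Flippin-Lodge
    nucleophilic attack angles, hydrogen-bond detection, Kabsch-superposed
    RMSD, ring-puckering dihedrals, Eisenberg hydrophobicity mapping, and
    per-residue Coulomb plus Lennard-Jones interaction energies with a
    smooth switching function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    pracma,
    bio3d,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
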