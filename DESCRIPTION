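Package: tapsr
Title: Travelling-Salesman Automated Path Searching for Minimum
    Free-Energy Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Locates minimum free-energy paths (MFEPs) between metastable
    states of molecular and model systems by travelling-salesman automated
    path searching (TAPS).  Provides path collective variables (PCV-s,
    PCV-z) with their smoothing constant lambda, restrained node sampling
    in hyperplanes perpendicular to the current path, travelling-salesman
    reordering of candidate nodes, geometric path reparametrization, and
    convergence monitoring via the mean path distance z-bar and classical
    multidimensional scaling.  Free-energy profiles along the converged
    path are computed by umbrella sampling and the weighted histogram
    analysis method (WHAM), with automatic identification of transition
    and intermediate states.  An overdamped Langevin sampler on bundled
    analytic potentials (Mueller-Brown, quartic double well, three-hole)
    supports desk-scale validation; Kabsch superposition and
    align-set/compute-set RMSD metrics extend the same machinery to
    molecular coordinates read from XYZ or PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
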