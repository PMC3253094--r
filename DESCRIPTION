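Package: lqrfold
Title: Optimal-Control Folding Trajectories for Coarse-Grained Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates low-energy protein folding trajectories by coupling a
    coarse-grained (C-alpha) optimal-control stage to an iterative refinement
    loop. The coarse-grained stage builds an elastic-network weight matrix from
    the current contact map, solves the infinite-horizon Linear Quadratic
    Regulator via the continuous algebraic Riccati equation, decomposes the
    optimal gain into an inter-residue harmonic spring matrix plus uniform
    native anchors, and propagates the closed-loop (optionally Langevin)
    dynamics. A scheduler picks target frames from each optimal trajectory,
    a refinement backend (built-in mock refiner, or export of targeted-MD
    inputs for an external engine) carries the conformation toward the target,
    and the contact map is rebuilt from the refined structure before the next
    cycle. Includes synthetic structure generators, trajectory metrics
    (RMSD, radius of gyration, contact counts, energy fluctuation), and PDB
    trajectory I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    deSolve,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
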