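Package: mdrin
Title: Essential Dynamics and Residue Interaction Network Analysis of
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis of biomolecular molecular dynamics
    trajectories of protein-nucleic acid complexes: multi-model PDB input
    and output with an atom-selection mini-language, superposition-based
    deviation and fluctuation metrics (RMSD, RMSF, radius of gyration,
    solvent-accessible surface area, centre-of-mass and minimum distances),
    geometric hydrogen-bond detection and counting, pairwise nonbonded
    interaction-energy decomposition into Coulomb and Lennard-Jones terms,
    essential dynamics (coordinate covariance analysis, principal-component
    projections, free-energy landscapes, covariance overlap, root mean
    square inner products, porcupine vectors), and residue interaction
    networks with Brandes betweenness centrality including a reference
    versus variant differential procedure.  Includes deterministic synthetic
    generators (toy receptor-ligand complexes with planted hydrogen bonds,
    low-rank Gaussian fluctuation trajectories, graph and parameter
    fixtures) so every stage is testable against planted ground truth, and
    a config-driven pipeline that writes a CSV/PDB report tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    igraph,
    pracma
Config/testthat/edition: 3
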