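Package: cmqa
Title: Chaotic Multiquenching Annealing for Dihedral-Angle Energy Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the chaotic multiquenching annealing (CMQA) optimizer
    for protein-conformation energy minimization in dihedral-angle space,
    together with classical simulated annealing and multiquenching-annealing
    baselines. Provides quenching and geometric cooling schedules with analytic
    temperature tuning, a chaotic local search driven by sine-singularity maps,
    a least-squares dynamic-equilibrium stopping rule, a reduced four-component
    peptide energy model with torsion-to-Cartesian chain building,
    planted-minimum validation landscapes, distance-RMSD reporting, and a small
    command-line interface for folding runs, variant comparisons and parameter
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
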