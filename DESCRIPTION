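Package: switchWE
Title: Weighted-Ensemble Design of Protein Conformational Switch Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Residue-level, native-centric (Go-type) modelling of
    alternate-frame-folding (AFF) protein conformational switches, with
    weighted-ensemble (WE) path sampling of switching pathways under
    overdamped Brownian dynamics.  Builds C-alpha bead models and native
    contact maps from PDB structures, assembles dual-frame AFF topologies
    in which two overlapping folds compete for a shared segment, applies
    in-silico underpacking mutations and ligand bias, and calibrates
    contact strengths against a target folding stability.  The WE engine
    supports steady-state recycling and equilibrium modes with rigorous
    trajectory-weight management; analysis tools turn WE archives into
    rate constants (k = f/p), stabilities, mean first passage times,
    free-energy surfaces, transition path ensembles, per-residue contact
    scores, and ranked candidate mutations for accelerating switching.
    Ships seed-deterministic synthetic fixtures (1-D diffusive wells,
    beta-hairpin folders, a miniature AFF construct) with brute-force
    oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'contacts.R'
    'aff.R'
    'dynamics.R'
    'we.R'
    'kinetics.R'
    'calibrate.R'
    'ensemble.R'
    'fixtures.R'
    'structure.R'
    'zzz.R'
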