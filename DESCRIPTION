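Package: pepdock
Title: Coarse-Grained Flexible Peptide-Protein Docking by Replica-Exchange
    Monte Carlo Annealing
Version: 0.1.0
Authors@R: person("pepdock", "developers", role = c("aut", "cre"),
    email = "pepdock@example.org")
Description: Blind flexible docking of short peptides (up to 30 residues) to
    protein receptors with no prior knowledge of the binding site. Receptor
    and peptide are reduced to a two-center-per-residue coarse-grained
    representation; the peptide is started from random conformations on a
    sphere around the receptor and docked by replica-exchange Monte Carlo
    simulated annealing under flat-bottom distance restraints that keep the
    receptor near its input conformation. Bound low-energy snapshots are
    filtered per trajectory and reduced to ten final models by multi-restart
    k-medoids consensus clustering; model quality is assessed by ligand RMSD
    after receptor superposition. Includes synthetic receptor/peptide fixture
    generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
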