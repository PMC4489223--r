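---
title: "pepdock: model, sampling protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepdock: model, sampling protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

pepdock performs blind flexible docking of a short peptide (up to 30
residues) onto a protein receptor: no binding-site information is given, the
peptide is fully flexible, and the receptor backbone is allowed small
fluctuations. The pipeline has four stages:

1. **Initialization.** Random self-avoiding peptide conformations are placed
   on the surface of a sphere centered at the receptor's C-alpha centroid,
   with radius equal to the receptor's longest dimension (maximum pairwise
   C-alpha distance) plus 20 Å.
2. **Sampling.** Replica-exchange Monte Carlo (REMC) with 10 replicas
   uniformly spread on a reduced-temperature ladder; the whole ladder is
   annealed multiplicatively over the macrocycles. Each replica yields a
   trajectory of time-stamped snapshots (1000 at defaults; 10 000 models in
   total). The receptor is held near its input conformation by flat-bottom
   distance restraints.
3. **Model selection.** Per trajectory, unbound snapshots are discarded and
   the 100 lowest-binding-energy models are kept; the pooled set is
   clustered by k-medoids 100 times with random initial medoids and k = 10,
   and the 10 consensus medoids become the final models.
4. **Evaluation.** Model quality is ligand RMSD: superimpose the receptors
   (Kabsch), compute RMSD over peptide C-alpha atoms with no further
   fitting. High quality means RMSD < 3 Å, medium 3–5.5 Å (both boundaries
   inclusive), low > 5.5 Å. Contact maps between peptide and receptor
   residues use a user-defined cutoff (default 6.5 Å) on the side-chain
   centers.

## The coarse-grained representation

Each residue carries two interaction centers: the C-alpha and a pseudo
side-chain centroid. The centroid is the mean of the side-chain heavy atoms
when coordinates are available; otherwise it is placed at a per-residue-type
canonical distance opposite the bisector of the C-alpha→N and C-alpha→C
directions (for bare C-alpha chains, the bisector of the two neighboring
C-alpha directions; glycine's centroid coincides with its C-alpha). For the
*sampled peptide* the centroid is always a deterministic function of the
C-alpha trace, recomputed after every accepted move. Terminal residues use
the two nearest chain bonds, so the rule is covariant under rigid
transformations — a requirement for the energy to be invariant under global
rotation (verified to 1e-9 in the tests). A known edge case: a 1-residue
peptide has no chain direction and receives an axis-aligned centroid; its
energy is then not rotation-covariant. Consecutive C-alphas are connected by
virtual bonds of 3.8 Å (trans peptide; cis-proline is ignored) with a hard
±0.4 Å tolerance enforced by move rejection.

This two-center, off-lattice model is the package's principal simplification
relative to lattice models with up to four centers per residue; it keeps the
full protocol architecture testable while making the move set simple.

## The interaction model (a documented stand-in)

Statistical force fields are not reproduced here. The energy is a small,
pluggable stand-in in reduced units (no claim of kcal/mol), with three
blocks:

* **Intra-peptide.** A flat-bottom band on pseudo-bond angles (allowed
  75–150°, quadratic penalty outside, k = 5 rad⁻²); a secondary-structure
  bias pulling angles toward 91° (H) or 124° (E) with strength 0.5 rad⁻²
  (coil residues are unbiased — consistent with the advice that
  over-assigning regular structure is worse than under-assigning); and
  excluded volume between nonconsecutive C-alphas with a 5.0 Å minimum
  separation (quadratic soft core, k = 10 Å⁻²). The 5.0 Å intra-peptide
  value is deliberately larger than the 4.0 Å inter-chain clash distance:
  it models the local stiffness of short peptides and, practically,
  prevents the pair-additive contact term from being gamed by unphysical
  chain collapse.
* **Inter-chain.** A residue-type contact potential on side-chain-centroid
  pairs within a distance shell (default 4.5–7.0 Å). The default matrix is
  the negated, scaled outer product of Kyte–Doolittle hydropathies
  (hydrophobic–hydrophobic favorable, mixed contacts penalized); any
  symmetric 20×20 matrix can be plugged in. The **attractive part
  saturates**: each peptide residue contributes only its single most
  favorable in-shell contact, while unfavorable contacts sum. Without
  saturation the global minimum of an additive hydropathy potential on a
  designed-site fixture is a peptide ball stacked into the site (we
  measured minima three times deeper than any extended pose), which no
  real contact potential rewards; one dominant packing partner per side
  chain is the coarse-grained reading of contact saturation. C-alpha pairs
  closer than 4.0 Å pay a quadratic clash penalty. Contacts with receptor
  residues marked "unlikely to bind" add a fixed positive penalty
  (default 2.0) per contact, and final models still contacting such
  residues are additionally removed post hoc.
* **Receptor restraints.** Every receptor residue pair with input C-alpha
  distance in [5, 15] Å and intra-chain sequence separation ≥ 5 (pairs in
  different chains always eligible) is restrained to its input distance
  with a flat bottom of ±1 Å and a linear penalty beyond it. The base
  slope (default 5 per Å) is halved if either endpoint is marked
  moderately flexible and zeroed if either is fully flexible; when the two
  endpoints disagree the more flexible mark wins. For compact receptors
  the network is dense enough that the receptor stays near-native — about
  1 Å mean C-alpha RMSD to the input (after superposition) even at the
  hottest replica temperature. One instructive caveat: the restraint band
  tops out at 15 Å, so an *isolated thin helix* possesses zero-energy
  bending modes in which every restrained pair stays inside its ±1 Å flat
  bottom while the ends swing by several Å; no slope value suppresses
  them (we measured ~3 Å mean drift regardless of stiffness). This is a
  property of the restraint design itself, which presumes globular
  receptor domains; the near-native test therefore uses compact fixtures.

`E_total = E_intra_peptide + E_inter + E_restraint`; the binding energy used
to rank snapshots during filtering is the inter-chain block alone. A pose is
*bound* when the minimum peptide–receptor C-alpha distance is at most 8 Å
(closed boundary; the criterion is not stated by the protocol description
and is configurable). Note one geometric caveat: with long side chains, an
sc–sc contact at 7 Å can in principle coexist with a minimum C-alpha
distance slightly above 8 Å, so "unbound implies zero binding energy" holds
for separated poses (and for all initialization-sphere placements) but is
not a theorem of the defaults.

## Sampling

The temperature ladder interpolates linearly between 3.5 and 1.0 (reduced
units) over 10 replicas; at macrocycle *m* of *M* the whole ladder is scaled
by `0.6^((m-1)/(M-1))`, so the run ends with every replica at 0.6 times its
initial temperature. The endpoints and the factor are configuration with
these defaults; they were fixed, together with the move budget (300
attempted moves per replica per snapshot interval), by requiring the toy
funnel property below to hold, and were not revisited afterwards.

The move set: single-residue peptide displacement (≤ 0.7 Å), crankshaft
rotation of 2–4-bond fragments about their chord (≤ 60°), rigid-body peptide
rotation (≤ 30°) plus translation (≤ 2 Å), and single-C-alpha receptor
displacement (≤ 0.5 Å, side-chain centroid follows). Crankshaft moves
preserve bond lengths exactly; displacement moves are rejected outright if a
virtual bond leaves 3.8 ± 0.4 Å. Acceptance is Metropolis at the replica's
temperature, with the proposal energy recomputed in full (systems are small;
this removes any possibility of bookkeeping drift, which the tests verify
against re-evaluation). Exchanges are attempted after every snapshot
interval between adjacent replicas, alternating even and odd pairs, with
probability `min(1, exp((1/T_a − 1/T_b)(E_a − E_b)))`; configurations swap,
temperatures stay attached to their rungs.

One non-obvious but essential ingredient: the peptide centroid is confined
to a hard spherical wall at the initialization radius. A free 3-D random
walk is transient — without the wall the peptide drifts away and never
returns (we observed runs with zero bound snapshots once the move budget was
raised). The wall is the simulation volume; it is configurable and disabled
(`Inf`) outside docking runs.

All randomness flows through R's RNG: a run is bit-reproducible given the
inputs, the configuration and the seed, which the pipeline records in a
plain-text log sufficient to recreate the simulation.

## Model selection details

Filtering keeps, per trajectory, the bound snapshots sorted by binding
energy (stable tie-break on snapshot index), capped at 100. The pose metric
for clustering is the same receptor-superposed peptide C-alpha RMSD used for
evaluation — the original protocol does not state its clustering metric, so
we chose consistency with the quality measure. This metric is symmetric and
zero exactly on identical poses, but RMSD after independent superpositions
need not satisfy the triangle inequality, and we do not rely on it.

`kmedoids_once` is a PAM-style alternation of assignment (nearest medoid,
ties to the lower index) and medoid update (member minimizing the
within-cluster distance sum, ties to the lowest index) until the cost stops
decreasing. The consensus procedure — the protocol gives it one sentence —
is implemented as frequency-of-selection: 100 restarts from random initial
medoids, count how often each model is chosen as a medoid, take the k = 10
most frequent (ties broken by lower binding energy, then lower index), and
assign every model to its nearest consensus medoid. A best-cost single-run
alternative is available behind `method = "best_cost"`. Per-cluster density
(mean member-to-medoid distance) and diversity (maximum) are reported as in
the server's clustering table.

## Synthetic fixtures and what a green test establishes

Fixtures are generated programmatically, never stored: ideal α-helices
(rise 1.5 Å/residue, 100°/residue, radius 2.3 Å, full backbone so
validation passes), a two-antiparallel-helix groove, a three-helix "cradle",
and compact random globules (confined self-avoiding walks). The groove uses
a 13 Å axis separation — at 10 Å the inter-wall free space is narrower than
the clash distance and no peptide pose is clash-free.

The funnel-recovery property — REMC at defaults places at least one of the
10 final models within 5.5 Å ligand RMSD of a designed reference pose in at
least 2 of 3 seeded runs — is carried by the cradle, not the groove. An open
groove is translationally degenerate along its axis under any smooth contact
potential, so "the designed pose" is not a well-posed target there; the
groove fixture still provides a bound, energetically favorable reference for
unit tests. The cradle localizes by construction: two walls and a floor form
a channel that only an extended peptide fits (collapse is sterically
blocked), the outer surface is lysine (repulsive to the hydrophobic
peptide), and the channel lining is leucine in the lower half and isoleucine
in the upper half while the peptide is FFFSVVV with boosted F–L and V–I
contact energies — sliding or reversing the peptide forfeits boosted
contacts, so the extended centered pose is the unique basin. Verified at
full protocol defaults: best final-model RMSD 5.26/4.57/4.68 Å for seeds
1–3; the 10-macrocycle smoke version used in the test suite gives
4.91/4.44/4.38 Å (about 70 s per seeded run).

What a green funnel test does establish: the whole pipeline — initialization,
REMC annealing, restraints, filtering, consensus clustering, RMSD
evaluation — cooperates to find and rank a designed binding site from a
blind start. What it does not establish: anything about accuracy on real
protein–peptide complexes, which would require the original statistical
force field and experimental structures, both out of scope here.

## Numerical choices and degenerate inputs

* Kabsch superposition via 3×3 SVD with a determinant sign correction;
  an independent quaternion (Horn) implementation serves as the test
  oracle at 1e-6.
* Flat-bottom restraint energy is exactly zero on [d_ref − 1, d_ref + 1];
  the acceptance grid (step 1e-4 Å) reports 1.0 as the largest free
  violation.
* Energies are re-evaluated in full per proposal; stored snapshot energies
  match re-evaluation to better than 1e-6.
* Quality boundaries: 3.0 Å and 5.5 Å both classify as medium, exactly as
  the criteria are printed.
* Empty edge cases: a trajectory with no bound snapshots filters to an
  empty set with a warning; a job whose trajectories are all unbound
  returns status `failed_no_bound_states` rather than an error; fewer
  models than k reduces k with a warning; duplicate points leave the
  k-medoids cost unchanged (lowest-index tie-breaks).
* Restraint generation, contact maps, pose distances and energies are all
  checked against literal double-loop oracles at 1e-6 to 1e-9.

## Known limitations

* The interaction model is a stand-in; rankings on real systems would be
  dominated by its crudeness, and no benchmark claims are made.
* Receptor flexibility is single-center displacements under restraints —
  adequate for "small backbone fluctuations", not for loop rearrangements.
* All-atom reconstruction of final models is out of scope; outputs are
  C-alpha traces (a hook point for an external reconstruction tool is the
  multi-MODEL PDB output itself).
* Secondary-structure prediction is not integrated: the peptide
  secondary-structure string is user-supplied or defaults to all-coil.
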