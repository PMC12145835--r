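---
title: "Methods: torsion-MI allosteric communication pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torsion-MI allosteric communication pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Allosteric communication is treated as statistical dependence between the
internal (torsional) degrees of freedom of distant residues, estimated over
a conformational ensemble. The chain of quantities is:

1. **Torsion series.** φ, ψ and χ1–χ4 per residue, in degrees, wrapped to
   `[-180, 180)` (with +180 mapped to −180 so every angle has one binned
   representation). Torsions whose atoms are missing are skipped and logged,
   never NaN-filled.
2. **Mutual information.** For two series the plug-in estimate on a fixed
   24-bin (15°/bin) joint histogram, in nats. Zero-count cells contribute 0.
   The residue-pair value aggregates over all torsion-pair combinations;
   the default aggregation is **max** (strongest single channel, scale-free);
   **sum** is available. Pairs closer than 3 in sequence on one chain are
   flagged ineligible for the graph — neighbors share backbone atoms and
   their MI is trivially inflated — but their values are still reported.
3. **Graph.** Edges are the eligible pairs in the top 10% of MI values
   (rank threshold; ties at the threshold are always included, so the edge
   set never depends on sort order). Edge weight is `-ln(MI/MI_max) ≥ 0`,
   the additive transform under which a Dijkstra shortest path maximizes
   the product of normalized MI.
4. **Pathways.** For each source and every sink whose reference Cα–Cα
   separation exceeds 10 Å, the minimum-weight path. Ties in weight break
   to the lexicographically smallest residue-key sequence, so output is
   deterministic. Unreachable and sub-threshold pairs are counted, not
   silently dropped.
5. **Pipelines.** Pathway–pathway distance is the symmetrized mean, over
   the residues of one path, of the nearest-residue Cα distance to the
   other; single-linkage components at 7 Å form pipelines, ranked by
   population with total MI as tie-break. The representative is the member
   minimizing mean distance to the rest.
6. **Hub scores.** The number of pathways containing a residue, endpoints
   included. Conservation — Σ hubs = Σ pathway lengths — holds exactly and
   is asserted in the tests.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| MI bins | 24 | — | 15° bins resolve rotamer wells; fixed bins keep the estimator deterministic and its independence bias analytically boundable by `(B−1)²/(2N)` nats |
| aggregation | max | — | no published aggregation rule exists; max preserves the strongest channel |
| sequence-separation exclusion | 3 | residues | removes backbone-shared trivial correlation; 0 mimics no exclusion |
| top MI fraction | 0.10 | — | graph sparsity rule |
| source–sink separation | 10 | Å (Cα–Cα, reference structure) | restricts pathways to genuinely distant pairs; measured on the starting structure for determinism |
| pipeline proximity | 7 | Å | single-linkage threshold |
| contact criterion | 4.5 | Å heavy-atom minimum | untyped and hydrogen-free, hence reproducible on deposited coordinates; typed (H-bond/salt-bridge) criteria would require protonation |
| contact-frequency filters | 40 / 10 | % of frames | persistent vs extended interface maps; the ≥ filter is inclusive |
| nonbonded cutoff | 1.2 | nm | plain truncation; a per-pair decomposition cannot contain a mesh (PME) term, so none is attempted |
| cluster cutoffs | 1.2 / 0.85 | Å pairwise fitted RMSD | whole-pocket vs microswitch-scale clustering |
| PCA extreme frames | 30 | frames | interpolation count along a chosen component |

Units follow the field: Å for distances, kJ/mol for energies, degrees at
the interface (radians internally), nats for MI. The Coulomb constant is
f = 138.935458 kJ·mol⁻¹·nm·e⁻²; Lennard-Jones parameters combine by
Lorentz–Berthelot (arithmetic σ, geometric ε).

## What the synthetic generators emulate — and what they do not

`generate_torsion_system()` plants a hidden two-state symmetric Markov
chain (flip probability 0.02/frame) behind an ordered relay of residues.
Each relay residue copies the latent state with probability c per frame
(otherwise it draws an independent state) and emits
χ1 ~ vonMises(center(state), κ) with centers −60°/180° (gauche⁻/trans) and
κ = 50 (≈8° well width). Background residues run their own independent
chains. This reproduces the *statistical* signature the method assumes —
bimodal rotamer populations with graded inter-residue coupling and an
analytic MI ceiling of ln 2 — and nothing else: no sterics, no force
field, no kinetics. All randomness derives from one seed, and draws are
laid out so that regenerating with a different coupling reuses the same
latent chain, corruption uniforms and angular deviations (common random
numbers); relay MI is therefore monotone in c by construction, which the
property tests exploit.

`generate_cartesian_system()` builds an idealized Cα helix bundle
(1.5 Å rise, 100°/residue, helix radius 2.3 Å, axes spaced ≥ 10 Å) and
adds per-residue isotropic Gaussian jitter, scheduled contact formation
and an optional collective mode. Two geometric subtleties were found
during development and are part of the generator's contract:

* **Scheduled contacts are exclusive.** The contact former is placed
  4.0 Å from its partner *radially outward from the partner's helix axis*.
  Displacing it along the inter-residue vector — the naive choice — left
  it within 4.5 Å of the partner's helical neighbors (the rise is only
  1.5 Å/residue), so the planted occupancy table was not exactly
  recoverable. With the radial placement the nearest non-partner residue
  is > 7 Å away and the contact table equals the schedule exactly.
* **Planted collective modes must be non-rigid.** A displacement field
  proportional to position (e.g. x-shift growing along the axis) is, to
  first order, a rigid rotation and is absorbed by the superposition step
  of PCA; recovery tests plant an axial stretch, which is orthogonal to
  all six rigid-body motions.

Consequently a green planted-mode or contact test establishes that the
analysis recovers what was planted, not that real membrane-protein
ensembles look like this.

## Numerical choices

* **Superposition** is the Kabsch SVD fit with the proper-rotation
  determinant correction; the test suite cross-checks it against an
  independent quaternion (Horn) formulation. Degenerate (collinear, < 3
  atom) fits are errors, not warnings.
* **RMSF** uses a two-pass scheme: align to the reference, compute the
  mean structure, re-align to the mean, then
  RMSF_i = √(mean_t |x_i(t) − ⟨x_i⟩|²). When *all* measured atoms jitter
  and the fit is on those same atoms, the rigid-body fit absorbs 6 of the
  3N fluctuation degrees of freedom and deflates RMSF by ≈ √(1 − 6/3N)
  (~10% at 10 atoms); the closed-form σ√3 check therefore fits on a
  static subset, which is also the physically meaningful protocol
  (fit on the stable core, measure the flexible part).
* **Daura clustering** recomputes an optimal superposition per frame
  pair (as the GROMOS method does) rather than sharing one reference;
  all tie-breaks (centroid choice, equal-size ordering) go to the lowest
  frame index.
* **Dihedrals** follow the IUPAC sign convention. Note the convention's
  actual symmetries, both asserted in the tests: the angle is *invariant*
  under atom-order reversal and *negated* under mirror reflection.
* **MI tolerance semantics**: "agreement to 1e-12 nats" is enforced as an
  absolute difference; relative tolerances are meaningless for MI values
  near zero.
* **Exact frequencies**: contact frequencies are rationals
  (100·n_present/n_frames) computed from integer counts; repeated runs are
  bit-identical, and output CSVs use fixed numeric formatting so reruns
  are byte-identical.

## Open design points and how they were resolved

* Residue-pair MI aggregation (max vs sum vs torsion-level nodes): max by
  default, sum selectable; torsions-as-nodes was rejected to keep hub
  scores residue-valued.
* ">10 Å" separation: Cα–Cα on the reference structure (deterministic;
  configurable in code by supplying a different structure).
* Hub endpoints: included. Excluding them would zero every one-edge
  pathway's contribution and break the conservation identity used as an
  invariant.
* Side-chain minimum distances include Cβ; all geometry defaults to heavy
  atoms (deposited structures lack hydrogens).
* Replicates: analyses concatenate frames by default; energy summaries
  switch to across-replicate mean ± SD when several results are pooled.

## Limitations

* The plug-in MI estimator is biased upward by ≈ (B−1)²/(2N) nats for
  independent series; with 24 bins this is the relevant noise floor and is
  what the independence tests assert against. Miller–Madow correction is
  available but off by default (it can produce small negative values).
* Binary trajectory formats (DCD/XTC) are not read — no reader exists in
  the dependency budget; ensembles enter as multi-model PDB or in-memory
  arrays.
* The untyped 4.5 Å contact criterion differs from typed
  hydrogen-bond/salt-bridge counting; on interfaces rich in typed
  interactions it will generally report more pairs.
* Permutation-based MI significance testing is provided only as a
  diagnostic pattern in the tests (series shuffling), not as a pipeline
  stage.
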