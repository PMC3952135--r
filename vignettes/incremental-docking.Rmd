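---
title: "Incremental docking of large ligands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental docking of large ligands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incdock)
```

## The problem and the model

Rigid-receptor docking searches the motion space of the ligand: three
translational and three orientational degrees of freedom plus one dihedral
per rotatable bond. Stochastic engines handle this well up to about six
torsions; beyond that the search degrades sharply. `incdock` addresses large
ligands (peptide-sized, 10–25 rotatable bonds) by docking them
*incrementally*, so that no single engine call ever samples more than a
small torsion window.

### Torsion tree

Rotatable bonds are acyclic single bonds between heavy atoms that each have
at least two heavy neighbours; amide C–N bonds are excluded. (The source
structures do not prescribe a rotatability convention, so the package fixes
this one — it is the convention classical ligand-preparation pipelines use.)
Removing the rotatable bonds partitions the ligand into rigid groups; the
torsion tree has these groups as nodes and the rotatable bonds as edges,
rooted at the group containing the root atom. Edges are ranked by
breadth-first visit order, children visited in ascending index of the
child-side bond atom — a fixed tie-break that makes tree construction
deterministic.

The root is chosen so that the *initial fragment* — the root node plus the
nodes of the bonds ranked 1..`fragment_size` — maximises the combined count
of hydrogen-bond donors and acceptors (donors and acceptors counted
separately; an atom that is both contributes twice). Ties break by smaller
maximum tree depth, then lower atom index. When a positional restraint is
set, the restrained atom is used as the root instead, so the restrained atom
is present from the first increment onward.

### The increment schedule

With the defaults (`fragment_size = 6`, `extension_size = 3`,
`reexplore_size = 3`) the active torsion windows for a 14-bond ligand are
[1–6], [4–9], [7–12], [10–14]: each extension adds the next three ranked
bonds and re-explores the three most recent ones, freezing everything
older. When fewer than `extension_size` bonds remain the new set is
clipped and the re-explored set kept, which is how the final [10–14] window
(3 re-explored + 2 new) arises. `plan_schedule()` exposes the schedule as
data; a property test checks that every rank is newly explored in exactly
one step for arbitrary bond counts.

### Dock–select–extend

The initial fragment is docked with `initial_runs = 50` independent engine
runs; `select_k = 5` lowest-scoring conformations are selected; each
selected parent is extended and re-docked with `runs_per_parent = 20` runs,
pooling 5 × 20 = 100 candidates per round; selection and extension repeat
until the whole ligand is placed, so the final pool always holds 100 fully
docked conformations (or `initial_runs` when the ligand has at most
`fragment_size` bonds and the protocol degenerates to one engine call).
These counts are configuration, not constants. Every sub-docking draws its
seeds from an independently derived block, so results are bitwise identical
regardless of the order in which sub-dockings execute.

## The scoring field

The engine treats the score as a black box behind `score_pose()`, so any
backend honouring that contract can replace the built-in one (the
`docking_engine` adapter contract). The built-in field is a deliberately
simple grid force field:

* 12-6 van der Waals term with per-type-pair radii `R_ij = (R_ii + R_jj)/2`
  and well depths `eps_ij = sqrt(eps_i eps_j)` from a fixed, documented
  table over the types {C, A, N/NA, O/OA, S/SA, H/HD, P, halogens};
* a 12-10 term (`R = 1.9` Å, `eps = 5` kcal/mol) for donor–acceptor pairs;
* Coulomb electrostatics with the distance-dependent dielectric
  `eps(r) = 4r`;
* node values clamped at 1e5 kcal/mol; atoms outside the box add a 1e6
  kcal/mol penalty each, which unambiguously rejects escapes.

There is no desolvation or torsional-entropy term: the protocol's
contribution is the incremental search, not the energy model, and the
simplification keeps the field reproducible and fully testable. Maps are
tabulated on a rectangular grid (default spacing 0.375 Å; box dimensions
are given in grid points, so a 76 × 80 × 60 box spans
(npts − 1) × spacing Å per axis) and scored by trilinear interpolation.

**Where grid and direct scores agree.** Trilinear interpolation has error
on the order of `f''(r) h² / 8`. For the 12-6 wall this exceeds 1 kcal/mol
inside r ≈ 3.6 Å of a carbon receptor atom at any feasible spacing, so the
grid–direct equivalence tests sample the physically meaningful, non-clashing
region (r ≥ 0.95 R_ij). A separate property fixes one pose and checks the
error strictly decreases at spacings 0.75/0.375/0.1875 Å.

### Restraints

A restraint names one ligand atom and a target location; conformation
*selection* (never the engine itself) then ranks by
`S = w · D_a + S_engine` with `w = 0.25` kcal/(mol·Å²) by default, so
`D_a = 10 Å²` costs 2.5 kcal/mol. The penalty is quadratic and monotone in
`D_a`; ties in `S` break by engine score, then insertion order.

## The engine

One engine run is a generational genetic algorithm over the genome
(translation, orientation quaternion, active torsions): population 50,
elitism 1, tournament selection (k = 2), two-point crossover with the
quaternion renormalised, Gaussian mutation (σ = 1 Å translation, 0.1 rad
rotation/torsion), greedy local search on the top 10% of each generation,
and a final annealed coordinate-wise hill-climb on the run best using the
last ~10% of the evaluation budget. Every score evaluation is counted and
the per-run total never exceeds `ga_num_evals`. All randomness flows
through R's RNG (the compiled inner loop consumes the same stream), so a
seed fully determines a run.

Populations are seeded from the parent conformation at extension steps
(one exact copy plus Gaussian perturbations), and from uniform draws —
torsions on [−π, π), orientations uniform on the quaternion sphere, the
placed centroid uniform in the box — at the first step. Whether the
original protocol re-samples rigid-body DoFs globally or near the parent at
extension steps is not documented; the package keeps rigid-body DoFs active
at every step with parent-seeded initialisation and full-range mutation,
and records this as a package choice.

## Kinematics conventions

* Torsion genome values are *deltas* from the reference (input) geometry:
  the identity genome reproduces the input coordinates exactly, and a newly
  added bond "initialised at reference geometry" is simply delta 0.
* A positive delta increases the measured (IUPAC-signed) dihedral about the
  bond; rotations propagate in rank order from the root, so ancestors move
  descendants rigidly.
* The rigid-body rotation acts about the fragment's reference centroid; the
  translation then displaces that centroid, and `randomize_conformation()`
  samples the placed centroid uniformly inside the box.
* Bond lengths, angles, and unlisted dihedrals are invariant by
  construction; a property test holds them to 1e-6 Å over random genomes.

## Synthetic fixtures and what the tests show

`make_chain_ligand(n)` builds an all-trans heavy-atom chain (1.54 Å bonds,
109.47° angles) with exactly `n` rotatable bonds; with `polar_head = TRUE`
the first two heavy atoms are a hydroxyl-like oxygen and an N–H, giving one
terminus four donor/acceptor contributions. Carbons are united atoms (no
hydrogens), which keeps fixtures small without affecting rotatability.

`make_planted_complex()` plants a random full-ligand pose (rejection-sampled
at least 1 Å inside the box) and builds an analytic funnel: per-atom
harmonic wells `k‖x_i − p_i‖²` (default `k = 0.5` kcal/(mol·Å²)), optionally
roughened by the nonnegative ripple `amp · (1 − cos(2π d_i / period))`.
Both terms vanish exactly at the planted pose, so it is the *provable*
global minimum — the property that makes recovery tests unambiguous, and
the reason a harmonic funnel is used instead of a physics-like field (a
12-6 grid built from point receptors cannot carry that guarantee, so the
planted-complex generator supports the funnel only; grid fields are
exercised directly in the scoring tests).

The recovery tests run the full protocol on a 9-torsion chain in a 24 Å box
at 20000 evaluations per run and ask for the planted pose within 1.5 Å
heavy-atom RMSD in at least 8 of 10 seeds. The restraint-efficacy
comparison runs on the *rough* funnel (`amp = 2` kcal/mol, period 1.5 Å):
on the smooth funnel both arms converge to the planted pose and the
comparison is vacuous, whereas competing ripple minima make the selection
bias of the restraint observable. Problem sizes throughout the tests
(9–14 torsions, 300–20000 evaluations per run) are chosen so the whole
suite exercises every pathway at desk scale; they are smaller than the
budgets one would use in production (the published default is 250000
evaluations per sub-docking).

What passing these tests does *not* show: that the simplified force field
ranks real protein–ligand poses correctly, that real ligands' ring systems
and conjugation are handled (rings are rigid here; no protonation or
tautomer handling), or that a receptor's flexibility is accounted for. The
fixtures probe the search machinery, bookkeeping, and selection logic — the
protocol — under a landscape whose answer is known.

## Degenerate inputs and edge rules

* Rigid ligands (0 rotatable bonds) produce a single-node tree, a
  single-step schedule, and a pool of `initial_runs` conformations.
* Pools smaller than `select_k` are returned whole; reports on small pools
  emit fewer entries (never fewer than min(pool, 3) and never more than 6),
  with any overlap between the lowest-score and cluster-representative
  sections flagged as duplicates rather than hidden.
* Clustering is greedy leader clustering visited in ascending total score —
  a pose joins the first cluster whose representative (its lowest-scoring
  member, by construction) lies within the cutoff, default 2.0 Å, the
  conventional "very accurate" docking threshold; report annotation marks
  poses within 4.0 Å of a reference as acceptably accurate.
* RMSD uses identity atom correspondence over heavy atoms with no
  superposition (poses share the receptor frame); no symmetry correction is
  applied.
* mol2 files without a charge column load with a warning and zero charges
  (electrostatics then contributes nothing); PDB alternate locations
  resolve to the highest-occupancy copy; receptor donor capability is
  approximated at the heavy atom (N donor+acceptor, O/S acceptor) because
  deposited structures usually lack hydrogens.

## Limitations

The scoring field is a stand-in: absolute energies are not comparable to
any published force field, and no claim is made about ranking accuracy on
real complexes. Receptor flexibility, ring conformer sampling, protonation
and tautomers are out of scope. Wall-clock performance claims are
hardware-dependent and deliberately untested; determinism and budget
accounting are tested instead.
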