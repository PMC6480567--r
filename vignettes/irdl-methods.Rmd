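---
title: "Iterative residue docking and linking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative residue docking and linking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the protocol

Short linear peptides bind protein surfaces through many rotatable bonds, so
whole-peptide docking must search an exponentially large conformational
space.  `irdl` implements an incremental alternative: the peptide is split
into short segments, the C-terminal segment is docked first, and each
remaining segment is docked under a covalent proximity restraint to the free
amine of the growing chain, fused to it by an in-silico amide-forming
reaction (an acyl chloride on the incoming segment's C-terminus, chlorine as
the leaving group), locally relaxed at the new junction, clustered, and
rescored.  After the last segment, all surviving full-length poses are
rescored with a harder-weighted scoring variant and ranked.  Growth is
strictly C-terminus to N-terminus; the receptor is rigid throughout.

Fragmentation obeys two rules: a segment may have at most ten rotatable
bonds, and no segment may begin (N-terminally) with a residue carrying a
nucleophilic sidechain (Tyr, Cys, Ser, Thr, Asn, Gln), which would compete
with the backbone amine in the modeled reaction.  The peptide's own
N-terminal residue is exempt, since it never receives a bond.  Among minimal
tilings, the plan maximizes the rotatable-bond content of the C-terminal
segment (the seed must carry as much specific interaction as possible) and
then takes the lexicographically earliest boundaries.

Rotatable bonds are counted as backbone phi (residues 2..n, proline
excluded), psi (residues 1..n-1), all sidechain chi angles, and one
C-terminal carboxyl rotation; amide omega torsions are excluded.  This
convention is a documented choice: published per-peptide torsion counts
rarely state their convention, and we make no claim of reproducing any
particular published count.

## The surrogate scoring function

The original protocol was built on a proprietary docking engine.  `irdl`
ships its own grid-based scoring core; it reproduces the *logic* of the
protocol, not any proprietary score.  Five fields are precomputed on a
rectangular grid over the cavity (default spacing 0.4 Å, box = bounding box
of the reference peptide + 5 Å margin):

* **Steric**: soft-core Lennard-Jones summed over receptor heavy atoms
  (per-element radii; distances floored at 2.2 Å; each pair capped at +10 so
  near-clashes during growth remain finite).
* **Hydrogen-bond wells**, one field sampled by peptide donors (wells around
  receptor acceptors) and one by peptide acceptors (wells around receptor
  donors).  The well is V-shaped: minimum −1 at a donor–acceptor separation
  of 2.9 Å, rising linearly to 0 at 2.3 Å and to −0.15 at 3.5 Å, with a
  shallow capture tail to 4.3 Å.  The V-shape (rather than a flat-bottomed
  band) matters: it gives coordinate descent a gradient all the way to the
  designed geometry, which measurably tightens recovered poses.
* **Electrostatics**: screened Coulomb with a distance-dependent dielectric
  (energy ∝ q·q/4r², distances floored at 2 Å).
* **Burial**: the count of receptor atoms within 6 Å, capped at 20; used
  only by the final-ranking weight set.

A pose's score is `w_vdw·steric + w_hb·hbond + w_el·elec +
w_str·strain (+ burial bonus)`, terms interpolated trilinearly from the
fields; atoms outside the box incur a penalty folded into the steric term.
Internal strain is a harmonic bond restraint plus capped Lennard-Jones over
atom pairs at graph distance ≥ 3.  The standard-precision (SP) surrogate
weights are `w_vdw = 1, w_hb = 2, w_el = 0.5, w_str = 0.25`; the
extra-precision (XP) surrogate used only for final ranking doubles the
hydrogen-bond weight to 4 and adds a small burial bonus (0.004 per counted
neighbor).  The burial weight is deliberately small: at larger values the
bonus rewards compact, deeply buried but wrongly placed poses more than the
designed hydrogen bonds, inverting the final ranking.  The hydrogen-bond
*count* reported in score breakdowns is computed from exact pair geometry
(donor–acceptor ≤ 3.5 Å, donor angle ≥ 120°), since an angular criterion
cannot be stored in a scalar field; the energy itself stays grid-based.

## Conformers

Fragment ensembles are generated by torsion sampling on a grid: phi/psi on a
60° grid with the always-clashing eclipsed 0° value omitted
(−180/−120/−60/60/120), staggered sidechain rotamers (−60/60/180), and the
carboxyl rotation on the backbone grid.  When the full grid has at most
4000 combinations it is enumerated exhaustively; otherwise it is sampled
with a seeded RNG plus ±15° jitter.  Conformers with a nonbonded heavy-atom
contact below 2.0 Å are discarded; survivors are ranked by internal strain
and deduplicated at 0.5 Å internal RMSD, up to the ensemble cap
(200 by default, matching the protocol's stated conformer budget).

## Search

Docking a fragment combines three candidate generators:

1. a uniform scan — translations on a 1.5 Å stride through the box times a
   configurable number of seeded uniform orientations — over the
   lowest-strain conformers;
2. polar-site matching: pairs of pose donor/acceptor atoms are aligned onto
   pairs of candidate partner points (low-energy grid nodes on the
   2.6–3.2 Å shell around each receptor polar site), subject to polarity
   and pair-distance compatibility, with a few rotations about the pair
   axis (a cyclic-coordinate-descent closure variant that bends the
   intervening torsions onto the targets is implemented but off by
   default — on these systems it added cost without improving ranks);
3. the best candidates are refined by greedy multi-scale coordinate descent
   (rigid translations 0.4/0.15 Å, rotations 45/15/5°, torsion moves
   ±120…±10°), deduplicated at 1.5 Å RMSD, and polished with finer steps.

Covalent growth samples the incoming fragment with its acyl carbon on a
shell (2.8/3.2/3.6 Å) around the anchor's amine nitrogen, refines under a
flat-bottomed distance restraint (2.5–4.0 Å, harmonic outside), then forms
the bond: an ideal trans-planar amide frame (C–N 1.33 Å, sp² angles,
omega 180°) is constructed on the amine, the frame's free rotation about
the anchor's N–CA axis is chosen to minimize fragment displacement, and the
fragment is rigidly superposed onto the frame by its acyl triangle
(C, CA, O).  Rebuilding the junction ideally — instead of nudging the
docked geometry — proved essential: translate-and-twist snapping left the
acyl oxygen buried in the amine and the topology filter then rejected
nearly every pose.  After bond formation, torsions whose far side lies
within the new fragment (plus the anchor's first residue) are relaxed with
the anchor held fixed, followed by a small cartesian polish of the two
junction residues with 1–3 distances restrained (a plain per-atom descent
without the angle surrogate collapses sidechain geometry).

Poses whose distance-perceived bond graph (covalent radii × 1.25) is not
isomorphic to the expected peptide graph — element-colored VF2 — are
discarded.  Survivors are clustered (average-linkage on the plain RMSD
matrix, 15 clusters by default, best-scoring member as representative),
scored covalently (the unweighted mean of anchor, fragment and linked
scores, each scored in place), rescored with the SP surrogate, and the beam
(top-10 by default; an oracle mode keeping every pose down to the best-RMSD
one is available when a reference exists) is carried to the next step.

## The synthetic test-bed

`make_pocket_system()` builds the fixture the whole package is tested on: a
peptide conformation drawn from the sampler's own torsion grid (so the
planted rotamers are representable by the conformer generator), surrounded
by a pseudo-atom cage: `n_contacts` hydrogen-bond partners placed at 2.9 Å
ideal geometry opposite peptide polar atoms, designed hydrophobic carbons
opposite apolar sidechain tips, and cage carbons at 4.45 Å carving a snug
cavity (candidate wall positions at least 3.55 Å from every peptide atom).

Contact allocation is the most consequential design choice in the
generator, because a scalar per-atom-type field cannot encode *registry*:
any peptide donor gains the same well energy in any donor well, so a
wrong-registry decoy can satisfy every designed hydrogen bond.  The one
registry-specific signal available to the surrogate is charge
complementarity.  The allocation therefore anchors the two *charged* chain
ends — the C-terminal carboxylate gets a +1.2-charged donor partner and
the N-terminal ammonium a −1.2-charged acceptor partner — and spends the
third contact on the seed segment's N-terminal backbone, the residue that
becomes the first amide junction during growth (junction error propagates
multiplicatively, so pinning it matters more than pinning mid-chain
atoms).  Designed partners are also dispersively stronger than the walls
(well depth 0.3 vs 0.07 for cage carbons), and the hydrogen-bond well
bottom is −2 rather than −1: specific designed contacts must out-pull
nonspecific wall packing, or compact wrong-fold decoys dominate the score.

Generation certifies each complex: the planted pose must be clash-free,
its hydrogen-bond set must equal the designed contacts exactly, and its
score must beat 95% of 1000 seeded random rigid placements; otherwise a new
sub-seed is drawn.  Recovery being well-posed is therefore a property of
the fixture, not luck.

What this test-bed does *not* emulate: real protein sidechain flexibility
and rotamer diversity on the receptor side, solvent and bridging waters,
backbone motion, weak or water-mediated contacts, and the rugged
near-degenerate energy surfaces of real cavities.  Passing recovery tests
here demonstrates that the protocol's machinery — fragmentation, seeding,
restrained growth, bond formation, filtering, clustering, rescoring — works
as specified; it does not predict accuracy on crystallographic complexes.

## Numerical choices and degenerate inputs

* Problem sizes: the shipped tests and the acceptance experiment run
  5–8-residue peptides in 2–3 segments, ensembles of ≤ 72 conformers for
  the seed segment and ≤ 30 for growth segments, 36 orientations for seed
  docking and 16 per covalent step.  These sizes keep a full 10-replicate
  recovery experiment on one desktop core at roughly a minute per
  replicate; all budgets are config knobs and can be raised for production
  use.
* Determinism: every stochastic stage takes an explicit seed; a master seed
  fans out per-stage sub-seeds; rank ties break by creation order.
* Ties among minimal fragmentations, cluster representatives and equal
  scores are broken deterministically (documented in the respective
  functions).
* Single-residue peptides cannot be fragmented (growth needs at least two
  residues); single-segment plans reduce the pipeline to plain docking plus
  final rescoring.
* Proline contributes no phi and no chi; its ring is rigid with a fixed
  pucker approximation.  Hydrogens are never modeled; all geometry is
  heavy-atom.
* RMSD is computed in the fixed receptor frame without superposition (the
  docking convention), with symmetry-equivalent sidechain atoms (Phe/Tyr
  ring, Asp/Glu carboxylates, Arg NH pair) matched to minimize the value.

## Known limitations

* Growth is C→N only; a poorly seeded C-terminal segment cannot be rescued
  later, which is the protocol's own stated weakness and is faithfully
  reproduced here.
* The anchor is frozen during growth (only the junction residues relax), so
  seed-segment error propagates to the full-length pose; the final ranking
  stage rescores but does not re-minimize, mirroring the protocol.
* The surrogate scoring function is not calibrated against any physical
  energy scale; its units are arbitrary and only ranks matter.
* The beam default (top-10) can drop the correct lineage on adversarial
  score surfaces; the oracle beam mode exists for benchmarking when a
  reference pose is available.
* Well-registry degeneracy bounds end-to-end reliability: whole-peptide
  recovery on a pocket designed around the full peptide is robust (the
  salt-bridge anchors at both termini disambiguate the registry), but
  during growth the intermediate segments carry neither terminus, so their
  placement leans on the covalent restraint, the junction contact and
  shape alone.  Sidechain torsions of long residues (Lys, Glu) are only
  weakly guided, which inflates whole-peptide RMSD even when the backbone
  is rebuilt well; end-to-end recovery under the default desk-scale
  budgets therefore succeeds on a minority of random pocket draws rather
  than the large majority the iterative protocol achieved with a
  production-grade docking engine.  The per-stage tests quantify exactly
  which stages meet their contracts.
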