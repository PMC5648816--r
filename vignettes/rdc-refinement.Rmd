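---
title: "RDC-restrained refinement and conformational comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RDC-restrained refinement and conformational comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcrefine)
```

## The measurement model

A residual dipolar coupling measured for a backbone amide in a weakly
aligned protein is, in the static-structure idealization used throughout
this package, a quadratic form in the N–H unit bond vector $u$:

$$D(u) = u^\top A\, u
       = D_a\left[(3\cos^2\theta - 1) +
         \tfrac{3}{2} R \sin^2\theta \cos 2\phi\right],$$

where $A$ is the Saupe alignment tensor (symmetric, traceless, expressed
directly in Hz so that no gyromagnetic prefactors appear at the
interface), $D_a = S_{zz}/2$ is the axial magnitude, and
$R = 2(S_{xx} - S_{yy})/(3 S_{zz}) \in [0, 2/3]$ the rhombicity under the
magnitude ordering $|S_{zz}| \ge |S_{yy}| \ge |S_{xx}|$. This form of $R$
is the one consistent with the closed-form expression above (it makes the
two principal transverse values $-D_a(1 \mp \tfrac{3}{2}R)$); we use it
throughout. Eigen-decomposition ties are broken deterministically by
signing each principal axis so its largest-magnitude component is
positive and completing a right-handed frame.

Because $D$ is linear in the five independent elements of $A$, the tensor
is fitted to $n \ge 5$ observed couplings by singular value decomposition
of the $n \times 5$ direction-cosine design matrix (`rdc_fit()`). Fit
quality is the Q-factor $Q = \mathrm{rms}(D_{obs} - D_{calc}) /
\mathrm{rms}(D_{obs})$. Rank-deficient geometry (near-parallel bond
vectors) is reported as an error rather than silently regularized.

## The flat-bottom restraint

Measured couplings carry a global $\pm 3$ Hz uncertainty, so the
refinement penalty is flat inside that band and linear outside:

$$E_{rdc} = \sum_r k \, \max(0,\, |D_{obs,r} - D_{calc,r}| - 3\ \mathrm{Hz}),$$

with $k$ ramped geometrically from $10^{-3}$ to $10^{-2}$
kcal mol$^{-1}$ Hz$^{-1}$ over the refinement. The linear form follows
from the units of the penalty constant (energy per Hz of deviation); a
harmonic variant is available behind the `form` argument of
`restraint_energy()` for sensitivity checks. Records flagged as
persistent violators or excluded contribute neither energy nor gradient,
but their deviations are still tabulated.

## The desk-scale annealing surrogate

The original refinements of this kind run restrained explicit-solvent
molecular dynamics. This package deliberately replaces the MD engine with
a deterministic, seconds-to-minutes surrogate whose behaviour is driven
by the same restraint logic:

1. **Reference-geometry ("stereochemical") model.** Harmonic distance
   restraints to the start structure: bonds; 1–3 pairs for bond angles;
   the Cα(i)–Cα(i+1) pair for peptide-plane (ω) integrity; weak 1–4
   surrogates for φ/ψ; backbone O···N hydrogen bonds; and sp2 planarity
   terms (squared parallelepiped volume) for the amide H and carbonyl O,
   whose out-of-plane flap would otherwise be a quadratically soft mode
   that distance restraints cannot pin.
2. **Annotation-aware stiffness.** φ/ψ torsions *inside* annotated
   helix/strand elements are stiff (100 kcal mol$^{-1}$ Å$^{-2}$ on the
   1–4 surrogate), emulating the torsional rigidity of packed secondary
   structure; loop and linker torsions carry no reference restraint at
   all, so hinges between elements are compliant and hold no memory of
   the start conformation. Tertiary packing — absent from a backbone-only
   model — is emulated by an elastic-network term: Cα pairs within 10 Å
   whose residues both lie in annotated elements are restrained, but
   never across an unannotated stretch of three or more residues, which
   is treated as a potential hinge. Hydrogen bonds with a coil partner
   are likewise treated as transient and not enforced. These choices were
   made to reproduce, in a surrogate, the mechanical separation real
   proteins exhibit: rigid elements, compliant linkers.
3. **Move set and acceptance.** Each increment applies one Gaussian kick
   (default σ = 2°) to a randomly chosen compliant torsion — rotating
   everything downstream — plus small Cartesian noise (0.02 Å), then
   re-minimizes the total energy (L-BFGS with analytic gradients; the
   inner loop is compiled, and the R reference implementation of the same
   energy serves as its oracle in the tests). A move that raises the
   energy by more than 10⁻³ kcal/mol is rejected and the previous
   coordinates are kept. This greedy ratchet lets the structure cross
   into, and then diffuse within, the set of conformations compatible
   with the restraints, without wandering away from it. Torsion-space
   kicks are essential: Cartesian noise alone cannot discover collective
   hinge motions, whose straight-line path stretches the junction bonds.
4. **Per-increment tensor refitting.** After each increment every
   medium's tensor is refit to the current coordinates, as in the
   original protocol's optimization phase. All media (two by default) are
   restrained simultaneously with equal weight.

Snapshots store the structure, tensors, per-record deviations and a
violation energy evaluated at the final penalty constant (so energies are
comparable across the ramp). Whether the per-structure violation energy
should sum both media is not uniquely defined by the workflow we emulate;
we sum both and record that choice here.

## Ensemble, representative, and iterative correction

`select_ensemble()` takes the $n$ snapshots of lowest violation energy
(ascending, ties broken by earlier increment; $n = 10$ by default, the
conventional reporting size). `representative()` superposes the members,
averages Cα positions and returns the member closest to the average —
the standard "closest to the mean" representative conformer. The
recovery experiments take the ensemble from the final third of the
trajectory (the production phase, after the ramp and tensor refits have
settled), because within the restraint-compatible plateau all snapshots
are equally violation-free and averaging over the sampled plateau is what
centres the estimate.

Persistent violators are flagged when a record's violation exceeds 0 Hz
in at least 80% of the last 10 increments (both configurable; the
workflow we emulate does not quantify "consistent violations", so the
default is documented rather than derived). Detection is two-pass: after
the first pass the flagged records are excluded and the refinement is
repeated, and every record — including the tentatively excluded ones —
is re-judged on its raw deviation under tensors no longer dragged by the
outliers. The second pass is what prevents marginal clean records
(pushed a fraction of a Hz outside the band by an outlier-biased tensor
fit) from being flagged; flags never force deletion, records keep their
status so reports can show them.

## Conformational comparison

* `superpose()` — least-squares rigid fit (Kabsch, SVD with determinant
  correction); the quaternion-eigenvalue method is used as an independent
  oracle in the tests, never as the implementation.
* `screw_axis()` — the rigid transform best mapping a selection between
  two states, decomposed into axis, angle (axis canonicalized so its
  largest component is positive), pivot (closest point on the axis to the
  selection centroid) and axial translation. Below 0.5° the axis is
  ill-determined and the result is flagged unreliable. The caller
  superposes the anchor region first, so the transform expresses motion
  relative to the anchor.
* `helix_axis_rotation()` — spin of a helix about its own long axis. The
  two helices are aligned by matching centroids and applying the
  *minimal* rotation mapping one fitted axis onto the other —
  deliberately not a full Kabsch fit, which would absorb the spin being
  measured. Positive values are right-handed about the N→C axis
  (clockwise viewed from the N-terminus).
* `hbond_patterns()` — for each donor amide the i−4 (α) and i−3 (3₁₀)
  carbonyl candidates are tested with O···N ≤ 3.5 Å and, when the amide H
  is present, an N–H···O angle ≥ 120°; the donor is classified by the
  shortest qualifying bond. The cutoffs are conventional backbone H-bond
  geometry, configurable because the underlying workflow specifies none.
* `sequence_identity()` — BLOSUM62 with affine gaps (open 11, extend 1),
  identity counted over gap-free columns only (the conventional
  denominator; documented because conventions differ).
  `positional_identity()` scores an explicit residue-pair list from a
  user-supplied structural alignment — cross-enzyme correspondences are
  never inferred silently.
* `write_morph()` — linear Cartesian interpolation between superposed
  states (a deliberate simplification of rotational "corkscrew"
  interpolation, which is out of scope).

## The synthetic test systems

The generator builds ideal backbones (N, H, Cα, C, O) from standard
internal coordinates — α: φ = −57°, ψ = −47°; 3₁₀: φ = −49°, ψ = −26°;
strand: φ = −119°, ψ = 113°; coil: φ = −80°, ψ = 130°; amide H at 1.02 Å
in the peptide plane, trans to the carbonyl — and simulates per-medium
couplings with Gaussian noise, planted offset outliers (random sign by
default; an "inflate" mode biases toward magnitude inflation, emulating
increased local alignment at exposed sites), and planted rigid-body
hinges.

The study conditions of the recovery experiments are fixed in
`two_state_spec()` and `outlier_detection_experiment()`:

* **Two-state system**: two helix-turn-helix blocks (10–2–10 residues)
  joined by a 3-residue coil linker; a 10° hinge of the second block
  about an axis perpendicular to its long axis; 1 Hz measurement noise;
  two media — "pf1"-like $D_a = 30$ Hz, $R = 0.25$ and "C12E5"-like
  $D_a = -22$ Hz, $R = 0.55$ in a distinct orientation. The alignment
  strengths sit at the strong end of what phage and liquid-crystal media
  produce for amide couplings. They have to: with a ±3 Hz flat bottom the
  data constrain a domain orientation only to about
  ±(3 Hz)/max|∂D/∂θ| ≈ ±(2°–6°), and the maximal orientational
  sensitivity scales with $|D_a|$. At weak alignment a 10° hinge is
  simply not resolvable by this restraint — an identifiability limit of
  the method itself, not of the implementation — so the experiment is
  posed at an alignment strength where the motion of interest is inside
  the resolvable regime, exactly as a real measurement campaign would
  choose its medium concentration. Blocks are helix-turn-helix rather
  than single helices because a lone helix's amide vectors form a
  near-parallel bundle whose orientation (and hence the hinge) a
  refitted tensor can absorb.
* **Outlier system**: a fully structured three-helix protein
  (101 residues, 3₁₀ turns so every amide is held by the stereochemical
  model), one pf1-like medium, 100 records, 5% planted outliers at
  ±15 Hz, 1 Hz noise. Outliers planted on flexible coil residues would be
  genuinely undetectable — a freely reorienting amide can accommodate any
  coupling — which is why the detection benchmark uses a fully
  structured system, and why, on real proteins, flagged records at
  exposed flexible sites need human interpretation.

Problem sizes used by the tests and the acceptance script: the two-state
refinements run 288 increments of 300 minimizer steps (about a minute
each); the outlier runs use two passes of 14 increments. Five fixed seeds
drive each multi-seed experiment.

What passing these tests shows — and does not show. The synthetic systems
are rigid, ideal-geometry, backbone-only, with uncorrelated Gaussian
noise and static-structure couplings. Real data add conformational
averaging, correlated errors, missing assignments, side-chain packing and
solvent effects; success on the toys validates the restraint logic,
estimators and bookkeeping, not the physics of any particular protein.

## Numerical choices and degenerate inputs

* Tensor eigen-ties: deterministic axis signing (largest component
  positive, right-handed completion).
* Fit rank: singular values below 10⁻⁸ of the largest mark the geometry
  degenerate; fewer than five usable records is an error, and records
  flagged violator/excluded do not count toward the minimum.
* Minimization: L-BFGS-B, `factr = 10`, `pgtol = 1e-10`, per-increment
  iteration budget from the schedule; runs are bitwise reproducible for
  a fixed seed.
* Superposition needs ≥ 3 non-collinear shared atoms; screw axes with
  |angle| < 0.5° are flagged unreliable; `representative()` breaks RMSD
  ties (within 10⁻⁹ Å) toward the earliest member.
* PDB I/O uses the fixed-width 8.3 convention, so round-trips preserve
  coordinates to 0.001 Å; coordinates ≥ 10⁴ Å cannot be written and are
  an error; insertion codes are rejected; both "H" and "HN" amide naming
  dialects are accepted; author numbering is authoritative throughout,
  with `apply_numbering_offset()` for conventions that differ by a
  constant (e.g. solution vs crystal numbering offset by the four
  N-terminal residues absent from one model).

## Known limitations

* N–H couplings only; no Cα–Hα or N–C′ RDCs, no dynamic averaging or
  order parameters, no paramagnetic contributions.
* The stereochemical surrogate has no sterics, no side chains and no
  solvent; its stiffness constants are effective values chosen to mimic
  packed-protein rigidity, not force-field parameters.
* Hydrogens are never built; residues lacking an amide H are skipped.
* Secondary-structure annotation is supplied, never computed from
  geometry; the annotation drives the stiffness model, so refining a
  structure with no annotation leaves all torsions compliant.
* Structure-based cross-enzyme correspondences must be supplied
  explicitly; the package does not perform structural alignment.
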