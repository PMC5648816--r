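# rdcrefine

Structure refinement and conformational comparison with residual dipolar
couplings (RDCs), for solution-NMR structural biologists studying
substrate- or ligand-dependent conformational change — the kind of
analysis used to compare substrate-free and substrate-bound conformers of
cytochrome P450 enzymes.

An RDC measured for a backbone amide reports the orientation of that N–H
bond vector relative to the molecular alignment tensor: for a unit vector
**u** and Saupe tensor **A** (symmetric, traceless, in Hz),

    D(u) = uᵀ A u
         = Da [ (3 cos²θ − 1) + (3/2) R sin²θ cos 2φ ]

with axial magnitude `Da = Szz/2`, rhombicity `R ∈ [0, 2/3]`, and (θ, φ)
the polar angles of **u** in the tensor's principal frame. The package

* fits **A** to measured couplings by SVD of the direction-cosine design
  matrix (`rdc_fit()`, a classed model object with `coef`, `predict`,
  `residuals`, `summary`, `plot` methods) and scores fits with Q-factors;
* refines structures under the flat-bottom RDC penalty
  `E = k · max(0, |ΔD| − 3 Hz)` (k ramped 0.001 → 0.01 kcal mol⁻¹ Hz⁻¹)
  with an incremental stochastic annealer: seeded torsion-space and
  Cartesian perturbations, gradient minimization against a
  reference-geometry model, per-increment tensor refitting, and greedy
  move acceptance (`soft_anneal()`);
* runs the iterative correction that flags persistently violating
  couplings (`detect_persistent_violators()`, `mark_violators()`), selects
  the lowest-violation-energy ensemble (`select_ensemble()`) and the
  representative conformer closest to the ensemble average
  (`representative()`);
* quantifies conformational differences: Kabsch superposition
  (`superpose()`), per-residue displacement profiles, screw-axis
  decomposition of domain motions (`screw_axis()`), helix-axis rotations
  (`helix_axis_rotation()`), α vs 3₁₀ backbone hydrogen-bond
  classification (`hbond_patterns()`), sequence and positional identity,
  and linear morph export;
* generates synthetic test systems with planted ground truth
  (`make_structure()`, `simulate_rdc_sets()`, `apply_hinge()`,
  `two_state_spec()`), so the whole pipeline is verifiable without any
  external data.

## Worked example

Fit the alignment tensor of a synthetic two-medium dataset and recover a
planted 10° domain rotation:

```r
library(rdcrefine)

spec  <- two_state_spec(seed = 1)          # two helix-turn-helix blocks
s0    <- make_structure(spec)              # 47-residue ideal backbone
moved <- apply_hinge(s0, spec$hinge$range, spec$hinge$axis, 10)
rdcs  <- simulate_rdc_sets(moved, spec)    # pf1-like + C12E5-like media

fit <- rdc_fit(rdcs$pf1, nh_vectors(moved))
fit
#> <rdc_fit> medium pf1: n = 46, Q = 0.0275, rms = 0.719 Hz
#>   Da = 30.237 Hz, R = 0.257

sx <- screw_axis(s0, moved, spec$hinge$range)
sx
#> <screw_axis> angle = -10.00 deg, axial translation = 0.00 A
#>   axis  = (0.267, 0.964, 0.000)
#>   pivot = (7.67, -10.89, -28.27) A
```

The Q-factor of 0.028 reflects the 1 Hz measurement noise on couplings
whose rms is ~26 Hz; the screw-axis decomposition recovers the planted
10° rotation and its axis exactly (the axis is canonicalized so its
largest component is positive, which here flips the reported sign). The full inverse problem — starting
from the *unmoved* structure and letting `soft_anneal()` find the hinge
from the couplings alone — is run by `hinge_recovery_experiment()`; with
the default schedule it recovers the planted angle to within ~1–3°.

Command-style entry points (`cmd_fit_tensor()`, `cmd_refine()`,
`cmd_compare()`, `cmd_make_fixtures()`) read a declarative YAML config
and write plain-text reports; `inst/cli/rdctool.R` wraps them for shell
use.

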