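---
title: "Restraint-based absolute binding free energies at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based absolute binding free energies at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfekit)
```

## The model

abfekit implements the computational core of restraint-based absolute
binding free energy (ABFE) workflows of the BAT2 family. The standard
binding free energy of a ligand L to a protein P is related to the
dissociation constant by

$$K_d = C^\circ \exp(\Delta G^\circ_{bind} / RT), \qquad C^\circ = 1\ \mathrm{M},$$

and, when several non-interconverting bound poses $i$ contribute,

$$\Delta G^\circ_{bind} = -RT \ln \sum_i e^{-\Delta G^\circ_i / RT},$$

so the lowest pose dominates. Rather than simulating binding directly, the
workflow transfers the ligand from the binding site to bulk solvent in the
presence of artificial restraints and adds the free energies of attaching
and releasing those restraints:

$$\Delta G^\circ_{bind} = -\big(\Delta G_{att} + \Delta G_{trans} +
\Delta G_{rel}\big),$$

with every contribution tabulated in the site-to-bulk direction and
identified by a letter code:

| letter | contribution | method |
|---|---|---|
| a, l, t | attach protein-conformational, ligand-conformational, ligand TR restraints (bound state) | MBAR |
| e, f | decouple ligand charges in site / recouple in bulk | MBAR or TI-GQ |
| v, w | decouple ligand Lennard-Jones in site / recouple in bulk | MBAR or TI-GQ |
| b | release ligand TR restraints to 1 M | analytic |
| c, r | release ligand-conformational / protein-conformational restraints | MBAR |
| m, n | merged attach-all / release-all (n folds the analytic b term in) | MBAR |

Two transfer routes are supported. The split route (double decoupling,
DDM) decouples the ligand in the complex box and recouples it in a separate
ligand box, using the ten letters a, l, t, e, f, v, w, b, c, r. The merged
route (simultaneous decoupling and recoupling, SDR) performs both
transformations in one box — which keeps the net charge constant, so it is
the route of choice for charged ligands — and attaches or releases all
restraints in a single set of windows, using only m, e, v, n. Short
protocols `tevb` (no conformational restraints) and `m*evbc` (ligand-only
conformational restraints) use the same machinery with fewer letters.
When both routes start from the same reference state, m should equal
a+l+t, n should equal b+c+r, SDR e should equal DD e+f and SDR v should
equal DD v+w; `consistency_report()` quantifies these closures.

### Restraints

Three restraint classes are built by `build_restraints()`:

* **TR (Boresch) restraints** tie the ligand's position and orientation to
  the protein through six coordinates defined on three protein anchors
  P1–P3 and three ligand anchors L1–L3: the distance $r = |P1{-}L1|$, the
  angles $\theta$ (P2-P1-L1) and $\Theta$ (P1-L1-L2), and the dihedrals
  $\phi$ (P3-P2-P1-L1), $\Phi$ (P2-P1-L1-L2) and $\Psi$ (P1-L1-L2-L3).
  This anchor-to-coordinate assignment is the standard Boresch
  construction; we validate it against the stiff-spring closed form rather
  than against any drawing.
* **Conformational restraints** are harmonic wells on dihedrals: every
  bonded heavy-atom quadruple of the ligand (one entry per distinct
  i-j-k-l path along bonds — "all dihedrals" is read as all distinct
  bonded quadruples, not one per rotatable bond, and the enumeration is
  checked against an exhaustive graph walk), and protein $\phi/\psi$
  backbone dihedrals within user-declared residue ranges.
* **COM restraints** pin the center of mass of the protein backbone (and
  of the bulk ligand copy in SDR boxes). They only maintain the reference
  frame and carry no free-energy component.

All restraints are harmonic, $u = \tfrac{1}{2} k (x - x_0)^2$, with the
AMBER force-constant convention: kcal mol⁻¹ Å⁻² for distances and
kcal mol⁻¹ rad⁻² for angles and dihedrals. Dihedral differences are
wrapped into (−180°, 180°] before squaring, so the energy is symmetric
about the reference across the periodic boundary.

### Anchor selection

Protein anchors are user-chosen backbone atoms; `validate_protein_anchors()`
checks the qualitative rules that prevent gimbal locking — mutual distances
of at least `min_dist` (default 5 Å) and a P1-P2-P3 angle at least
`angle_window` (default 25°) away from 0° and 180°. Ligand anchors are
selected automatically in the reference frame: L1 is the non-hydrogen
ligand atom closest to the center of a user-defined spherical search zone;
if no ligand atom lies inside the zone the pose is *unstable* — a defined
workflow outcome (`unstable_pose`, CLI exit code 2), not an error. L2 then
minimises |angle(P1,L1,L2) − 90°| among heavy atoms with an L1–L2 distance
inside a configurable window (default 2.5–5.0 Å; the workflow this package
follows leaves the value to its input file, and these bounds bracket two
to three bond lengths), and L3 repeats the rule with (L1, L2). Candidates
are restricted to heavy atoms (hydrogen anchors would be unstable), and
exact ties break to the smallest serial so selection is reproducible under
any iteration order. Selection commutes with rigid motions of the system
plus the matching motion of the zone center.

### The standard-state correction

Releasing the TR restraints into unrestrained bulk at 1 M is analytic.
With the separable harmonic potential the restrained configurational
integral factorises,

$$Z_{TR} = \int r^2 \sin\theta \sin\Theta\, e^{-u/RT}\,
dr\, d\theta\, d\Theta\, d\phi\, d\Phi\, d\Psi,$$

and the release free energy is
$\Delta G = -RT \ln (8\pi^2 V^\circ / Z_{TR})$ with
$V^\circ = 1/(C^\circ N_A) = 1660.5392\ \text{Å}^3$ and orientational
volume $8\pi^2$. `tr_release_free_energy()` evaluates each
one-dimensional factor by composite Gauss–Legendre quadrature with
interval doubling to a relative tolerance of 1e-6 (the r integral over
$[\max(0, r_0 - 10\sigma_r),\, r_0 + 10\sigma_r]$, angles over $(0,\pi)$,
dihedrals over a full period — which makes the result exactly independent
of the dihedral references). The `stiff_spring` method instead uses the
Boresch closed form
$Z_{TR} \approx r_0^2 \sin\theta_0 \sin\Theta_0 (2\pi RT)^3 (\prod k)^{-1/2}$,
valid when every well is narrow and the polar references are ≥ 5σ from
0°/180°. Quadrature is the default because it stays correct for loose
restraints; the two agree to well under 0.01 kcal/mol for typical force
constants, and an independent Monte-Carlo perturbation oracle
(`mc_release_oracle()`) cross-checks both. The sign convention is pinned
by the cycle arithmetic: releasing tight restraints into 1 M bulk is
favorable (negative), and the bundled reference components assemble to
the published binding free energies only with this convention.

### Estimators

* **MBAR** (`mbar()`): the dimensionless window free energies solve the
  self-consistent equations with $f_1 = 0$. We iterate the
  self-consistent map and switch adaptively to Newton steps (analytic
  gradient and Hessian of the MBAR objective) once the residual enters
  the Newton basin, stopping when the largest change drops below `tol`
  (default 1e-8, dimensionless); non-convergence after `max_iter` is an
  error carrying the last residual. A window-overlap matrix
  (`mbar_overlap()`) warns — it does not fail — when adjacent windows
  barely overlap.
* **BAR** (`bar()`): for two windows the equations reduce to one scalar
  self-consistency condition, solved independently by bracketed root
  finding; it agrees with two-state MBAR to solver tolerance and serves
  as the internal cross-check.
* **TI with Gaussian quadrature** (`ti_gq()`): $\Delta G = \sum_i w_i
  \langle \partial U/\partial \lambda \rangle_i$ over the n-point
  Gauss–Legendre nodes mapped to [0, 1] (`gq_schedule()`; each n fixes a
  unique node/weight set, exact for polynomial integrands of degree
  ≤ 2n−1).
* **Finite-difference derivatives** (`fd_dudl()`): engines that cannot
  emit $\partial U/\partial\lambda$ directly get it as
  $\delta G_{BAR}/\delta\lambda$ between two windows bracketing
  $\lambda_i$ at $\pm\delta\lambda/2$, with $\delta\lambda = 0.001$ by
  default.

Reduced potentials are dimensionless ($u = U/RT$); results are reported
in kcal/mol at the configured temperature (default 298.15 K, with
R = 1.987204259×10⁻³ kcal mol⁻¹ K⁻¹).

### Uncertainties

Block analysis is the single uncertainty route: a series is split into
`n_blocks` contiguous equal blocks (remainder dropped from the front, a
choice we document because only "block analysis" itself is standard), the
estimator is recomputed per block, and the uncertainty is the standard
deviation of block estimates divided by √n_blocks. For MBAR the estimator
is recomputed per block rather than propagating asymptotic covariances.
Replica spreads use the population (divisor-n) standard deviation — the
convention that reproduces the reference tables' printed spreads, where
the sample SD does not. Component uncertainties combine in quadrature
when a cycle is assembled. Displayed values round to one decimal, half
away from zero; stored values are never rounded.

## What the toy sampler emulates — and what it does not

Production ABFE runs sample windows with molecular dynamics at
microsecond-per-ligand scale. The built-in generator replaces MD with
Metropolis Monte-Carlo on one-dimensional quadratic potentials whose
partition functions are Gaussian integrals, so every leg has a closed-form
free energy: harmonic ladders (window k has its own well), λ-coupled
potentials (linear alchemical mixing between two wells), and λ-scaled
restraint fields on a base well. Chains use a 10% burn-in and a proposal
scaled to the window width, kept above 0.2 acceptance; identical seeds and
parameters give bit-identical tables. `toy_cycle()` builds a complete
merged or split cycle from such legs — with end states shared between the
two routes, so their analytic totals are identical and the merged-vs-split
closure can be tested synthetically — and takes the analytic TR release
from a fixed restraint measured on the generated toy complex. The toy
complex itself is a rigid 3-residue helical peptide fragment plus a
branched 8–15 heavy-atom ligand grown next to it, enough to exercise
anchor selection, dihedral enumeration and restraint measurement.

Passing these tests shows that the estimators, the standard-state
integral and the cycle bookkeeping are correct on distributions with
known answers. It says nothing about force fields, sampling convergence
of real ligands, water models, or finite-size electrostatics — none of
which this package attempts.

## Numerical and design choices

* Coordinates are Å throughout; serials are 1-based as in PDB; angle math
  is done in radians internally and reported in degrees.
* PDB reading keeps the first alternate-location conformer and ignores
  insertion codes with a warning; CONECT records populate bonds, and
  `perceive_bonds()` adds distance-based bonds from a bundled covalent
  radius table (tolerance 0.4 Å, the common heuristic).
* Superposition is a Kabsch least-squares fit over alpha-carbons matched
  by chain and residue number (a consistent numbering between mobile and
  reference is required); fewer than three pairs or a collinear selection
  is an error.
* Degenerate geometry (coincident consecutive anchors, collinear dihedral
  points) raises errors rather than returning NaN.
* Stochastic agreement checks use the three-combined-standard-error
  convention throughout, including the synthetic split-vs-merged closure:
  an agreement band of one combined SE is exceeded about a third of the
  time by any unbiased estimator, so it cannot serve as a test criterion.
* Test and example problem sizes — 10⁴ samples per window for estimator
  recovery, 1.5×10³ per window across five windows per toy-cycle leg,
  3×10⁴ Monte-Carlo steps per release-oracle coordinate — were chosen as
  the package's own desk-scale defaults: large enough that block
  uncertainties are a few hundredths of a kcal/mol, small enough to run
  anywhere.
* The merged `n` component folds the analytic TR release into its value,
  so merged schemes never add `b` separately; the short `tevb` and
  `m*evbc` schemes add `b` explicitly.
* The protein-restraint release (`r`) is pose-independent when the apo
  reference state is shared, so a ledger may reuse it across poses.

## Known limitations

* No engine execution: window samples come from an external engine's
  energy output or from the toy sampler; HREX, soft-core potentials and
  equilibration protocols are out of scope.
* Flat-bottom and distance-from-bound-configuration (DBC) restraints are
  not implemented; the analytic release covers harmonic TR restraints
  only, and diverges (by design, with an error) if any force constant is
  zero.
* Autocorrelation-based effective sample sizes are not estimated; block
  analysis is the only uncertainty route, and blocks shorter than the
  correlation time will understate uncertainties.
* Pose combination assumes non-interconverting poses.
* mmCIF input, hydrogen addition and sequence-independent structural
  alignment are not provided; inputs are PDB files with consistent
  numbering.
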