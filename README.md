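# abfekit

Desk-scale toolkit for the computational core of restraint-based
**absolute binding free energy (ABFE)** workflows in the style of the
BAT2 program family.

Estimating how strongly a small molecule binds a protein,
ΔG°_bind = RT ln (K_d / C°), is a routine need in structure-based drug
discovery. Alchemical ABFE workflows compute it by decoupling the ligand
from the binding site and recoupling it in bulk solvent while harmonic
restraints hold the ligand in place, then adding the analytic cost of
releasing those restraints to the 1 M standard state. The simulations
themselves run on GPU MD engines; everything around them — choosing
anchor atoms, building Boresch-style translational/rotational (TR)
restraints, turning per-window energies into free energies with rigorous
uncertainties, and assembling the letter-coded thermodynamic cycle — is
deterministic bookkeeping and numerics that deserves to be testable
without a cluster. abfekit implements exactly that layer, plus a
Metropolis Monte-Carlo toy sampler with closed-form free energies that
stands in for MD so the entire pipeline runs on a laptop.

At its core are:

* **Anchor selection** — L1 is the ligand heavy atom nearest the center
  of a spherical search zone (an empty zone is a defined "unstable pose"
  outcome); L2 and L3 minimize |angle − 90°| within a distance window;
  protein anchors P1–P3 are validated against distance/collinearity
  rules.
* **Restraints** — TR restraints on (r, θ, Θ, φ, Φ, Ψ), conformational
  restraints on every heavy-atom ligand dihedral and on protein φ/ψ
  ranges, COM tethers; all harmonic, AMBER unit conventions.
* **Estimators** — MBAR (self-consistent + Newton), BAR (independent
  root solve), TI with Gauss–Legendre quadrature
  (ΔG = Σᵢ wᵢ ⟨∂U/∂λ⟩ᵢ), finite-difference ∂U/∂λ from bracketing
  windows (δλ = 0.001), block-analysis uncertainties, replica statistics.
* **Standard state** — ΔG_release = −RT ln(8π² V° / Z_TR) with
  Z_TR = ∫ r² sinθ sinΘ e^(−u/RT) d⁶q, by adaptive Gauss–Legendre
  quadrature or the Boresch stiff-spring closed form, cross-checked by a
  Monte-Carlo oracle.
* **Cycle assembly** — the letter-coded component ledger (m, a, l, t, e,
  f, v, w, n, b, c, r), split/DDM vs merged/SDR schemes, the short
  `tevb` and `m*evbc` protocols, merged-vs-split consistency reports,
  Boltzmann pose combination, and Kd conversion.

Everything is tibble-first: results are tidy tables, fitted objects have
`tidy()`/`glance()` methods, and `autoplot()` draws the standard plots.

## Worked example

Assemble the merged/SDR cycle for one pose of the bundled BRD4(2)
bromodomain reference tables and check the merged-vs-split closure:

```r
library(abfekit)
library(purrr)

comp <- brd4_component_comparison()
rows <- subset(comp, pose == "pose 1" & scheme == "merged")
ledger <- component_ledger(pmap(list(rows$letter, rows$value, rows$uncertainty),
                                component))
assemble(ledger, "merged_sdr")
#> ABFE cycle (merged_sdr): dG_bind = -2.4 (1.3) kcal/mol, Kd = 0.0174 M

closure <- consistency_report(subset(comp, scheme == "merged"),
                              subset(comp, scheme == "split"))
head(closure, 4)
#> # A tibble: 4 × 5
#>   pose   pair       merged_value split_value discrepancy
#>   <chr>  <chr>             <dbl>       <dbl>       <dbl>
#> 1 pose 1 m vs a+l+t         28.2        29.3       1.10
#> 2 pose 1 n vs b+c+r        -37.3       -38.4       1.10
#> 3 pose 1 e vs e+f           -0.7        -0.5       0.2
#> 4 pose 1 v vs v+w           12.2        12.5       0.300
attr(closure, "max_discrepancy")
#> [1] 1.1
```

The components m = 28.2, e = −0.7, v = 12.2, n = −37.3 kcal/mol are
tabulated in the site→bulk direction; their negated sum is the binding
free energy −2.4 kcal/mol, the uncertainty is the quadrature combination
of the per-component block uncertainties, and Kd = exp(ΔG/RT) at 1 M
standard concentration. No merged component deviates from its split
counterpart by more than 1.1 kcal/mol.

Free energies from sampled windows work the same way on synthetic data
with a known answer — two harmonic windows with force constants k and 4k
have ΔG = (RT/2) ln 4 = 0.4107 kcal/mol:

```r
p <- toy_potential("harmonic_ladder", k = c(2, 8))
tab <- sample_windows(p, n_samples = 10000, seed = 1)
free_energy_estimate(tab, "mbar", n_blocks = 10)
#> # A tibble: 1 × 4
#>   value uncertainty method blocks
#>   <dbl>       <dbl> <chr>   <int>
#> 1 0.394     0.00737 MBAR       10
```

which agrees with the exact value within three block standard errors.
`toy_cycle()` runs a complete merged or split cycle on such potentials
and recovers its analytic binding free energy the same way.

A thin command-line wrapper with subcommands (`anchors`, `restraints`,
`release`, `estimate`, `assemble`, `check`, `toy`, `plan`) is installed
at `system.file("cli", "abfekit", package = "abfekit")`; exit code 2
marks an unstable pose.

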