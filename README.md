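# pmfkit

Umbrella sampling, WHAM, and dual-level free-energy surfaces for
covalent-inhibition studies, with the structural descriptor suite used
to rationalize them.

## What this is for

Mechanistic studies of covalent enzyme inhibitors — e.g. beta-lactone
warheads attacked by the catalytic threonine of the 20S proteasome beta5
subunit — characterize the chemistry with free-energy surfaces along
reaction coordinates (distances and antisymmetric distance
combinations), computed by umbrella sampling and recombined with the
weighted histogram analysis method (WHAM):

```
W(xi) = C - kT ln ∫ rho(r^N) delta(xi(r^N) - xi) dr^(N-1)
DeltaG‡ ≈ W(xi‡) - W(xi_R)
E = E_LL + S(Delta E_LL->HL)(xi1, xi2)      (dual-level spline correction)
```

pmfkit implements the full pipeline — grid scan → biased Langevin
sampling → 1D/2D WHAM → spline correction → maximum-probability path
tracing with perpendicular-coordinate integration → stitched, labelled
free-energy profiles — plus the geometric analyses that accompany such
studies: Buergi-Dunitz and Flippin-Lodge nucleophilic-attack angles,
geometric hydrogen-bond detection (3.0 Å / 135°), Kabsch-superposed
RMSD, ring-puckering dihedrals, Eisenberg hydrophobicity maps, and
per-residue Coulomb + Lennard-Jones interaction energies with a smooth
14.5–16 Å switching function.

A synthetic-surface module (analytic double wells, separable and coupled
2D surfaces, paired low-level/high-level forms, molecular fixtures with
prescribed geometry) stands in for the quantum-chemical engine, so every
estimator is testable against closed-form results.

## Worked example

Recover a 5 kcal/mol double-well barrier from 31 umbrella windows at the
conventional stiff force constant (2500 kJ·mol⁻¹·Å⁻² = 597.51
kcal·mol⁻¹·Å⁻², 310 K), and compare with direct Boltzmann inversion:

```r
library(pmfkit)

dw   <- make_double_well(h = 5, b = 1)          # barrier 5 kcal/mol, wells at ±1 Å
scan <- grid_scan(dw, list(c(-1.5, 1.5, 0.1)))  # 31 nodes
ws   <- build_windows(scan)                     # k = 597.51, T = 310 K
ws   <- sample_windows(ws, dw, stride = 5, seed = 1, n_samples = 20000)
pmf  <- wham(ws)                                # density tolerance 1e-3
pmf
#> <pmf_grid> 122 bins, T=310 K, max W=9.891 kcal/mol (WHAM converged in 641 iter)

activation_free_energy(pmf, reactant_region = c(-1.3, -0.7),
                       ts_region = c(-0.2, 0.2))
#> [1] 4.85642
activation_free_energy(reference_pmf(dw, pmf$breaks),
                       c(-1.3, -0.7), c(-0.2, 0.2))  # exact oracle
#> [1] 4.994111
```

The estimate sits within the 0.3 kcal/mol agreement the estimator is
held to.  Assembling a printed stationary-point profile and querying
barriers — the worked-example arithmetic for an irreversible covalent
inhibitor — looks like:

```r
prof <- assemble_profile(hbelc_profile_segments())
prof
#>   label    type     G
#> 1   E.I minimum   0.0
#> 2   TS1  saddle  24.9
#> 3  E-I2 minimum   1.9
#> 4   TS3  saddle  21.0
#> 5  E-PC minimum -15.6
barrier_query(prof, "E.I", "TS1")    # rate-limiting nucleophilic attack
#> [1] 24.9
barrier_query(prof, "E-PC", "E.I")   # reverse barrier: 24.9 - (-15.6)
#> [1] 40.5
```

A 40.5 kcal/mol reverse barrier from the product complex is what makes
the inhibition effectively irreversible.

A shell pipeline is available through the installed script
(`system.file("cli", "pmfkit", package = "pmfkit")`) with subcommands
`make-toy | scan | sample | wham | correct | path | profile | geometry |
interactions`; results go to files, logs to stderr, and identical seeds
give byte-identical outputs.

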