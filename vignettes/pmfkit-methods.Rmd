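---
title: "Free-energy surfaces for covalent inhibition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy surfaces for covalent inhibition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfkit)
```

## The problem

Covalent enzyme inhibition — here the archetype is a beta-lactone warhead
attacked by the catalytic threonine of the proteasome beta5 subunit — is
characterized computationally by free-energy surfaces along chemically
meaningful reaction coordinates: interatomic distances and antisymmetric
combinations of a breaking and a forming distance (proton transfer,
nucleophilic attack with ring opening).  The standard pipeline is

1. a **grid scan** of the energy surface along the chosen coordinates,
   which locates the minimum-energy path and supplies starting
   configurations;
2. **umbrella sampling**: biased simulations in overlapping windows with
   a stiff harmonic restraint on the coordinate;
3. **WHAM** (weighted histogram analysis method) to recombine the window
   histograms into a potential of mean force (PMF) `W(xi)`, in one or two
   dimensions;
4. a **maximum-probability path** traced across a 2D PMF with a 1D
   profile recovered by integrating over the perpendicular coordinate;
5. a **dual-level spline correction** adding interpolated high-level
   minus low-level energy differences to the cheaply sampled surface;
6. assembly of the per-step profiles into one labelled free-energy
   profile (Michaelis complex, transition states, intermediates, product
   complex), from which forward and reverse barriers are read.

pmfkit implements every stage plus the structural descriptors used to
rationalize such profiles (nucleophilic-attack angles, hydrogen bonds,
RMSD, ring puckering, per-residue interaction energies, hydrophobicity
maps).  The quantum-chemical engine that would normally supply energies
is replaced by **analytic surfaces with exactly known free energies**, so
every estimator can be validated against closed-form results.

## Models and conventions

Energies are kcal/mol, distances Angstrom, angles degrees, temperatures
Kelvin; `k_B` = 0.0019872041 kcal/mol/K and the default temperature is
310 K (body temperature, the usual choice for simulations of human
enzymes).  Inputs quoted in kJ (the conventional umbrella force constant
of 2500 kJ/mol/A^2) are converted at the boundary with 1 kcal = 4.184 kJ:
`kj_to_kcal(2500)` = 597.51 kcal/mol/A^2.  Dihedral signs follow the
IUPAC convention; because reported puckering values in the literature
are sign-convention dependent, comparisons should be made up to a global
sign.  The antisymmetric coordinate is ordered breaking-minus-forming so
reactant states sit at negative values.  All fixtures are gas-phase
point sets; there are no periodic boundary conditions anywhere.

### Synthetic surfaces

Four analytic forms stand in for the molecular energy function:
a harmonic well; the quartic double well `V(x) = h((x/b)^2 - 1)^2`
(minima at `x = ±b` with `V = 0`, barrier `h` at `x = 0`); a separable
2D surface (double well in x, harmonic or double well in y); and a
coupled 2D surface whose `c x^2 y^2` coupling vanishes to second order
at the origin, pinning the saddle exactly there.  These generators
define the study conditions for all sampling tests: `h = 5` kcal/mol
(a chemically realistic barrier an umbrella-sampling study must climb),
`b = 1` A, 31 windows spaced 0.1 A apart at the 597.51 kcal/mol/A^2
force constant, 310 K, 20,000 production samples per window.  What the
toys deliberately do *not* emulate: multidimensional orthogonal
relaxation, sampling along slow environmental degrees of freedom, and
anharmonic coupling between the reaction coordinate and a fluctuating
protein — so passing these tests demonstrates the correctness of the
estimators, not the convergence of any real QM/MM free-energy
calculation.

### Langevin sampler

Windows are sampled with a BAOAB-splitting Langevin integrator (compiled
kernel for the analytic forms, R fallback for arbitrary energy models),
unit mass, default friction 5 /ps and time step 0.01 ps in reduced
units.  BAOAB was chosen because its configurational sampling error is
small even at moderate `omega * dt`, which matters under a stiff bias
(`omega ≈ 25` at the default force constant).  Samples are retained
every 5 steps by default in the worked examples so that consecutive
samples are essentially decorrelated (the position relaxation time under
the stiff bias is a few steps).  The integrator draws from R's RNG, so a
seed fixes every trajectory bitwise; equilibration (default 5 time
units) is discarded by sample index, production is 20 time units unless
a sample count is given explicitly.

## WHAM: estimator choices

The self-consistent WHAM equations are iterated until the maximum
absolute change of the per-window normalization free energies, in kT,
drops below the density tolerance (default 1e-3) — the standard,
monotone, unit-consistent reading of a "density tolerance" convergence
criterion.  Non-convergence is an error that still carries the last
profile so it can be inspected.

**Binning.** The default bin width is half the window spacing, *capped
at 0.8 standard deviations of the stiffest bias*
(`sd = sqrt(kT/k)` ≈ 0.032 A at the defaults).  The cap matters: with
bins comparable to the bias width, evaluating the bias Boltzmann factor
at the bin center misrepresents the strongly varying bias inside a bin
and distorts the recovered barrier by a few tenths of a kcal/mol —
an effect we measured directly with exactly distributed (inverse-CDF)
window samples, i.e. independently of the integrator.  Explicit bin
counts or break vectors override the default.

**Coverage.** Empty bins are flagged `NA`, never interpolated.  The
disconnected-histogram check labels occupied bins (contiguous runs in
1D, 8-connected components in 2D) and fails when more than 1% of all
samples fall outside the dominant component.  The 1% mass rule, rather
than strict single-component occupancy, is needed because a well-sampled
2D histogram always has a few one-sample bins detached from the main
blob; genuinely non-overlapping windows put entire windows (several
percent of the mass) into separate components and are still rejected.

**Activation free energies** are plain PMF differences,
`max W` over the transition-state region minus `min W` over the reactant
region.  The Jacobian free-energy term associated with fixing the
coordinate at the reactant state is deliberately neglected — it is
ordinarily a small contribution — and the package mirrors that
approximation rather than estimating the term.

**The oracle.** `reference_pmf()` integrates `exp(-V/kT)` over every bin
by quadrature.  It shares no code path with WHAM and is the independent
reference all sampling tests compare against; agreement is required
within 0.3 kcal/mol under the study conditions above.

## Path tracing on 2D surfaces

The maximum-probability route between two minima is the minimum-cost
path on the 8-connected graph of covered bins with node cost
`exp(+W/kT)` (edge weight: mean endpoint cost times step length),
computed by Dijkstra's algorithm via igraph.  Cost ties are broken
deterministically by adding a vanishing lexicographic term (1e-12
relative), so symmetric two-channel surfaces always return the same
route.  No further off-lattice refinement is applied: on a binned PMF a
local descent cannot leave the bin lattice, and the profile below
already meets its accuracy target.

The 1D profile along the path integrates `exp(-W/kT)` over the
direction perpendicular to the local path tangent — five bins each side,
bilinear interpolation, trapezoidal weights — and is min-referenced.  On
a separable double-well surface this reduces to the 1D PMF up to a
constant, which is how the tracer is validated.

## Dual-level correction

Corrections are built from HL − LL energy differences on a rectilinear
node grid: a natural cubic spline in 1D (≥ 4 nodes), a tensor-product
natural bicubic in 2D (≥ 4×4 nodes).  "Spline" is under-specified in
common usage; cubic is the minimal smooth standard and reproduces the
polynomial test surfaces exactly.  Corrections are applied to grid/bin
energies — mirroring per-window single-point corrections — never to
individual samples, and evaluation outside the node hull is a hard
error: silent extrapolation is the classic failure mode of dual-level
schemes, so there is no extrapolation policy at all.

## Structural descriptors

* **Attack geometry**: Buergi-Dunitz angle `alpha_BD` = Nu-C-O angle
  (ideal ≈ 105 deg); Flippin-Lodge angle `alpha_FL` = `asin(v · w)`
  with `v` the unit C→Nu vector and `w` spanning the electrophile plane
  perpendicular to the C=O axis (ideal 0 deg).  The plane normal comes
  from an SVD best-fit of the three substituent directions through the
  carbon, oriented so positive `alpha_FL` tips toward the first
  substituent — the sign is a package convention; published values are
  typically unsigned, so comparisons use `|alpha_FL|`.  The fixture
  generator `make_attack_fixture()` is the exact inverse of the
  measurement (round-trip < 1e-6 over random draws), with combinations
  `sin(alpha_BD) < |sin(alpha_FL)|` rejected as geometrically
  unreachable.
* **Hydrogen bonds**: donor···acceptor ≤ 3.0 A and donor-H···acceptor
  ≥ 135 deg, both boundaries inclusive (enforced with a 1e-9
  floating-point guard).  Donors are N/O with a hydrogen within 1.25 A;
  donors without one are skipped with a warning.  N and O accept by
  default; all of this is configurable.
* **RMSD** with optional Kabsch superposition (SVD with reflection
  guard), cross-checked against an independent reference implementation
  in the test suite.
* **Ring puckering** of four-membered rings is the signed improper
  torsion of the four ring atoms; a sign change along a step is a
  puckering inversion.
* **Eisenberg consensus hydrophobicity** is embedded as a constant
  20-residue table (normalized scale; e.g. LYS −1.50, THR −0.05,
  ILE +1.38); unknown residue names are an explicit error.

## Per-residue interaction energies

`E_int = E_elec + E_vdW` between a ligand selection and each environment
residue: point-charge Coulomb (constant 332.0636 kcal·A/mol/e^2, no
distance-dependent dielectric) plus 12-6 Lennard-Jones in Rmin form
with Lorentz-Berthelot combination, both multiplied by a CHARMM-style
cubic switching function that is 1 below 14.5 A, 0 above 16 A and
C1-continuous at both bounds (the functional form is the standard
choice for a stated 14.5–16 A switching range).  Ligand and residue
selections are disjoint by construction, so no exclusion bookkeeping is
needed; per-residue terms partition the total exactly.  Frame averages
report mean ± sample SD.  Note these are molecular-mechanics
point-charge energies; published per-residue values computed with a
QM/MM Hamiltonian for the ligand will differ systematically, which is
why printed interaction energies are treated as context, not as
reproduction targets.

## Problem sizes and numerical tolerances

The worked examples and the acceptance script use: 31 windows × 20,000
samples for the 1D barrier (recovered within 0.3 kcal/mol of Boltzmann
inversion); 217 windows × 10,000 samples for the 2D surface (path
barrier within 0.3 kcal/mol, saddle within one bin of the origin); the
same 1D setup at 10,000 samples plus a 17-node cubic correction for the
dual-level barrier (within 0.35 kcal/mol — sampling plus spline budget);
200 random draws for geometry round trips (< 1e-6).  These sizes were
chosen as the smallest at which the stochastic estimates sit comfortably
inside their tolerances across seeds, and they complete in seconds.

## Known limitations

* Bootstrap error bars for WHAM are not implemented (stub-free v1
  scope), nor replica exchange or cross-temperature reweighting; mixed
  temperature window sets are rejected outright.
* The 2D WHAM assumes windows biased on both coordinates.
* XYZ input carries no topology; residue-level analyses need PDB input.
* No Cremer-Pople puckering for 5+ membered rings, no SASA, no
  secondary structure.
* The toy energy models are 1–2 dimensional by design; the package's
  estimators are validated there, not on molecular Hamiltonians.
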