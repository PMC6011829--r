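---
title: "Methods: binding statistics, continuum energetics and activation thermochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding statistics, continuum energetics and activation thermochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostguest)
```

This vignette explains the models behind `hostguest`, the defaults and
their units, the numerical choices, and what the synthetic-data tests do
and do not establish about real data.

## The scientific setting

A macrocyclic host (cyclodextrin-like: a truncated cone with a narrow rim
of primary hydroxyls and a wide rim of secondary hydroxyls) can catalyze a
bimolecular reaction between two guests.  Two mechanisms compete as
explanations: specific hydrogen bonds between host hydroxyls and the
substrate, or entropy reduction by co-localizing and orienting both
reactants in the cavity (pre-organization).  Distinguishing them requires
exactly the three layers this package implements: how often H-bonds
actually form along a trajectory, what holds the complex together
energetically, and how the activation free energy splits into ΔH‡ and
−TΔS‡.

## Trajectory statistics

**H-bond criterion.** A triple X–H···Y counts as bonded when
d(H···Y) < 2.2 Å *and* the deviation from linearity 180° − ∠(X–H···Y) is
< 90°, both strict.  The angular rule is deliberately interpreted as a
bound on the *complement* of the bond angle (i.e. ∠(X–H···Y) > 90°): the
alternative reading (angle itself < 90°) would accept folded, non-physical
geometries.  Occurrence percentage is frame-level — a frame with several
simultaneous bonds counts once — with per-triple percentages reported
alongside, because "fraction of frames containing an H-bond" is the
quantity that decides whether bonding is persistent.

**Depth metrics.** The host frame is the unweighted geometric center of the
host's heavy atoms (no mass weighting, hydrogens excluded) plus the unit
axis from the narrow-rim centroid to the wide-rim centroid.  A selection's
depth is the *signed* projection of its centroid displacement onto that
axis, positive toward the wide rim.  Signed projections (rather than 3-D
center–center distances) are the only reading under which a slightly
negative mean depth is meaningful — it places a moiety just below the
cavity center.  Which atoms constitute each moiety is configuration-driven;
the statistic is agnostic.

**RMSD and residence.** Each frame is superposed on a reference by Kabsch
least squares over the host selection (uniform weights; the determinant
correction restricts to proper rotations, so mirror solutions are never
returned; at least 3 alignment atoms are required or the rotation is
underdetermined).  Guest RMSD over its own selection then classifies
frames as bound (RMSD < 5 Å, strict) — the threshold separates the bound
cluster from excursions in typical host–guest runs.  Residence analysis
reports occupancy (bound frames / total) and the durations of maximal
contiguous bound runs.

**Frame spacing.** Trajectory files carry no time axis, and analysis
strides in published workflows are often ambiguous (trajectories written
every 2 ps, analyzed every 20 ps, normalized over 3000 frames of a 300-ns
run, which implies 100-ps spacing).  The package therefore treats
`frame_interval` as explicit caller-supplied metadata and never infers it;
the synthetic generator defaults to 100 ps so that 3000 frames span 300 ns.

## MM-PB/SA interaction enthalpy

The decomposition is ΔH = ΔE_Coulomb + ΔE_PB + ΔE_NP + ΔE_VDW under the
single-trajectory convention: receptor and ligand geometries are cut from
the complex frame without relaxation, so valence terms cancel identically
and only inter-set MM terms plus solvation differences remain.

* Coulomb: pairwise `k q_i q_j / r_ij`, k = 332.0637 kcal·Å/(mol·e²) (the
  Amber convention, matching the force-field lineage such analyses use).
* Lennard-Jones: 12-6 with Lorentz–Berthelot combination; no cutoff —
  systems are finite, exactness is cheaper than bookkeeping.
* PB: ΔE_PB = PB(complex) − PB(receptor) − PB(ligand), each solved on the
  same spacing.
* Nonpolar: γ·ΔSASA with γ = 0.0072 kcal/(mol·Å²), b = 0, probe 1.4 Å
  (Amber-style defaults).

Dielectrics default to ε_in = 1, ε_out = 80 at zero ionic strength.
Published MM-PB/SA tables rarely state these knobs, so absolute component
values are generally *not* reproducible across implementations; the
package's self-checks therefore verify internal sums of bundled reference
tables rather than re-deriving their components.

### The finite-difference PB solver

The linearized equation ∇·(ε∇φ) − ε_s κ̄²φ = −4πkρ is discretized on a
regular cubic grid (spacing default 0.5 Å, padding 8 Å, grid centered on
the solute so symmetric systems sit on nodes):

* charges spread to the 8 surrounding nodes trilinearly;
* the dielectric is a sharp two-valued map from the union of atom spheres
  at their PB radii, with face values formed by **harmonic averaging along
  each grid edge** (the edge is sampled at 5 interior points; the
  inside-solute fraction f gives ε_face = 1/(f/ε_in + (1−f)/ε_out)).
  Without this smoothing the discrete cavity volume jumps with grid
  alignment and convergence under refinement is erratic; with it the
  Born-ion error decreases monotonically over spacings 1.0 → 0.5 → 0.25 Å
  and is ~0.2 % at 0.25 Å;
* Dirichlet boundary values are Debye–Hückel monopole sums in the exterior
  dielectric;
* the solve is red–black successive over-relaxation (ω = 2/(1 + π/N),
  compiled kernel), converged when the relative residual falls below 1e-6;
  exceeding the iteration cap is an error that reports the residual, never
  a silent partial answer.

The solvation energy is ½Σqφ evaluated at the atom positions (trilinear
interpolation) in the solvated map *minus the identical quantity with the
solute dielectric everywhere on the same grid*, so the divergent discrete
self-energy cancels exactly.  Uniform dielectric or all-zero charges
short-circuit to exactly 0.

### SASA

Shrake–Rupley with a deterministic Fibonacci sphere (default 960 points
per atom): per-atom accessible area is the exposed fraction of the
probe-inflated sphere.  A point exactly on the shared boundary of two
spheres is owned by the lower-index atom, so two exactly coincident
identical spheres contribute the surface once (the union area), a
degenerate case a naive strict/non-strict test would count twice or zero
times.  Doubling the point count changes 10-atom cluster totals by < 0.5 %.

## RRHO thermochemistry

For each optimized structure (electronic energy, masses, coordinates,
harmonic frequencies, symmetry number σ, multiplicity):

* translation: Sackur–Tetrode at the stated pressure;
* rotation: classical rigid rotor; linear vs nonlinear is detected from
  the principal moments of inertia; σ enters as −R ln σ;
* vibration: product over real positive modes, bottom-of-well reference
  with ZPE kept separate; a transition state's single imaginary mode is
  excluded from all thermal functions (standard TS-theory convention);
* electronic: q = multiplicity.

H = E_elec + ZPE + E_thermal + RT and G = H − TS hold to 1e-9 kcal/mol by
construction.  The standard state is 1 atm and T = 298.15 K (the Gaussian
convention; published "298 K" tables are produced by that toolchain), both
overridable via `thermo_conditions()`.

**Activation decomposition.** ΔG‡ = G(TS) − ΣG(reactants), with the
entropic part reported as −TΔS‡ = ΔG‡ − ΔH‡.  The reactant reference may
be a single pre-reactive supermolecule or a sum of separated species; the
choice materially changes ΔH‡ (a near-zero uncatalyzed ΔH‡ is only
interpretable under a complex reference), so both are supported and the
mode used is recorded in the result.  No frequency scaling and no
quasi-harmonic treatment of low modes is applied — consistent with the
toolchain being emulated, and a known source of entropy underestimation.

## The synthetic-data generator

The generator emulates the *statistical structure* of a long explicit-
solvent run, not its physics: a rigid truncated-cone host (two rings of
pseudo-atoms plus wide-rim donor hydrogens), a maleimide-like primary
guest whose whole-body depth is drawn per frame from
Normal(depth_mean, depth_sd), exact H-bond geometry imposed with
probability `p_hbond` (1.9 Å, 10° deviation — inside the criterion by
construction, so detection tests decouple from jitter), and a second guest
hopping between bound and ≥ 10 Å-displaced states as a two-state Markov
chain with per-frame hop probabilities 1 − exp(−k·Δt), started from its
stationary distribution.  Host and bound second-guest atoms carry 0.1 Å
Gaussian jitter.  Identical parameters and seed give bit-identical
trajectories.

Defaults form one coherent study arm — the plain-host system: 3000 frames
at 100 ps (300 ns), p_hbond = 0.041, depth 1.44 ± 0.70 Å with moiety
offsets −1.47/+1.91 Å, k_on = 0.0176 ns⁻¹, k_off = 0.2 ns⁻¹ (stationary
occupancy 8.1 %, mean dwell 5 ns).  The methylated-host arm uses the same
generator at p_hbond = 0.0067, depth 2.05 ± 0.73 Å, k_on = 0.0268 ns⁻¹,
k_off = 0.05 ns⁻¹ (occupancy 34.9 %, mean dwell 20 ns, so maxima of tens
of ns occur in a 300-ns run).

One discretization property is worth stating: with hop probabilities
1 − exp(−k·Δt) the chain's exact stationary law is
p_on/(p_on + p_off), which equals the rate ratio k_on/(k_on + k_off) only
when k·Δt is small.  At the default rates the two agree to four decimals;
convergence tests use rates that stay in that regime.

**What passing tests show — and don't.** Recovery tests establish that the
estimators are unbiased and correctly normalized on data whose ground
truth is known, and that detection is exact at criterion-satisfying
geometry.  They do not validate force fields, sampling convergence of real
MD, solvent models, or the rigid-template assumption (a real guest's
moieties fluctuate internally, so their depth standard deviations differ
from the whole-guest value; the rigid template cannot reproduce that).

## Degenerate inputs and tie-breaks

* Criterion comparisons are strict: d = 2.2 Å exactly, RMSD = 5 Å exactly,
  both fall outside.
* Coincident donor X,H coordinates are an error (undefined angle), as are
  coincident atoms across Coulomb/LJ sets (r = 0).
* Empty selections, non-positive frame intervals/thresholds, parameter
  tables with duplicated or missing indices, and transition-state flags
  inconsistent with the count of negative frequencies are all errors, not
  warnings.
* A declared minimum with fewer than its expected real mode count
  (3N−6, or 3N−5 if linear) is rejected.

## Problem sizes

The test suite and acceptance script run at desk scale by choice: Born-ion
grids up to 81³ nodes (0.25 Å), 100-atom brute-force oracle systems,
trajectories of 50–3000 frames with 20 replicate seeds, and a 40000-frame
run for the stationary-occupancy check.  These sizes give 3-standard-error
recovery bands of a few tenths of a percentage point for occupancies and
a few hundredths of an Å for depth means.

## Known limitations

* The PB dielectric map has no reentrant (molecular-surface) cavity; at
  desk scale the union-of-spheres map with edge smoothing is accurate to
  well under 1 % on the Born ion but will differ from molecular-surface
  codes on clefts between atoms.
* Nonlinear PB, salt-dependent decomposition terms and explicit-solvent
  energetics are out of scope.
* Thermochemistry covers a single conformer per species; configurational
  entropy over conformer ensembles is not included.
* The synthetic host is rigid and its parameters are generic pseudo-atom
  values, not a force field.
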