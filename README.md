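# hostguest

Analysis toolkit for host–guest inclusion complexes of the cyclodextrin
type, built around the question of *why* a macrocyclic host catalyzes a
bimolecular reaction: is it hydrogen bonding to the substrate, or entropy
reduction by pre-organizing the two reactants inside the cavity?

The package implements the three quantitative layers such a study needs,
for anyone analyzing trajectories and frequency calculations of host–guest
systems:

1. **Trajectory statistics** — hydrogen-bond detection with the geometric
   criterion d(H···Y) < 2.2 Å and 180° − ∠(X–H···Y) < 90°, and the
   occurrence percentage over frames; signed depth metrics d = (r⃗_guest −
   r⃗_host) · û along the cavity axis û (narrow rim → wide rim); guest RMSD
   after Kabsch superposition of the host; bound-state classification
   (RMSD < 5 Å) and residence analysis (occupancy %, dwell times).
2. **Interaction energetics (MM-PB/SA)** — the interaction enthalpy
   ΔH = ΔE_Coulomb + ΔE_PB + ΔE_NP + ΔE_VDW with pairwise Coulomb
   (k = 332.0637 kcal·Å/(mol·e²)) and 12-6 Lennard-Jones terms, a
   finite-difference linearized Poisson–Boltzmann solver (ε_in = 1,
   ε_out = 80, harmonic edge-averaged sharp dielectric, Debye–Hückel
   boundary), and a Shrake–Rupley SASA nonpolar term ΔE_NP = γ·ΔSASA with
   γ = 0.0072 kcal/(mol·Å²).
3. **Activation thermochemistry (RRHO)** — S, H, G from translational,
   rotational, vibrational and electronic partition functions of optimized
   structures (Sackur–Tetrode, classical rigid rotor with symmetry number,
   harmonic oscillator with ZPE separated, imaginary TS mode excluded), and
   the activation decomposition ΔG‡ = ΔH‡ + (−TΔS‡).

Because raw MD/QM outputs for such studies are rarely deposited, a
first-class **synthetic-data module** generates a toy truncated-cone host,
stochastic binding trajectories with known ground truth (H-bond
probability, imposed depth law, two-state residence kinetics), and
thermochemistry/electrostatics fixtures with closed-form answers — so every
stage is testable at desk scale.

## Worked example

```r
library(hostguest)

sim <- simulate_binding_trajectory(
  params = synthetic_trajectory_params(n_frames = 3000, seed = 1))
sel <- sim$selections

hbond_occupancy(sim$trajectory, sel$donors, sel$acceptors)
#> <hbond_occupancy> 4.20% of 3000 frames contain an H-bond

depth_profile(sim$trajectory, sel$host, sel$rim_narrow, sel$rim_wide,
              list(d1 = sel$guest_whole, d2 = sel$guest_cyclohexyl,
                   d3 = sel$guest_imide))
#> # A tibble: 3 × 4
#>   selection     mean    sd n_frames
#> 1 d1         1.46    0.703     3000
#> 2 d2        -0.00431 0.713     3000
#> 3 d3         3.36    0.695     3000

rmsd <- guest_rmsd(sim$trajectory, sim$reference, sel$host, sel$guest_second)
residence_summary(classify_bound(rmsd, threshold = 5))
#> <residence_summary> occupancy 13.7% (412/3000 frames), max dwell 21.90 ns, 6 dwells
```

The 4.20 % H-bond occurrence recovers the imposed per-frame probability
0.041; the depth means (1.46, −0.004, 3.36 Å) recover the imposed depth law
(whole guest 1.44 ± 0.70 Å, moiety offsets −1.47/+1.91 Å): positive values
sit toward the wide rim, the near-zero d2 means the cyclohexyl-like moiety
sits at the cavity center.  The residence summary comes from the RMSD < 5 Å
rule; this seed's realization spends 13.7 % of 300 ns bound.

Activation thermochemistry with a constructed reactant/TS pair whose
entropy gap is known in closed form:

```r
fx <- make_thermo_fixture("ts_pair", removed_mode = 50)
activation_decomposition(thermo_result(fx$reactant), thermo_result(fx$ts))
#> <activation_decomposition> dG = 0.84, dH = -0.60, -TdS = 1.44 kcal/mol (supermolecule reference)
```

The −TΔS‡ of 1.44 kcal/mol equals (to 1e-15) the closed-form entropy of the
50 cm⁻¹ mode deleted at the TS — the mechanism by which freezing
low-frequency motion raises an entropic barrier.

Bundled reference decomposition tables are checked for internal consistency
with `run_reference_selfcheck()`, and `run_full_analysis(analysis_config())`
runs the whole pipeline end to end, writing CSV reports and a run log.
A thin command-line wrapper lives at `inst/scripts/hostguest-cli.R`
(`synth`, `traj-report`, `energy-report`, `thermo-report`, `full`,
`selfcheck`).

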