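---
title: "Entropic tensions in crowded membranes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic tensions in crowded membranes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdgate)
```

## The physical picture

Membrane proteins occupy a large fraction of the bilayer plane — protein:lipid
mass ratios of 1–2.5 with transmembrane domains making up about half the
protein mass translate into area fractions of roughly 30–55%
(`mass_ratio_to_area_fraction()`), and imaging and labelling studies on
different membranes report anywhere from ~20% to near close packing. At such
coverage, a channel that enlarges its in-plane footprint upon opening steals
free area from its neighbors. The neighbors' lost translational entropy acts
back on the channel as an effective tension opposing opening.

`crowdgate` formalizes this with a hard-disk model: every crowding protein is
a disk of some radius r in the membrane plane, interacting with everything
else only by exclusion. Two quantities summarize the effect:

- a **surface tension** σ_c (kBT/nm²), conjugate to the channel's area change
  ΔA = π(R_o² − R_c²);
- a **line tension** τ_c (kBT/nm), conjugate to the circumference change
  ΔC = 2π(R_o − R_c). It exists because each crowder's center of mass is
  excluded from an annulus of width r around the channel, and the annulus
  grows with the circumference.

## Levels of theory

**Ideal gas.** If crowders ignore each other, a single crowder's entropy in a
patch of side L around a channel of radius R is
S/k_B = ln[((L−2r)² − π(R+r)²)/b²] (`ig_single_crowder_entropy()`), where b is
a lattice discretization length that cancels from every difference. Expanding
in the small protein-to-patch area ratio and summing over crowders gives
σ_c = c and τ_c = c⟨r⟩ (`ig_tensions()`), with c the areal number density.
The line tension vanishes with the crowder size, as it must.

**Scaled-particle theory.** At physiological coverage the exclusion zones of
different crowders overlap and the ideal-gas count underestimates the effect.
Scaled-particle theory (SPT) for hard-disk mixtures provides a closed-form
equation of state; in terms of c, φ = cπ⟨r²⟩ and the relative radius variance
δ² = (⟨r²⟩ − ⟨r⟩²)/⟨r⟩²:

σ_c = c[ 1/(1−φ) + φ/((1+δ²)(1−φ)²) ],  τ_c = c⟨r⟩/(1−φ).

For uniform crowders (δ² = 0) σ_c reduces to c/(1−φ)², so at φ = 0.5 the
surface and line tensions are exactly 4 and 2 times their ideal-gas values.
Size variability *lowers* σ_c at fixed c and φ: with δ² in the range implied
by transmembrane-helix censuses (~0.15–0.25) the correction is modest, which
is why the worked example sets δ² = 0. The SPT excess chemical potential of a
test disk, μ_ex(R) = −ln(1−φ) + 2πc⟨r⟩R/(1−φ) + πR²σ_c
(`spt_excess_chemical_potential()`), ties all of this to an exact
probabilistic statement: exp(−μ_ex) is the probability that a randomly placed
test disk overlaps nothing.

## Ensembles

The free energy a channel pays to open depends on what is held fixed:

- **Constant area** (`gating_energy_constant_area()`): the membrane patch
  cannot grow, so opening consumes free area directly,
  ΔG_crowd = σ_cΔA + τ_cΔC.
- **Constant tension** (`gating_energy_constant_tension()`): a loading device
  holds tension σ; the total area adjusts so that the lipid area is
  conserved (lipids are treated as incompressible — membranes are far stiffer
  than any energy scale here, so areal strain is neglected). The crowders'
  surface-tension term then cancels between the channel's own area change and
  the compensating total-area change, leaving ΔG_crowd = τ_cΔC plus the
  loading-device relaxation −σΔA. This is the appropriate ensemble for
  patch-clamp experiments on MscL.

The two ensembles should be read as limiting cases: real proteins with bulky
extramembranous domains can break the cancellation that removes σ_c at
constant tension.

`constant_tension_decomposition_check()` verifies the constant-tension result
non-perturbatively: it evaluates an explicit three-step route (remove the
closed channel at its finite-area state, change the total area at fixed
crowder numbers via the integrated equation of state
`spt_area_change_free_energy()`, insert the open channel) and compares it
with the closed form. The two agree up to a finite-size residual of order
1/A₀; at A₀ = 10⁶ nm² (a bacterium-scale membrane) the residual for the
worked example is below 0.01 kBT. The channel's own ideal translational term,
also O(1/A₀), is excluded from the route so that the residual measures purely
the crowding bookkeeping.

## Gating observables

With all non-crowding contributions (protein internal energetics,
lipid–protein interactions) lumped into a bare gating tension σ*₀, the
two-state open probability at applied tension σ is
P_open = 1/(1 + exp[(σ*₀ − σ)ΔA + τ_cΔC]) (`open_probability()`). Crowding
shifts the midpoint by exactly Δσ* = τ_cΔC/ΔA, which equals
`gating_tension_shift()` of the constant-tension result — an algebraic
identity the tests check to machine precision. For the worked MscL example
(R: 2.4 → 3.5 nm, uniform 1 nm crowders, φ = 0.5) the shifts are 0.05
(ideal gas) and 0.11 kBT/nm² (SPT), against measured gating tensions of
0.3–1.3 kBT/nm² for isolated MscL.

## From proteomes to disk mixtures

Quantitative size distributions of membrane proteins are scarce; the number
of transmembrane (TM) helices n is used as a proxy, with each helix assigned
an in-plane footprint a (default 1.4 nm², configurable everywhere it
appears), so r = √(na/π) (`radius_from_tm_helices()`). Proteins with no
predicted TM helix have no in-plane footprint and are rejected. A convenient
consequence of r ∝ √n is δ² = ⟨n⟩/⟨√n⟩² − 1, independent of the footprint
(`delta2_from_tm_distribution()`). Only the first two radius moments enter
any formula, so mixtures are kept as finite discrete distributions; a
continuous radius distribution should be quadrature-sampled by the caller.
Aggregation of subunits into complexes, and TM-helix prediction itself, are
out of scope.

## The Monte Carlo oracle

Because every SPT expression is an approximation, the package carries an
independent numerical oracle: Metropolis sampling of hard disks in a periodic
square box (minimum-image convention) with Widom test-particle insertion
(`mc_validate_spt()`). Periodic boundaries are used deliberately — they
remove the wall effects that the analytic expansions neglect; the hard-wall
single-crowder geometry is covered separately by the exact/grid pair
`exact_free_area_one_crowder()` / `grid_free_area()`.

Numerical choices: box side 40⟨r⟩ (≈50–150 disks at φ = 0.1–0.3, large
enough that a test disk up to R = ⟨r⟩ respects the minimum-image bound with
wide margin); random-sequential-insertion start (feasible well below the RSA
saturation density; requests above packing 0.7 are rejected); 300
equilibration sweeps during which the maximum displacement is tuned toward
~40% acceptance in blocks of 25 sweeps and then frozen; 1000 sampling sweeps
with a configuration stored every 20; 2000 trial insertions per stored
sample. These sizes put the statistical error on μ_ex near 1% at the densest
state probed, well inside the 5% band within which SPT is checked, and keep a
full validation sweep to well under a minute per area fraction on one CPU.
All stochastic entry points take explicit integer seeds and are
bit-reproducible for a fixed seed.

At φ ≤ 0.3–0.4 SPT for disks is near-exact and the Widom estimates agree to
about 1–2%; close to the packing limit (φ ≳ 0.6) SPT is known to degrade, so
the mixture constructor warns above φ = 0.78 and the oracle is not asserted
there. The test-particle identity exp(−μ_ex(0)) = 1 − φ is exact and is
checked against the realized finite-box area fraction.

## What the synthetic fixtures do and do not emulate

`generate_fixture()` produces seeded crowder descriptions: uniform and
two-species mixtures, and a TM-helix census whose abundance decays roughly
geometrically over 1–30 helices — dominated by few-helix proteins and
spanning about an order of magnitude, the qualitative shape seen in
proteome surveys (its default δ² lands in the empirically reported range).
The fixtures emulate the *distributional* structure used by the model (radii
and weights); they do not emulate protein complex formation, soft or
anisotropic interactions, membrane-mediated elastic forces, or spatial
correlations beyond hard-disk exclusion, so passing tests validate the
statistical mechanics of the disk model, not those additional features of
real membranes.

## Degenerate inputs and conventions

- Energies are in kBT throughout (β ≡ 1); temperature never appears
  explicitly. Tensions are positive magnitudes opposing opening; internally
  the equation of state uses the dF = −σdA sign convention.
- φ ≥ 1 is rejected outright; c = 0 gives exact zeros everywhere; ΔA = 0
  makes the gating-tension shift undefined (error, not NaN).
- Closing transitions (R_o < R_c) are allowed; all crowding energies flip
  sign antisymmetrically.
- Printed tables round energies to one decimal (kBT) and tension shifts to
  two decimals (kBT/nm²); full precision is always retained in the unrounded
  columns.

## Known limitations

Hard disks only (no SPT for non-circular particles, no 3D SPT for
cytoplasmic crowding of channels like MscS); strictly two-state gating with
no sub-conductance states; no bilayer deformation energetics or
hydrophobic-mismatch interactions; the loading device is ideal (constant
tension, no compliance). The Monte Carlo oracle implements only single-disk
displacement moves and Widom insertion — no constant-tension moves, cluster
moves, or event-chain algorithms.
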