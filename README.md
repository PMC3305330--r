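# crowdgate

Biological membranes are so densely packed with proteins (20% to well over
50% of the bilayer area) that excluded-area interactions alone can reshape
the free-energy landscape of any membrane protein whose conformational change
alters its in-plane footprint. `crowdgate` models the crowding proteins as a
two-dimensional mixture of hard disks and computes the **entropic surface
tension** σ_c (kBT/nm²) and **entropic line tension** τ_c (kBT/nm) they exert
on a disk-shaped channel that switches radius upon gating — the
mechanosensitive channel MscL (radius 2.4 nm closed, 3.5 nm open) is the
built-in case study. It is intended for biophysicists estimating how crowding
shifts gating energies and gating tensions measurable in patch-clamp
experiments.

## Model

For a crowder mixture with areal density c, mean radius ⟨r⟩, area fraction
φ = cπ⟨r²⟩ and relative radius variance δ² = (⟨r²⟩−⟨r⟩²)/⟨r⟩², two levels of
theory are implemented (energies in kBT, lengths in nm):

| model | σ_c (kBT/nm²) | τ_c (kBT/nm) |
|---|---|---|
| ideal gas | c | c⟨r⟩ |
| scaled-particle theory (SPT) | c·[1/(1−φ) + φ/((1+δ²)(1−φ)²)] | c⟨r⟩/(1−φ) |

The crowding contribution to the gating free energy of a channel whose area
and circumference change by ΔA = π(R_o²−R_c²) and ΔC = 2π(R_o−R_c) is

- **constant membrane area:** ΔG_crowd = σ_c ΔA + τ_c ΔC
- **constant applied tension σ:** ΔG_crowd = τ_c ΔC (the surface-tension term
  cancels when the total area adjusts to conserve lipid area), plus loading
  work −σΔA.

The corresponding shift in gating tension is Δσ* = ΔG_crowd/ΔA, and the
two-state open probability is P_open(σ) = 1/(1 + exp[(σ*₀−σ)ΔA + τ_cΔC]).
An independent hard-disk Metropolis Monte Carlo oracle with Widom
test-particle insertion validates the SPT excess chemical potential
μ_ex(R) = −ln(1−φ) + 2πc⟨r⟩R/(1−φ) + πR²σ_c.

## Worked example

```r
library(crowdgate)
channel  <- channel_geometry(closed_radius = 2.4, open_radius = 3.5) # MscL
crowders <- uniform_mixture(r = 1, area_fraction = 0.5)              # c = 0.5/pi

gating_energy_constant_area(channel, crowders, model = "spt")
#> Gating free-energy change (constant_area ensemble, spt model)
#>   crowding:               15.180 kBT
#>   loading device:          0.000 kBT
#>   total:                  15.180 kBT
#>   gating-tension shift:   0.7445 kBT/nm^2

cmd_gating(default_run_config())[, c(1, 2, 5, 6)]
#>           ensemble     model delta_G_kT_rounded delta_sigma_rounded
#> 1    constant_area ideal_gas                4.3                0.21
#> 2 constant_tension ideal_gas                1.1                0.05
#> 3    constant_area       spt               15.2                0.74
#> 4 constant_tension       spt                2.2                0.11
```

Reading: at half coverage by 1 nm crowders, interactions between crowders
(SPT vs ideal gas) roughly triple the crowding penalty on opening; in the
constant-tension ensemble relevant to MscL the penalty is 2.2 kBT,
equivalent to a 0.11 kBT/nm² increase in gating tension — a sizable fraction
of the 0.3–1.3 kBT/nm² gating tensions measured for isolated MscL.

A command-line entry point wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "crowdgate.R", package = "crowdgate"))') gating
```

Subcommands: `tensions`, `gating`, `popen-curve`, `mixture-stats`,
`mc-validate`, `make-fixture`; `--config` accepts a YAML/JSON run
configuration (see `inst/extdata/mscl_example.yaml`).

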