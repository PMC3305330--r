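# Worked MscL example: channel radius 2.4 -> 3.5 nm on opening, crowded by
# uniform 1 nm hard disks covering half the membrane area (no size
# variability). Energies in kBT, lengths in nm, tensions in kBT/nm^2.
channel:
  closed_radius: 2.4
  open_radius: 3.5
crowders:
  radii: [1.0]
  abundances: [1.0]
  area_fraction: 0.5
ensemble: constant_tension
model: spt
gating_tension: 1.0
tension_grid:
  from: 0.0
  to: 2.0
  n: 201
seed: 1
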