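# Demo configuration for the full synthetic pipeline:
# toy landscape -> WT-MetaD -> FES/convergence/error -> state split ->
# per-state energy networks -> per-state pocket maps -> overlaps.
# Units: kcal/mol, Angstrom, degrees, Kelvin.
seed: 1
temperature: 303.15
potential:
  template: triple_well_2d
metad:
  steps_per_walker: 8000
states:
  stride: 2
receptor:
  n_residues: 48
  two_chains: false
ensembles:
  n_frames: 30
  noise_sd: 0.1
  cavity_fraction:
    basin1: 0.0
    basin2: 0.4
    basin3: 1.0
pen:
  cutoff: 11
  threshold: 0.1
pockets:
  spacing: 1.0
  probe: 1.4
  burial_radius: 10
  burial_min: 6
  iso: 0.2
  min_voxels: 5
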