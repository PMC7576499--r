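# Demonstration run: native aquaglyceroporin strain vs its ar/R double
# mutant, three-temperature Arrhenius design, toy structural and
# conservation stages.
seed: 7
mode: exponential
noise_sd: 0.01
geometry:
  v0_over_a: 8.3e-5
  vw: 18.07
  active_fraction: 1.0
osmolarity:
  osm_in: 1.4
  osm_out: 2.1
temperatures: [15.0, 25.0, 35.0]
replicates: 2
reference_temperature: 23.0
reference_replicates: 3
duration: 60.0
dt: 0.02
strains:
  - name: native
    pf: 6.78e-4
    pgly: 24.5e-8
    ea_water: 9.80
    ea_glycerol: 6.93
  - name: double_mutant
    pf: 5.12e-4
    pgly: 3.58e-8
    ea_water: 11.37
    ea_glycerol: 14.37
pore:
  enabled: true
  z_step: 0.5
  search: anneal
conservation:
  enabled: true
  n_seqs: 4
  n_cols: 60
  n_channel_cols: 29
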