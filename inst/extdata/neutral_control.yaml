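# Neutral control for the recursion: no reactions, no partition noise,
# monodisperse input; the mean trait must show no trend.
scenario: neutral_control
seed: 0
output_dir: neutral-out
species:
  - {name: monomer, molecular_weight: 132, exchangeable: true,
     osmotically_active: true}
platform:
  init_radius_cv: 0.0
  partition_noise_sd: 0.0
  incubation_time_s: 10000
  n_generations: 10
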