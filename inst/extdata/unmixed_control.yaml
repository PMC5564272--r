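# Unmixed control: every droplet carries 50 mM glycylglycine, so there is
# no osmotic gradient and the polydispersity stays flat.
scenario: unmixed_control
seed: 1
output_dir: unmixed-out
environment: {k_w: 0.01, k_s: 0.001, mw_ref: 100}
species:
  - {name: glycylglycine, molecular_weight: 132.12, exchangeable: false,
     osmotically_active: true}
platform:
  n_droplets: 100
  init_radius_um: 30
  init_radius_cv: 0.0
  composition:
    - {fraction: 1.0, concentrations_M: {glycylglycine: 0.05}}
  feedstock_concentrations_M: {glycylglycine: 0.05}
  incubation_time_s: 7500
  dt_s: 10
  size_threshold_um: 60
  n_generations: 1
sampling: {sample_every_s: 500}
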