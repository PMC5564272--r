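# Osmotic coarsening of a mixed, monodisperse 50 mM glycylglycine /
# pure-water droplet population co-incubated for 7500 s (125 min).
scenario: glygly_coarsening
seed: 1
output_dir: glygly-out
environment: {k_w: 0.01, k_s: 0.001, mw_ref: 100}
species:
  - {name: glycylglycine, molecular_weight: 132.12, exchangeable: false,
     osmotically_active: true}
platform:
  n_droplets: 100
  init_radius_um: 30
  init_radius_cv: 0.0
  composition:
    - {fraction: 0.5, concentrations_M: {glycylglycine: 0.05}}
    - {fraction: 0.5, concentrations_M: {}}
  feedstock_concentrations_M: {glycylglycine: 0.05}
  incubation_time_s: 7500
  dt_s: 10
  size_threshold_um: 60
  n_generations: 1
sampling: {sample_every_s: 500}
imaging: {scale_um_per_px: 2, frame_size_px: 800, noise_sd: 8,
          render_every_s: 1500}
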