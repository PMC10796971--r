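# Default pipeline configuration (mirrors arborcsr::default_config()).
base_seed: 1
bc:
  n_ribbons: 84
  n_inhibitory: 120
  n_excitatory: 8
  arbor_radius: 20.0
  soma_radius: 3.0
  axon_stalk_length: 30.0
  branch_order: 5
  branch_length_mean: 7.0
  neurite_radius: 0.15
rgc:
  pixon:
    n_cells: 6
    field_diameter: 250.0
    total_dendrite_length: 2500.0
  onalpha:
    n_cells: 6
    field_diameter: 350.0
    total_dendrite_length: 3000.0
rf:
  sigma_c: 22.0
  density: 0.3
  true_sigma_s: 100.0
  true_csr: 1.8
  noise_sd: 0.05
sim:
  dt: 0.025
  settle_time: 500.0
  stim_time: 1000.0
  compartment_max_length: 3.0
sweep:
  n_anchors: 12
  n_grid: [1, 10, 30, 60, 120]
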