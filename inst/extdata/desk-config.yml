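# Example declarative configuration for a desk-scale run.
# Sections map one-to-one onto larch_params(), simulation_config() and
# synth_geometry() arguments; read with read_config().
forcing:
  scenario: RCP4.5
  post_peak_mode: continued
  n_nodes: 6
  node_spacing_km: 10
  gradient_C_per_100km: 9
  rng_seed: 1
simulator:
  transect_length_km: 50
  transect_width_m: 20
  stabilization_years: 200
  repeats: 3
  rng_seed: 1
  initial_seed_count: 1000
  initial_seed_years: 50
  permanent_seeds_per_200km: 10
  hinterland_stretch_m: 500
  hinterland_seed_max: 20
params:
  g_max: 0.5
  t_jul_lo: 9.0
  t_jul_hi: 11.5
area:
  corridor_width_km: 100
  corridor_length_km: 50
  n_regions: 4
  curvature_km: 0
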