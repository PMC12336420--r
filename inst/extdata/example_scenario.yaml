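# Example synthetic-scenario configuration (see ?scenario_config)
seed: 42
grid: [60, 60]
cellsize: 1000
n_landcover_classes: 6
class_noise: 0.15
n_sites: 5
recorders_per_site: 6
n_experts: 9
n_syllables: 200
occupancy: 0.4
decay: 1.0
noise_sd: 0.3
detect_prob: 0.7
site_radius: 3000
buffer_radius: 1500
min_separation: 1000
species: synthetic_species
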