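# Example pipeline configuration for pipeline_config_from_yaml().
n_jae: 36
n_hc: 36
rate_hz: 500
seed: 1
alpha: 0.05
n_surrogates: 100
bands: [delta, theta, alpha, beta1, beta2]
subgroup_axes: [sex, age_13_split, discharge_pattern]
output_dir: results/run1
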