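# Shared scenarios, generated once per test run.

# Small scenario at the default noise levels.
SC_TINY <- generate_scenario(scenario_config(
  n_genes_per_species = 40L, rng_seed = 42L))

# Noise-free limit: every planted signal is observed, nothing spurious.
SC_NF <- generate_scenario(scenario_config(
  n_genes_per_species = 40L, detection_sensitivity = 1,
  false_call_rate = 0, peak_dropout = 0, rng_seed = 7L))
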