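# Example pipeline configuration.
# With simulate: true the synthetic block parameterizes the generator;
# with simulate: false the inputs block names the CSV files to analyse.
simulate: true
synthetic:
  seed: 1
  noise_sd: 0.2
  turnover_strength: 3
transform:
  log: true
  standardize: true
# inputs:
#   colony_table: data/colonies.csv
#   abundance_table: data/abundance.csv
#   sampled_species: [gen1, gen2]
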