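# Example model configuration: a desk-scale run with the stricter FIT
# threshold. Any omitted entry takes the package default.
demography:
  total_eligible_population: 50000
  entry_rate: 0.045
fit: fit100
natural_history:
  sojourn_mean_years: 4
  crc_death_prob: 0.06
costs:
  cancer_mgmt_annual: 12000
screening_colonoscopy_rate: 0.0135
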