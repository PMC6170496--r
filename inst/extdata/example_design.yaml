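# Example simulation design: a second-F3-style pedigree (mock control,
# single-generation stress, three successive stress generations), three
# pooled replicate samples of 10 plants per line.
model:
  n_cg: 3000
  n_chg: 300
  n_chh: 300
  n_chloroplast: 1000
  n_stress_responsive: 400
  delta_stress: 0.15
  penetrance: 0.8
  conversion_rate: 0.995
  coverage_mean: 20
  seed: 11
pedigree:
  design: [MMM, SMM, SSS]
  line_ids: [MMM, SMM, SSS]
  replicates: 3
  pool_size: 10
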