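# Demo configuration for the numt-atlas pipeline. Values mirror the
# package defaults; override any subset and pass the file via
#   numt-atlas run --config demo_config.yaml --seed 1 --out DIR
seed: 1
simulate:
  genome_length: 1000000
  mt_length: 16600
  mito_rate: 2.0e-8
  nuclear_rate: 2.2e-9
  kappa: 4
  n_wgs_samples: 3
  depth: 20
  read_len: 100
  insert_size: 300
  error_rate: 0.01
  n_reference_numts: 5
  n_novel_numts: 3
  min_numt_len: 100
  max_numt_len: 2000
scoring:
  match: 1
  mismatch: -1
  gap_open: 7
  gap_extend: 1
thresholds:
  score: 30
  merge_gap: 20000
  end_exclusion: 1000
  clip_support: 3
  clip_len: 7
  identity: 0.75
  e_value: 1.0e-4
  group_window: 100
  r1: 0.75
  r2_low: 0.30
  r2_high: 0.80
  min_length: 30
  min_datasets: 2
  polymorphic: 0.97
rates:
  mammalian: 2.2e-9
  ruminant: 2.48e-9
  pig_pedigree: 1.2e-9
divergence:
  sus: 3.5
  suinae: 10
  root: 55
dloop: [15400, 16600]
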