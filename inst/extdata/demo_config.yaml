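# Demonstration pipeline configuration: a 20-kb two-gene locus with one
# complex inversion-plus-deletion allele segregating in three populations.
# Mirrors polyfusion::demoConfig(); paths are created under `outdir`.
seed: 42
outdir: polyfusion_demo_run
genome:
  contig_name: toy1
  length: 20000
sv:
  sv_id: cx1
  sv_type: COMPLEX_INV_DEL
  breakpoints:
    - [8000, 11000]
    - [11000, 12200]
  expected_fusion: [geneA, geneB]
cohort:
  populations:
    label: [POPA, POPB, POPC]
    allele_frequency: [0.10, 0.0, 0.02]
    "n": [30, 30, 30]   # quoted: bare n is a YAML 1.1 boolean
tissues:
  labels: [tissue1, tissue2, tissue3, tissue4, tissue5, tissue6, tissue7, tissue8]
  samples_per_donor: 8
chimera:
  carrier_prob: 0.9
  background_prob: 0.005
  n_decoys: 10
  decoy_prob: 0.08
reads:
  read_length: 100
  insert_mean: 350
  insert_sd: 50
  coverage: 15
  base_error_rate: 0.001
  n_wgs_samples: 12
catalog:
  min_score: 0.6
  max_identity: 0.9
  max_individuals: 250
  min_tissues: 5
  min_sample_fraction: 0.6667
  aggregation: mean
genotype:
  max_edits: 0
  min_score: 90
  min_identity: 0.90
  rule: CTRL & JUNCTION
sv_evidence:
  min_support: 3
  gain_threshold: 1.3
  loss_threshold: 0.7
phenotypes:
  codes: [code001, code002, code003, code004, code005, code006, code007,
          code008, code009, code010, code011, code012, code013, code014,
          code015, code016, code017, code018, code019, code020]
  baseline_prevalence: 0.08
  model: dominant
association:
  min_total: 10
  min_in_experimental: 1
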