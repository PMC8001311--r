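# Demonstration pipeline configuration: a small two-timepoint study with
# planted U-to-C (and one C-to-U) editing sites, genomic SNPs and
# contaminated reads.
seed: 42
samples: [d12, d20]
synth:
  n_genes: 12
  gene_length: 240
  utr5_len: 50
  utr3_len: 60
  intergenic_len: 120
  coverage: 40
  error_rate: 0.001
  n_snp_sites: 4
  read_length: 75
  adapter_fraction: 0.05
  n_fraction_high: 0.03
editing_plan:
  - {gene: 2, feature: "5'UTR", offset: 20, conversion: U-to-C, d12: 0.77, d20: 0.66}
  - {gene: 3, feature: CDS,     offset: 40, conversion: U-to-C, d12: 0.24, d20: 0.00}
  - {gene: 5, feature: "5'UTR", offset: 10, conversion: U-to-C, d12: 0.00, d20: 0.23}
  - {gene: 6, feature: "3'UTR", offset: 30, conversion: U-to-C, d12: 0.46, d20: 0.50}
  - {gene: 7, feature: "3'UTR", offset: 15, conversion: U-to-C, d12: 0.00, d20: 0.20}
  - {gene: 9, feature: CDS,     offset: 80, conversion: C-to-U, d12: 0.35, d20: 0.30}
  - {gene: 10, feature: "3'UTR", offset: 25, conversion: U-to-C, d12: 0.21, d20: 0.00}
call:
  min_alt_reads: 2
  min_alt_frac: 0.05
validate:
  secondary_min_frac: 0.10
  noise_sd: 0.0
use_read_simulation: true
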