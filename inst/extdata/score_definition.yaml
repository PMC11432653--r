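snps:
- rsid: rs6511720
  gene: LDLR
  minor_allele: T
  common_allele: G
  counted_allele: common
  aprs_per_allele: 1
  weight_per_allele: 0.18
- rsid: rs629301
  gene: CELSR2
  minor_allele: G
  common_allele: T
  counted_allele: common
  aprs_per_allele: 1
  weight_per_allele: 0.146
- rsid: rs1367117
  gene: APOB
  minor_allele: A
  common_allele: G
  counted_allele: minor
  aprs_per_allele: 1
  weight_per_allele: 0.105
- rsid: rs4299376
  gene: ABCG8
  minor_allele: G
  common_allele: T
  counted_allele: minor
  aprs_per_allele: 1
  weight_per_allele: 0.071
- rsid: rs1800562
  gene: HFE
  minor_allele: A
  common_allele: G
  counted_allele: common
  aprs_per_allele: 1
  weight_per_allele: 0.057
- rsid: rs2479409
  gene: PCSK9
  minor_allele: G
  common_allele: A
  counted_allele: minor
  aprs_per_allele: 1
  weight_per_allele: 0.052
apoe:
- genotype: e2e2
  aprs: -2
  weight: -0.8
- genotype: e2e3
  aprs: -1
  weight: -0.4
- genotype: e2e4
  aprs: 0
  weight: -0.27
- genotype: e3e3
  aprs: 0
  weight: 0.0
- genotype: e3e4
  aprs: 1
  weight: 0.13
- genotype: e4e4
  aprs: 2
  weight: 0.26
excluded: rs676210
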