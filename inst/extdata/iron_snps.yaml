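# The 12 iron-status GWAS SNPs used as Mendelian randomization instruments.
# effect_allele: tested allele as in the source meta-analysis; freq: tested
# allele frequency in the analysis cohort. hypothesized_direction refers to
# the tested allele's hypothesized effect on atherosclerosis risk under the
# iron hypothesis (alleles raising iron/TS/ferritin raise risk).
# flip = true: the tested allele lowers risk, so score construction counts
# the opposite allele (dosage -> 2 - dosage).
# published_beta values (per-biomarker betas from the source meta-analysis)
# are not bundled here; synthetic annotations carry simulated betas instead.
snps:
  - {snp_id: rs1800562,  effect_allele: A, chrom: 6,  pos: 26093141,  freq: 0.06,
     hypothesized_direction: risk_increasing, flip: false, in_score: true,  role: exposure}
  - {snp_id: rs1799945,  effect_allele: C, chrom: 6,  pos: 26091179,  freq: 0.84,
     hypothesized_direction: risk_decreasing, flip: true,  in_score: true,  role: exposure}
  - {snp_id: rs9990333,  effect_allele: T, chrom: 3,  pos: 195827205, freq: 0.47,
     hypothesized_direction: risk_increasing, flip: false, in_score: true,  role: exposure}
  - {snp_id: rs7385804,  effect_allele: A, chrom: 7,  pos: 100235970, freq: 0.64,
     hypothesized_direction: risk_increasing, flip: false, in_score: true,  role: exposure}
  - {snp_id: rs744653,   effect_allele: T, chrom: 2,  pos: 190378750, freq: 0.86,
     hypothesized_direction: risk_decreasing, flip: true,  in_score: true,  role: exposure}
  - {snp_id: rs651007,   effect_allele: T, chrom: 9,  pos: 136153875, freq: 0.20,
     hypothesized_direction: risk_decreasing, flip: true,  in_score: true,  role: exposure}
  - {snp_id: rs411988,   effect_allele: A, chrom: 17, pos: 56709034,  freq: 0.58,
     hypothesized_direction: risk_decreasing, flip: true,  in_score: true,  role: exposure}
  - {snp_id: rs855791,   effect_allele: A, chrom: 22, pos: 37462936,  freq: 0.46,
     hypothesized_direction: risk_decreasing, flip: true,  in_score: true,  role: exposure}
  # direction unknown: effects confined to transferrin, or discordant
  - {snp_id: rs8177240,  effect_allele: T, chrom: 3,  pos: 133477701, freq: 0.66,
     hypothesized_direction: unknown, flip: false, in_score: false, role: exposure}
  - {snp_id: rs4921915,  effect_allele: A, chrom: 8,  pos: 18272466,  freq: 0.78,
     hypothesized_direction: unknown, flip: false, in_score: false, role: exposure}
  - {snp_id: rs6486121,  effect_allele: T, chrom: 11, pos: 13355770,  freq: 0.64,
     hypothesized_direction: unknown, flip: false, in_score: false, role: exposure}
  - {snp_id: rs174577,   effect_allele: A, chrom: 11, pos: 61604814,  freq: 0.32,
     hypothesized_direction: unknown, flip: false, in_score: false, role: exposure}
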