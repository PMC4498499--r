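# The six genome-wide significant loci for non-invasive measurements of
# atherosclerosis (NIMA) used for cross-trait association with the iron
# biomarkers: three for carotid intima-media thickness (nearest genes ZHX2,
# APOC1, PINX1), two for plaque presence (PIK3CG, EDNRA) and one for
# ankle-brachial index (CDKN2B). rs11781551 and rs10757269 are the loci
# named in the primary analysis; the remaining ids follow the source GWAS
# meta-analyses. Direction is with respect to the listed effect allele's
# published association with its outcome trait (risk_increasing = worsens
# the atherosclerosis measure).
snps:
  - {snp_id: rs11781551, effect_allele: G, chrom: 8, pos: 145639681,
     hypothesized_direction: risk_increasing, flip: false, in_score: false,
     role: outcome, trait: IMT}
  - {snp_id: rs445925,   effect_allele: A, chrom: 19, pos: 45415640,
     hypothesized_direction: risk_increasing, flip: false, in_score: false,
     role: outcome, trait: IMT}
  - {snp_id: rs6601530,  effect_allele: G, chrom: 8, pos: 10586880,
     hypothesized_direction: risk_increasing, flip: false, in_score: false,
     role: outcome, trait: IMT}
  - {snp_id: rs17398575, effect_allele: C, chrom: 7, pos: 106411858,
     hypothesized_direction: risk_increasing, flip: false, in_score: false,
     role: outcome, trait: plaque}
  - {snp_id: rs1878406,  effect_allele: T, chrom: 4, pos: 148393664,
     hypothesized_direction: risk_increasing, flip: false, in_score: false,
     role: outcome, trait: plaque}
  - {snp_id: rs10757269, effect_allele: G, chrom: 9, pos: 22088619,
     hypothesized_direction: risk_increasing, flip: false, in_score: false,
     role: outcome, trait: ABI_rest}
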