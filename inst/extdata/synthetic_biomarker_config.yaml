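# Example biomarker-indication config (synthetic).  Entries reference the
# synthetic cohort generator's gene panel (SG...) and drug ids (DRUG..)
# so the shipped example runs against gen_training_cohort() output; real
# analyses supply their own file with the same shape (one entry per
# indication, as in an FDA-label biomarker list).
- name: SG001 mutation sensitizes to DRUG01 (synthetic)
  drug: DRUG01
  direction: marker_more_sensitive
  rule:
    type: mutation_in_genes
    genes: [SG001]
- name: SG002 V600E-like variant sensitizes to DRUG02 (synthetic)
  drug: DRUG02
  direction: marker_more_sensitive
  cohort: [site_a]
  rule:
    type: variant_match
    gene: SG002
    patterns: [V600E, V600K]
- name: High SG003 expression confers DRUG03 resistance (synthetic)
  drug: DRUG03
  direction: marker_more_resistant
  rule:
    type: expression_above_quantile
    gene: SG003
    q: 0.5
- name: SG004 wild-type resists DRUG04 (synthetic)
  drug: DRUG04
  direction: marker_more_resistant
  rule:
    type: wildtype_in_genes
    genes: [SG004]
- name: Receptor-positive flag sensitizes to DRUG05 (synthetic)
  drug: DRUG05
  direction: marker_more_sensitive
  rule:
    type: annotation_flag
    flag: receptor_positive
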