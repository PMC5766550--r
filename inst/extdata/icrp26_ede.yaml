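# ICRP Publication 26 weighting factors for the effective dose equivalent.
# Mirrors tissue_weight_scheme("ICRP26_EDE").
scheme_id: ICRP26_EDE
weights:
  gonads: 0.25
  breasts: 0.15
  red_marrow: 0.12
  lungs: 0.12
  thyroid: 0.03
  bone_surface: 0.03
remainder_rule: top5_at_0.06
remainder_weight: 0.06
excluded_from_remainder: [skin, total_body]
aliases:
  colon: [uli_wall, lli_wall]
  esophagus: [thymus]
  gonads: [testes, ovaries]
  bone_surface: [osteogenic_cells]
  stomach: [stomach_wall]
  urinary_bladder: [urinary_bladder_wall]
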