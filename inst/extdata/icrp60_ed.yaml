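# ICRP Publication 60 tissue weighting factors for the effective dose.
# Mirrors tissue_weight_scheme("ICRP60_ED"); editable for sensitivity runs.
scheme_id: ICRP60_ED
weights:
  gonads: 0.20
  red_marrow: 0.12
  colon: 0.12
  lungs: 0.12
  stomach: 0.12
  urinary_bladder: 0.05
  breasts: 0.05
  liver: 0.05
  esophagus: 0.05
  thyroid: 0.05
  skin: 0.01
  bone_surface: 0.01
remainder_rule: mass_weighted_mean
remainder_weight: 0.05
remainder_organs:
  - adrenals
  - brain
  - small_intestine
  - kidneys
  - muscle
  - pancreas
  - spleen
  - uterus
aliases:
  colon: [uli_wall, lli_wall]
  esophagus: [thymus]
  gonads: [testes, ovaries]
  bone_surface: [osteogenic_cells]
  stomach: [stomach_wall]
  urinary_bladder: [urinary_bladder_wall]
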