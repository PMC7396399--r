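# ICRP Publication 60 tissue weighting factors, arranged for an
# OLINDA-style adult male organ list. Surrogates: testes stand in for
# gonads, thymus for the esophagus; the colon dose is composed from the
# upper and lower large intestine walls by mass (0.57 / 0.43). The
# remainder weight is applied to the mass-weighted mean of the remainder
# organs, with the ICRP-60 splitting rule when one remainder organ
# receives more dose than every named organ. Masses are ICRP reference
# adult organ masses in grams.
name: ICRP-60
sex: male
weights:
  gonads: 0.20
  red_marrow: 0.12
  colon: 0.12
  lungs: 0.12
  stomach_wall: 0.12
  urinary_bladder_wall: 0.05
  breasts: 0.05
  liver: 0.05
  esophagus: 0.05
  thyroid: 0.05
  skin: 0.01
  osteogenic_cells: 0.01
surrogates:
  gonads: testes
  esophagus: thymus
composites:
  colon:
    uli_wall: 0.57
    lli_wall: 0.43
remainder:
  weight: 0.05
  organs:
    - adrenals
    - brain
    - small_intestine
    - kidneys
    - muscle
    - pancreas
    - spleen
    - thymus
    - uterus
  masses:
    adrenals: 14
    brain: 1400
    small_intestine: 640
    kidneys: 310
    muscle: 28000
    pancreas: 100
    spleen: 180
    thymus: 20
    uterus: 80
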