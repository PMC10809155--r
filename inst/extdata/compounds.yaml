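# Compound registry: elemental formula (C/H/O/N counts), molar mass
# (g/mol) and, for weak acids, the acid dissociation constant pKa.
#
# pKa sources:
#   caproic acid  4.88  back-calculated from this package's reference
#                       speciation pairs (total vs undissociated caproate
#                       at pH 5.5); consistent with literature values for
#                       hexanoic acid (~4.85-4.88 at 25 C).
#   butyric acid  4.82  CRC Handbook.
#   acetic acid   4.76  CRC Handbook.
#   lactic acid   3.86  CRC Handbook.
# Molar masses are consistent with the formulas (atomic masses C 12.011,
# H 1.008, O 15.999, N 14.007). "biomass" is the standard C-mol cell
# composition CH1.8O0.5N0.2 (24.63 g/C-mol); adjust per organism if known.
compounds:
  - name: caproate
    synonyms: [caproic acid, hexanoic acid, hexanoate, CA]
    formula: {C: 6, H: 12, O: 2, "N": 0}
    molar_mass: 116.16
    pKa: 4.88
  - name: butyrate
    synonyms: [butyric acid, butanoate]
    formula: {C: 4, H: 8, O: 2, "N": 0}
    molar_mass: 88.11
    pKa: 4.82
  - name: acetate
    synonyms: [acetic acid, ethanoate]
    formula: {C: 2, H: 4, O: 2, "N": 0}
    molar_mass: 60.05
    pKa: 4.76
  - name: lactate
    synonyms: [lactic acid]
    formula: {C: 3, H: 6, O: 3, "N": 0}
    molar_mass: 90.08
    pKa: 3.86
  - name: glucose
    synonyms: [D-glucose]
    formula: {C: 6, H: 12, O: 6, "N": 0}
    molar_mass: 180.16
  - name: ethanol
    synonyms: []
    formula: {C: 2, H: 6, O: 1, "N": 0}
    molar_mass: 46.07
  - name: hydrogen
    synonyms: [H2]
    formula: {C: 0, H: 2, O: 0, "N": 0}
    molar_mass: 2.016
  - name: carbon dioxide
    synonyms: [CO2]
    formula: {C: 1, H: 0, O: 2, "N": 0}
    molar_mass: 44.01
  - name: water
    synonyms: [H2O]
    formula: {C: 0, H: 2, O: 1, "N": 0}
    molar_mass: 18.02
  - name: biomass
    synonyms: [cells, VSS]
    formula: {C: 1, H: 1.8, O: 0.5, "N": 0.2}
    molar_mass: 24.63
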