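# Default fragmentation rulebase for defense-metabolite glycoside annotation.
#
# Aglycones carry the skeleton formula, compound class, supported ion
# polarities, characteristic neutral losses applied to the aglycone-retaining
# (Y0) ion, and optional absolute diagnostic fragments (neutral formula of
# the fragment; ionized at the spectrum polarity).  Benzoxazinoid lactam
# skeletons (HBOA/HMBOA) lose CO, CH2O2 and 2CO; the 2,4-dihydroxy skeletons
# lose CO2 (DIMBOA) and CH2O2 (DIBOA, DIMBOA).  5,7-dihydroxyflavonoids give
# the retro-Diels-Alder A-ring fragment (nominal 153) in positive mode.
#
# Substituents are glycoside building blocks.  linkage O = cleavable
# (Y-ion forming), C = carbon-carbon linked (never fully cleaved; fragments
# by the cross-ring losses listed, nominal 120/150 for hexose, 90/120 for
# pentose), mod = small covalent modification retained in all fragments.
# Sugar identity is reported at the hexose/pentose/deoxyhexose level only;
# aliases map trivial names onto those mass-level identities.
aglycones:
  - name: HBOA
    formula: C8H7NO3
    class: benzoxazinoid
    polarities: [-1]
    losses:
      CO: CO
      CH2O2: CH2O2
      2CO: C2O2
  - name: HMBOA
    formula: C9H9NO4
    class: benzoxazinoid
    polarities: [-1]
    losses:
      CO: CO
      CH2O2: CH2O2
      2CO: C2O2
  - name: DIBOA
    formula: C8H7NO4
    class: benzoxazinoid
    polarities: [-1]
    losses:
      CH2O2: CH2O2
  - name: DIMBOA
    formula: C9H9NO5
    class: benzoxazinoid
    polarities: [-1]
    losses:
      CO2: CO2
      CH2O2: CH2O2
  - name: apigenin
    formula: C15H10O5
    class: flavone
    polarities: [1]
    fragments:
      A-ring: C7H4O4
  - name: luteolin
    formula: C15H10O6
    class: flavone
    polarities: [1]
    fragments:
      A-ring: C7H4O4
  - name: tricetin
    formula: C15H10O7
    class: flavone
    polarities: [1]
    fragments:
      A-ring: C7H4O4
  - name: tricin
    formula: C17H14O7
    class: flavone
    polarities: [1]
    fragments:
      A-ring: C7H4O4
substituents:
  - name: hexose
    formula: C6H10O5
    linkage: O
    max_count: 3
    aliases: [glucose, glucoside, galactose]
  - name: pentose
    formula: C5H8O4
    linkage: O
    max_count: 2
    aliases: [xylose, arabinose]
  - name: deoxyhexose
    formula: C6H10O4
    linkage: O
    max_count: 2
    aliases: [rhamnose, rhamnoside]
  - name: acetyl
    formula: C2H2O
    linkage: O
    max_count: 2
  - name: malonyl
    formula: C3H2O3
    linkage: O
    max_count: 2
  - name: methyl
    formula: CH2
    linkage: mod
    max_count: 3
  - name: C-hexose
    formula: C6H10O5
    linkage: C
    max_count: 1
    cross_ring_losses: [C4H8O4, C5H10O5]
  - name: C-pentose
    formula: C5H8O4
    linkage: C
    max_count: 1
    cross_ring_losses: [C3H6O3, C4H8O4]
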