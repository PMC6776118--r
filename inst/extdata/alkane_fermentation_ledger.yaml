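# Hypothesized short-chain n-alkane (propane) fermentation ledger:
# C1 addition to fumarate, CoA activation, carbon-skeleton rearrangement,
# decarboxylation, and substrate-level fatty-acid formation.
#
# ATP accounting (integer equivalents per step, documented choice by choice):
#  * coa_ligation is AMP-forming (ATP -> AMP + PPi) but is counted as one
#    ATP equivalent consumed, matching the depiction of the acetyl-CoA-
#    ligation-like reaction this step is modeled on.
#  * decarboxylation is modeled on the ion-gradient-coupled methylmalonyl-CoA
#    decarboxylase reaction and counted as one ATP equivalent gained.
#  * fatty_acid_formation gains one ATP by substrate-level phosphorylation
#    through an acyl-phosphate intermediate (phosphotransacylase + kinase).
# Net over the ledger: +1 ATP per alkane molecule fermented.
steps:
  - step_id: fumarate_addition
    enzyme: faeA
    atp_delta: 0
    substrates: {propane: 1, fumarate: 1}
    products: {propylsuccinate: 1}
    note: glycyl-radical C1 addition of propane to fumarate

  - step_id: coa_ligation
    enzyme: assK
    atp_delta: -1
    substrates: {propylsuccinate: 1, CoA: 1, ATP: 1}
    products: {propylsuccinyl-CoA: 1, AMP: 1, PPi: 1}
    note: AMP-forming CoA ligase; counted as one ATP equivalent consumed

  - step_id: rearrangement
    enzyme: mcmLS
    atp_delta: 0
    substrates: {propylsuccinyl-CoA: 1}
    products: {propylmalonyl-CoA: 1}
    note: methylmalonyl-CoA-mutase-like carbon skeleton rearrangement

  - step_id: decarboxylation
    enzyme: pccA
    atp_delta: 1
    substrates: {propylmalonyl-CoA: 1}
    products: {methylpentanoyl-CoA: 1, CO2: 1}
    note: ion-gradient-coupled decarboxylation; counted as one ATP gained

  - step_id: fatty_acid_formation
    enzyme: ptb
    atp_delta: 1
    substrates: {methylpentanoyl-CoA: 1, Pi: 1, ADP: 1}
    products: {methylpentanoate: 1, CoA: 1, ATP: 1}
    note: acyl-phosphate route; substrate-level phosphorylation gains one ATP

# Elemental formulas for balance checking. CoA esters use the full CoA
# moiety (C21H36N7O16P3S) minus water for the thioester bond.
compounds:
  propane: C3H8
  fumarate: C4H4O4
  propylsuccinate: C7H12O4
  CoA: C21H36N7O16P3S
  ATP: C10H16N5O13P3
  ADP: C10H15N5O10P2
  AMP: C10H14N5O7P
  PPi: H4P2O7
  Pi: H3PO4
  propylsuccinyl-CoA: C28H46N7O19P3S
  propylmalonyl-CoA: C28H46N7O19P3S
  methylpentanoyl-CoA: C27H46N7O17P3S
  methylpentanoate: C6H12O2
  CO2: CO2
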