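# Standard Gibbs free energies of formation (kJ/mol), 25 C standard state:
# solutes at 1 M, gases at 1 atm. Approximate values assembled from public
# thermodynamic compilations (NIST WebBook for the liquid-phase fumarate
# entry; biochemical tables for the aqueous species). These defaults are
# illustrative and editable: replace with curated values before drawing
# quantitative conclusions.
compound	dgf_kj_mol	phase	formula
propane	-23.4	gas	C3H8
fumarate	-655.6	liquid	C4H4O4
succinate	-690.2	aqueous	C4H6O4
acetate	-369.3	aqueous	C2H4O2
propionate	-361.1	aqueous	C3H6O2
butyrate	-352.6	aqueous	C4H8O2
methylpentanoate	-336.0	aqueous	C6H12O2
CO2	-386.0	aqueous	CO2
H2	17.6	aqueous	H2
H2O	-237.2	liquid	H2O
# Phosphate system (approximate aqueous values for the dominant species at
# standard conditions) and a group-contribution estimate for propylsuccinate:
ATP	-2768.1	aqueous	C10H16N5O13P3
ADP	-1906.1	aqueous	C10H15N5O10P2
AMP	-1034.7	aqueous	C10H14N5O7P
Pi	-1096.1	aqueous	H3PO4
PPi	-1939.2	aqueous	H4P2O7
propylsuccinate	-700.6	aqueous	C7H12O4
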