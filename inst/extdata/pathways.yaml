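# Packaged pathway definitions. Each step lists alternative gene-family
# symbols (any one suffices). prior_status selects the presence standard:
# previously_described -> present at >= 75% of steps; novel -> all steps.
em_glycolysis:
  name: Embden-Meyerhof glycolysis
  prior_status: previously_described
  steps:
    - [glk]
    - [pgi]
    - [pfk, pfp]        # ATP- or diphosphate-dependent phosphofructokinase
    - [fba]
    - [tpi]
    - [gap]
    - [pgk]
    - [gpm]
    - [eno]
    - [pyk]

propionate_degradation:
  name: propionate degradation (methylmalonyl-CoA route)
  prior_status: previously_described
  steps:
    - [prpE]
    - [mcmLS]
    - [pccA]

butanoate_generation:
  name: butanoate generation (ptb + buk)
  prior_status: previously_described
  steps:
    - [ptb]
    - [buk]

acetogenesis_pta_ack:
  name: acetogenesis via phosphotransacetylase + acetate kinase
  prior_status: previously_described
  steps:
    - [pta]
    - [ack]

acetogenesis_acd:
  name: acetogenesis via ADP-forming acetyl-CoA synthetase
  prior_status: novel
  steps:
    - [acdAB]

fae_operon:
  name: fumarate addition enzyme complex (glycyl radical enzyme + activase)
  prior_status: novel
  steps:
    - [faeA]
    - [faeB]
    - [faeC]
    - [faeD]

alkane_downstream:
  name: alkane degradation downstream of fumarate addition
  prior_status: novel
  steps:
    - [assK]
    - [mcmLS]
    - [pccA]

benzylsuccinate_beta_oxidation:
  name: benzylsuccinate beta-oxidation to benzoyl-CoA
  prior_status: novel
  steps:
    - [bbsEF]
    - [bbsG]
    - [bbsH]
    - [bbsCD]
    - [bbsAB]

naphthylmethylsuccinate_beta_oxidation:
  name: naphthyl-2-methyl-succinate beta-oxidation
  prior_status: novel
  steps:
    - [bnsEF]
    - [bnsG]
    - [bnsH]
    - [bnsCD]
    - [bnsAB]

benzoyl_coa_reduction:
  name: benzoyl-CoA reductase (ATP-dependent bcr or ATP-independent bam)
  prior_status: novel
  steps:
    - [bcrA, bamB]

benzoyl_coa_beta_oxidation:
  name: benzoyl-CoA downstream modified beta-oxidation
  prior_status: novel
  steps:
    - [dch, badK]       # Thauera-type / Rhodopseudomonas-type alternatives
    - [had, badH]
    - [oah, badI]
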