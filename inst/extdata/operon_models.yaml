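# Packaged operon architecture models. Cluster thresholds (max 3 intervening
# genes, max 5 kb intergenic gap, co-strand core) are configurable defaults.
faeDCAB:
  core_order: [faeD, faeC, faeA, faeB]
  accessory: [dctP, dctQ, dctM, faeE, faeF, faeG]
  max_intervening_genes: 3
  max_gap_bp: 5000
  require_co_strand: true

bssDCAB:
  core_order: [bssD, bssC, bssA, bssB]
  accessory: [bssE, bssF, bssG]
  max_intervening_genes: 3
  max_gap_bp: 5000
  require_co_strand: true

assDCAB:
  core_order: [assD, assC, assA, assB]
  accessory: [assE, assF, assK]
  max_intervening_genes: 3
  max_gap_bp: 5000
  require_co_strand: true
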