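# Synthetic haplogroup tree used by the cohort simulator.
# One distinctive control-region motif per major clade bin; positions are
# chosen inside the 16000-580 sequenced range and away from the default
# site-filter exclusions. Motifs are synthetic stand-ins, not the
# published human mtDNA phylogeny.
rCRS
  A2: 16111 16223 16290
  B2: 16217 16247
  C1: 16298 16325
  D1: 16342 16362
  L0: 16129 16148
  L1: 16187 16189
  L2: 16278 16294
  L3: 16209 16230
  HV: 16067 16162
  JT: 16069 16126
  N1'2: 16147 16172
  U: 16051 16249
  G: 16017 16227
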