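# Binary mixed droplet (A:B) with a time-delay circuit on 10% of the linker
# DNA. Concentrations in uM, enzyme in U/uL, lengths in um, times in s.
enzyme: 0.25
params:
  kCat: 2.0e-3        # uM/s per (U/uL) of RNase H
  Km: 0.5             # uM
  kHybRNA: 0.05       # 1/(uM s)
  competition: independent
  sdMode: two-step
circuits:
  - label: AB         # plain linker, cleaved immediately by free triggers
    linkerTotal: 0.36
    triggerTotal: 2.5
    delayed: false
    kOn: 0.1
    kDisp: 0.05
    weight: 0.9
  - label: ABd        # delayed linker behind the RNase H timer
    linkerTotal: 0.04
    triggerTotal: 1.0
    cTilde: 1.5
    delayed: true
    kOn: 0.1
    kDisp: 0.05
    weight: 0.1
grid:
  nx: 64
  ny: 64
  spacing: 2.5
  radius: 50
diffusion:
  inside:  {trigger: 1,  inhibited: 1,  rna: 1,  linker: 0}
  outside: {trigger: 10, inhibited: 10, rna: 10, linker: 0}
times:
  from: 0
  to: 2000
  by: 100
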