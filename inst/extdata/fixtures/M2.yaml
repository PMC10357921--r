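name: M2
description: >
  Copper-nitrogen adduct (Cu-N4, axial), frozen powder.
g: [2.05, 2.19]
lineshape: lorentzian
linewidth_convention: pp
analysis_level: 4
nuclei:
  - {A: [18.60, 18.60, 198.68], I: 1.5, count: 1, label: 63Cu}
  - {A: [14.99, 14.99, 17.78], I: 1.0, count: 4, label: 14N}
bands:
  L: {mw_freq_GHz: 1.4, linewidth: 5.5, grid: {start_G: 33, stop_G: 880, points: 1024}}
  S: {mw_freq_GHz: 3.3, linewidth: 6.0, grid: {start_G: 648, stop_G: 1505, points: 1024}}
  X: {mw_freq_GHz: 9.8, linewidth: 6.5, grid: {start_G: 2763, stop_G: 3650, points: 1024}}
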