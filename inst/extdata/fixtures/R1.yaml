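name: R1
description: >
  9,10-dimethylanthracene cation radical. Isotropic solution spectrum with
  175 first-order resonance lines (7 x 5 x 5).
g: 2.0316
lineshape: gaussian
linewidth_convention: fwhm
analysis_level: 7
nuclei:
  - {A: 7.91, I: 0.5, count: 6, label: methyl-H}
  - {A: -2.49, I: 0.5, count: 4, label: ortho-H}
  - {A: -1.20, I: 0.5, count: 4, label: meta-H}
bands:
  L: {mw_freq_GHz: 1.4, linewidth: 0.17, grid: {half_span_G: 41.8, points: 8192}}
  S: {mw_freq_GHz: 3.3, linewidth: 0.18, grid: {half_span_G: 41.8, points: 8192}}
  X: {mw_freq_GHz: 9.8, linewidth: 0.20, grid: {half_span_G: 41.8, points: 8192}}
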