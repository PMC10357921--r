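name: R2
description: >
  Bridged biaryl (dipyrido-imidazole) cation radical.  Synthetic
  reconstruction: couplings taken from the reported extracted values
  (CH2 pair, two 14N, three ring-proton pairs), not from a verbatim
  parameter table.
g: 2.0316
lineshape: lorentzian
linewidth_convention: pp
analysis_level: 7
shf_level: 5
nuclei:
  - {A: 24.2, I: 0.5, count: 2, label: CH2-H}
  - {A: 4.35, I: 1.0, count: 2, label: 14N}
  - {A: 2.6, I: 0.5, count: 2, label: ring-H (3,3')}
  - {A: 2.4, I: 0.5, count: 2, label: ring-H (5,5')}
  - {A: 0.65, I: 0.5, count: 2, label: ring-H (4,4')}
bands:
  L: {mw_freq_GHz: 1.4, linewidth: 0.05, grid: {half_span_G: 55, points: 8192}}
  S: {mw_freq_GHz: 3.3, linewidth: 0.05, grid: {half_span_G: 55, points: 8192}}
  X: {mw_freq_GHz: 9.8, linewidth: 0.06, grid: {half_span_G: 55, points: 8192}}
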