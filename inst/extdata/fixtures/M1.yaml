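name: M1
description: >
  Copper phthalocyanine (Cu-N4, axial).  Synthetic stand-in: the physical
  system is slow-motional; here it is approximated as a frozen axial
  powder with the same g and A tensors.  Demonstration fixture only.
g: [2.05, 2.20]
lineshape: gaussian
linewidth_convention: fwhm
analysis_level: 4
nuclei:
  - {A: [-18.82, -18.82, -197.46], I: 1.5, count: 1, label: 63Cu}
  - {A: [14.64, 14.64, 16.89], I: 1.0, count: 4, label: 14N}
bands:
  L: {mw_freq_GHz: 1.4, linewidth: 2.5, grid: {start_G: 60, stop_G: 850, points: 1024}}
  S: {mw_freq_GHz: 3.3, linewidth: 2.6, grid: {start_G: 675, stop_G: 1470, points: 1024}}
  X: {mw_freq_GHz: 9.8, linewidth: 3.0, grid: {start_G: 2785, stop_G: 3610, points: 1024}}
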