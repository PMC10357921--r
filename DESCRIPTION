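Package: esrwave
Title: Wavelet Pseudo-Decoupling of Continuous-Wave ESR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates hyperfine from super-hyperfine structure in
    continuous-wave electron spin resonance (cw-ESR) spectra by selective
    retention of undecimated discrete wavelet transform (UDWT) components
    ("pseudo-decoupling").  Provides a full-resolution a-trous UDWT with
    Daubechies filters and zero-phase component synthesis, a first-order
    cw-ESR simulator for isotropic solution spectra and axial frozen-powder
    spectra, wavelet-domain denoising, and an extraction stage that turns
    decoupled components into hyperfine coupling constants and g values via
    peak detection, peak-to-peak splitting measurement and splitting binning.
    Ships reference spin systems (organic radicals and copper-nitrogen
    adducts) at L-, S- and X-band microwave frequencies, plus a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
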