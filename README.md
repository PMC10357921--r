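# esrwave

Wavelet pseudo-decoupling of continuous-wave ESR spectra.

Continuous-wave electron spin resonance (cw-ESR) spectra are first
derivatives of the microwave absorption versus magnetic field.  When a
paramagnetic center couples to many magnetic nuclei, the spectrum is a
forest of overlapping multiplets and neither the g values nor the
hyperfine couplings *A* can be read off reliably.  `esrwave` separates
the spectrum by scale instead: an undecimated (à-trous) discrete wavelet
transform with Daubechies `db6` filters decomposes it into full-length
Detail components `D_j` (octave band-pass) and Approximation components
`A_j` (everything coarser), satisfying `A_{j-1} = A_j + D_j` exactly.
Retaining the Approximation path at a working level `j*` yields a
*hyperfine* component — the spectrum of the primary multiplet with the
fine structure stripped — while the level-`j*` Detail is the isolated
*super-hyperfine* comb.  Peak detection, peak-to-peak splitting
measurement and splitting binning then turn the two components into
coupling constants; field positions convert to g values through
`h·nu = g·mu_B·B`.

The package is aimed at ESR spectroscopists (and signal-processing
people working with them) who want a scriptable, testable version of
this analysis: it includes a first-order cw-ESR simulator (isotropic
solution spectra and axial frozen-powder patterns with Gaussian or
Lorentzian derivative lineshapes), wavelet-domain denoising by Detail
removal, reference Cu–N4 and organic-radical spin systems at L-, S- and
X-band, plain-text spectrum I/O, and a command-line interface.

## Worked example

Simulate the 175-line spectrum of a dimethylanthracene-type radical
cation at L band (1.4 GHz), split it at level 7, and extract the
couplings:

```r
library(esrwave)

spec <- simulate_fixture("R1", "L")
res  <- pseudo_decouple(spec, j_star = 7)
extract_report(res, mode = "isotropic")
```

```
<extraction_report> mode = isotropic , level j* = 7
g values:
 label      g field_G
 g_iso 2.0316  492.35
A values (Gauss):
     label   A_G uncertainty_G         source  n
 A_primary 8.567         1.019      hyperfine  6
    A_shf1 2.619         0.107 superhyperfine 43
    A_shf2 1.308         0.064 superhyperfine 44
```

Reading the report: the hyperfine component resolves the seven-line
methyl multiplet; its mean line spacing, 8.57 G, estimates the methyl
coupling (simulation input 7.91 G — the overlap-induced over-estimation
is a known property of the method).  The super-hyperfine Detail carries
a ~1.3 G comb from the near-degenerate ortho/meta ring-proton ladder;
its order-1 and order-2 spacings bin at 1.31 G and 2.62 G, which map to
the meta (1.20 G) and ortho (2.49 G) couplings.  `g_iso` returns the
simulation's g value at the multiplet centroid.

The same pipeline handles axial metal spectra: `simulate_fixture("M2",
"X")` builds a Cu–N4 frozen-powder spectrum, `pseudo_decouple(spec, 4)`
separates the copper quartet from the 14N super-hyperfine comb, and
`extract_report(res, mode = "axial")` reports g-par and g-perp, the
parallel copper coupling, and the nitrogen splitting in the low- and
high-field windows.

From a shell, the same steps are:

```sh
esrwave simulate --system R1 --band L --out r1.csv
esrwave decouple --in r1.csv --level 7 --out-dir out/
esrwave extract  --in r1.csv --level 7 --mode isotropic --out report.json
```

(`exec/esrwave` after installation; every run writes a JSON manifest
with the resolved options and input checksums.)

`level_scan(spec)` tabulates per-level diagnostics when the working
level is not known in advance, and `suggest_level()` encodes the octave
heuristic the reference analyses follow; `denoise(spec, c(1, 2))`
removes the noise-dominated low Details of a measured spectrum before
decoupling.  The methods vignette
(`vignettes/pseudo-decoupling.Rmd`) documents the transform conventions,
lineshape definitions, extraction rules and their limitations.

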