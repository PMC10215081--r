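# cochleaR

Frequency-domain mechanics of the chinchilla cochlea before and after
cochlear-implant (CI) electrode insertion.

A CI electrode sits in the scala tympani, partly blocking one of the two
fluid ducts that flank the basilar membrane (BM). A recurring clinical
question is whether the *depth* of that insertion — measured as the angle
travelled along the cochlear spiral — degrades the residual acoustic
hearing that the cochlea can still deliver mechanically. `cochleaR` makes
that question computable at desk scale: it builds a parametric two-duct
chinchilla cochlea with graded BM material laws, solves the harmonic
fluid–membrane interaction driven by stapes-footplate displacement, inserts
a tapered electrode at any angle up to 900°, and compares the tuning of the
implanted cochlea against the healthy control.

## The model

The three-chambered cochlea is reduced to a transmission line for the
trans-partition pressure difference `p(x)` (scala vestibuli + media above,
scala tympani below), with `x` the arc length along the 18.3 mm BM midline:

```
d/dx( A_h(x)/(i ω ρ) · dp/dx ) = Y(x, ω) · p
```

- `A_h = A_sv·A_st_eff / (A_sv + A_st_eff)` couples the two duct
  cross-sections; the electrode reduces the scala-tympani area to
  `A_st_eff = A_st·(1 − φ(x))`, where `φ` is the occlusion fraction of the
  inserted taper.
- `Y = w(x)/Z_p` is the partition shunt admittance per unit length, with
  the locally reacting partition impedance
  `Z_p = [K(1 + iωβ) − ω²m]/(iω)`,
  `K(x) = C·E(x)·t(x)³/((1−ν²)·w(x)⁴)` (clamped-strip plate reduction) and
  `m(x) = ρ·t(x)`.
- The graded laws are `E(x) = 7.1·10⁴·e^(−0.21x)` Pa and
  `β(x) = 2.3·10⁻⁸·e^(0.52x)` s (`x` in mm), thickness tapering
  16.5 → 5 µm; together they produce the travelling wave whose peak
  location encodes frequency (tonotopy).
- Boundary conditions: prescribed stapes volume velocity at the base (the
  round window is the pressure release), matched helicotrema impedance at
  the apex. BM displacement is recovered as `u = p/(iω·Z_p)` and normalized
  by the stapes displacement.

Tuning is extracted as the location of the maximum of the 0.2 mm-smoothed
normalized profile per frequency, benchmarked against the Greenwood (1990)
frequency–place map, and residual hearing is quantified as the per-frequency
peak-location shift (mm) and normalized-peak change (dB) between implanted
and healthy runs.

## Worked example

```r
library(cochleaR)

res <- run_healthy(outdir = "healthy_run")
as.data.frame(res$tuning)
#>   frequency_Hz x_max_mm normalized_peak flagged greenwood_x_mm  error_mm
#> 1          400  14.2100        107.6066   FALSE      13.785557 0.4244432
#> 2         1000  11.6075        156.3807   FALSE      10.953888 0.6536118
#> 3         2000   9.3175        225.6216   FALSE       8.568862 0.7486379
#> 4         4000   6.6150        363.0869   FALSE       6.070589 0.5444111
#> 5         6000   4.9325        446.6705   FALSE       4.578676 0.3538235
#> 6         8000   3.7350        480.1852   FALSE       3.511404 0.2235956
#> 7        10000   2.8125        485.3225   FALSE       2.679849 0.1326506
```

Each row is one stimulus tone: the peak of the smoothed, stapes-normalized
BM displacement sits at `x_max_mm` (higher frequencies peak basally, lower
frequencies apically — the tonotopic map), `normalized_peak` is the
mechanical gain over the stapes displacement, and `error_mm` is the signed
distance to the Greenwood-predicted place (RMS ≈ 0.49 mm here, about 2.7%
of the BM length).

```r
sw <- run_sweep(outdir = "sweep_run")   # insertion angles 180..900 deg
head(sw$deltas, 3)
#>   angle_deg frequency_Hz dx_mm       ddB
#> 1       180          400 0e+00 0.4364670
#> 2       180         1000 0e+00 0.4971786
#> 3       180         2000 0e+00 0.3609750
```

Across all five insertion angles and seven tones the peak never moves more
than 0.053 mm and the normalized peak never changes by more than 0.57 dB —
the electrode's occlusion leaves both the place code (pitch) and the
magnitude code (loudness) essentially intact, at every depth.

A command-line front end with the same pipelines is installed as
`exec/cochlear` (`healthy`, `sweep`, `fixtures`, `validate-config`
subcommands); ready-made YAML configs live in `inst/extdata/`.

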