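---
title: "A two-duct transmission-line model of the implanted chinchilla cochlea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-duct transmission-line model of the implanted chinchilla cochlea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cochleaR` asks a mechanical question with clinical weight: when a
cochlear-implant (CI) electrode is threaded into the scala tympani, how much
of the cochlea's passive acoustic function survives, and does the answer
depend on how deep — in degrees along the spiral — the electrode goes? This
vignette is the package's own account of the model that answers it: the
reduction, the parameters, the numerics, and the limits of what a passing
test suite demonstrates.

## The model and its assumptions

The cochlea is a coiled duct partitioned lengthwise by the basilar membrane
(BM). Sound enters as stapes-footplate motion at the oval window, travels as
a slow fluid-coupled wave along the BM, and peaks at a frequency-dependent
place (tonotopy). We reduce the three-chambered spiral to a one-dimensional
transmission line in the arc-length coordinate $x \in [0, L]$ along the BM
midline:

$$\frac{d}{dx}\!\left(\frac{A_h(x)}{i\omega\rho}\,\frac{dp}{dx}\right)
   = Y(x,\omega)\, p,$$

where $p$ is the trans-partition pressure difference. The derivation keeps
the anti-symmetric duct mode (equal and opposite volume velocities above and
below the partition), which carries the travelling wave; $A_h =
A_{sv}A_{st}^{\mathrm{eff}}/(A_{sv}+A_{st}^{\mathrm{eff}})$ is the
series-coupled duct area, with the scala media lumped into the upper duct.
The partition is locally reacting with impedance per unit area

$$Z_p(x,\omega) = \frac{K(x)\,(1 + i\omega\beta(x)) - \omega^2 m(x)}{i\omega},
\qquad Y = \frac{w(x)}{Z_p} + Y_{\mathrm{shunts}},$$

so each BM strip is an independent damped oscillator coupled to its
neighbours only through the fluid — the standard box-model idealization.
Stiffness comes from a clamped-strip plate reduction of the graded elastic
membrane, $K = C\,E(x)\,t(x)^3 / ((1-\nu^2)\,w(x)^4)$, and mass is the
membrane's own, $m = \rho_{\mathrm{BM}}\, t(x)$. Damping is
stiffness-proportional (Rayleigh $\beta$, units of seconds), the convention
of harmonic finite-element analysis: the complex modulus is
$E(1 + i\omega\beta)$.

Key physical assumptions, in decreasing order of consequence:

* **Passive linear mechanics.** No cochlear amplifier, no outer-hair-cell
  feedback. Responses scale exactly linearly with the drive, so all results
  are reported normalized by stapes displacement and the absolute drive
  level is immaterial.
* **Locally reacting partition.** Longitudinal elastic coupling within the
  BM is neglected; all longitudinal coupling is hydrodynamic.
* **Rigid walls, inert Reissner's membrane.** The bony labyrinth is fixed;
  the scala media is lumped with the scala vestibuli, which makes
  Reissner's membrane mechanically inert (its graded law is carried in the
  material table but not solved).
* **Incompressible fluid by default.** The long-wave incompressible
  formulation is the default; an `acoustic` formulation adds the
  compressibility shunt $i\omega A/(\rho c^2(1+i\omega\beta_f))$ with the
  fluid's speed of sound. At cochlear dimensions it is a small correction
  (the tests bound it at 20% of peak magnitude).

Boundary conditions: a prescribed stapes volume velocity $U_s = i\omega u_s
A_{fp}$ at the base — the round window, which vents the scala tympani, is
what permits this single-ended drive — and a helicotrema impedance at the
apex, defaulting to the local characteristic impedance $Z_c =
\sqrt{Z_s/Y}\,\big|_{x=L}$ so the remnant wave is absorbed rather than
reflected. The geometry implies a helicotrema but fixes no impedance for
it; since every stimulus frequency lies above the apical cutoff, almost no
energy reaches the termination and the choice is benign.

## The parametric geometry: what the generator emulates

Scan-derived meshes are replaced by a parametric generator
(`build_geometry()`), which emulates the features of the real organ that the
1-D physics consumes:

| quantity | default | why |
|---|---|---|
| BM midline length $L$ | 18.3 mm | average chinchilla BM length; the spiral is rescaled by one factor so $L$ is exact |
| BM thickness $t(x)$ | 16.5 → 5 µm, linear | measured basal/apical endpoints of the pars pectinata; the interpolant between them is unspecified by measurement, so the simplest monotone (linear) choice is the default, with an exponential alternative |
| BM width $w(x)$ | 0.125 → 0.25 mm, linear | literature-typical for chinchilla, *not* a measured profile |
| duct areas $A_{sv}, A_{st}$ | 0.8 → 0.3 mm², linear | order-of-magnitude scala areas; only their ratio to the electrode cross-section (occlusion) matters to the study question, and they are config-exposed for sensitivity runs |
| spiral | logarithmic, 1080°, $r_0 = 2$ mm, taper 0.12 rad⁻¹ | three turns matching chinchilla coiling; must be ≥ 900° so the deepest electrode fits; no numeric spiral parameters exist for the chinchilla in print, so these are stated placeholders |
| grid step `dx_mm` | 0.0025 mm | resolution of the shortest near-peak wavelength — see numerics below |

The generator does **not** emulate: the true three-chamber cross-section
shape (only areas), the osseous spiral lamina and its compliance, curvature
effects on the fluid (the spiral enters only through the angle ↔ arc-length
map), the vestibular system, or any inter-animal variability. Passing tests
therefore demonstrate the mechanics of *this idealized* cochlea; they
quantify occlusion physics, not surgical trauma, and say nothing about
outcomes mediated by active processes or tissue damage.

## Material laws

All structure constants live in `material_table()`, including those of
structures the reduced model never solves (bone, cupulae, maculae,
membranous labyrinth) so the table is complete and auditable
(`write_material_csv()`). The load-bearing entries are the BM's graded laws

$$E(x) = 7.1\times10^4\, e^{-0.21 x}\ \mathrm{Pa},\qquad
  \beta(x) = 2.3\times10^{-8}\, e^{0.52 x}\ \mathrm{s},$$

with $x$ in **mm** from the base. The units of $x$ are a modelling decision:
in mm the modulus falls ~47× base-to-apex, the physiologically sensible
gradient, whereas metres would make the laws effectively constant over an
18.3 mm duct. Two printed inconsistencies are surfaced rather than silently
fixed: the fluid's bulk modulus (2.6 GPa) and speed of sound (1498 m/s)
disagree at density 1000 kg/m³ (construction warns; the solver takes $c$ as
primary), and bone carries two published moduli (`E`, `E_text`), neither
used since the walls are rigid.

### The plate constant

The strip reduction needs one dimensionless constant $C$. A homogeneous
clamped strip under uniform load gives $C = 60$ on the mean-deflection
(volume-displacement-equivalent) convention — but the real BM is not a
homogeneous plate: transverse collagen fibres stiffen it well beyond the
isotropic estimate built from its transverse modulus. $C$ is therefore
treated as the one calibration constant of the reduction, set so that the
basal cutoff frequency $\sqrt{K(0)/m(0)}/2\pi$ of the default geometry
equals the Greenwood chinchilla base characteristic frequency
(≈ 20.4 kHz): $C = 175$. This mirrors how graded laws in 3-D harmonic
models are themselves selected against baseline tuning data, and it is what
places the whole 400 Hz – 10 kHz stimulus set inside the propagating region
of the map. It is config-exposed (`materials$plate_constant`).

## The electrode

`electrode_spec()` describes a linearly tapered body (defaults 0.55 →
0.25 mm diameter — a human long-array taper scaled to chinchilla dimensions,
stated defaults rather than measurements) inserted from the round window to
an angle up to 900°, in the study's 180° steps. `place_electrode()` reduces
it to the grid: occlusion fraction $\varphi(x) = A_e(x)/A_{st}(x)$ inside
the inserted span, zero beyond, with a one-cell ramp at the tip to avoid a
numerical discontinuity. Validation rejects any electrode that meets or
exceeds the duct area, naming the offending position.

How the electrode's *material* couples back was a genuinely open design
choice. The default is leading-order and passive: (i) duct-area reduction,
which locally raises the fluid series impedance, and (ii) a compliant-insert
shunt $Y_e = i\omega A_e/(E_e(1+i\omega\beta_e))$ in which duct pressure
works against the electrode's complex modulus — this is where the printed
silicone values $E_e = 0.4$ MPa and $\beta_e = 7.7\times10^{-2}$ s enter the
solved system, at the (negligible) magnitude their physics warrants. The
tempting alternative, adding $\beta_e$ directly to the partition's Rayleigh
damping, would impose loss factors $\omega\beta_e \gg 1$ across the span —
silicone's bulk loss applied to strain the electrode never experiences — and
was rejected. An optional `mass_loading` mode adds the electrode's mass to
the partition for sensitivity runs.

## Numerical choices

* **Discretization.** Finite-volume second-order central differences on the
  uniform grid; each node row is a volume-velocity balance, so the discrete
  energy identity (input power = partition + shunt + termination
  dissipation) holds to rounding — `power_balance()` verifies assembly
  consistency to ~1e-13, and the tests bound it at 1%.
* **Linear solve.** The system is complex tridiagonal; a direct Thomas
  elimination solves it in $O(n)$ with a relative-residual check (bound
  1e-10 by default, hard error above 1e-8). A singular pivot — possible
  only for a loss-free system driven exactly at resonance — is a diagnostic
  error, not a NaN.
* **Grid step.** The default `dx_mm = 0.0025` is set by the physics of the
  lightly damped base: near the response peak the local wavenumber reaches
  $\kappa_{\max} \approx \sqrt{\omega\rho w / (A_h K \beta)} \sim
  190\,\mathrm{mm^{-1}}$ (wavelength ≈ 0.033 mm), and the default grid puts
  ~13 nodes on that wavelength. A 0.05 mm grid — adequate for the peak
  *locations* — under-resolves the peak *magnitudes* there, which is why
  the coarse setting is kept only as a fast option and the convergence
  tests (halving 0.0025 → 0.00125: peak locations within 1% of $L$, peak
  magnitudes within 2%) run at the default.
* **Smoothing.** The "local filter across every 0.2 mm" is a centred moving
  average with reflective edges; window below one grid step is an error.
  Its transfer function is the Dirichlet kernel, asserted exactly in tests.
* **Peak extraction.** Global maximum of the smoothed normalized profile;
  ties break toward the base; an all-zero profile is flagged, not located.
* **Thresholds.** "Minimal effect" is made operational as $|\Delta x| \le
  0.1$ mm (two cells of the 0.05 mm reference grid, ≈ 0.55% of $L$) and
  $|\Delta\mathrm{dB}| \le 3$ dB per frequency and angle, frozen in the
  config (`analysis$max_dx_shift_mm`, `analysis$max_ddb`). The shift
  threshold is deliberately absolute rather than proportional to the run's
  `dx`: a tolerance that tightens as the grid is refined would invert the
  logic of convergence.
* **Viscosity.** Oscillatory boundary-layer duct resistance was evaluated
  and left out of the solver: at these duct areas its accumulated
  attenuation suppresses the low-frequency travelling wave entirely,
  unlike the lossless acoustic elements this model mirrors. The fluid
  viscosity remains in the material table, unused.
* **Determinism.** No randomness anywhere; identical configs give
  byte-identical CSV outputs (asserted in tests), and every run directory
  carries a config echo plus an md5 manifest.

## Benchmarks computed by the package

The test suite computes (and only the suite computes — this vignette adds
no numbers of its own): strict tonotopic ordering of the seven default
tones for healthy and all implanted runs; normalized peak magnitude
non-increasing toward low frequencies; RMS Greenwood location error below
5% of $L$ (chinchilla preset $F = 163.5\,(10^{2.1\tilde{x}} - 0.85)$,
Greenwood 1990, config-switchable to the human constants); and, across the
180°–900° sweep, peak shifts and magnitude changes inside the frozen
thresholds above. Problem sizes used by the default runs: 7321 nodes
(default grid) per frequency solve, seven frequencies, six solves for the
sweep — under five seconds end-to-end on one CPU; the convergence check
doubles the grid once.

```{r, eval = FALSE}
library(cochleaR)
res <- run_sweep(outdir = "sweep_run")
res$deltas          # 5 angles x 7 frequencies: dx_mm, ddB
```

## Known limitations

Beyond the assumptions above: the model has a single geometry (no
population statistics); the electrode is the final placed state (no
insertion dynamics, friction, tip fold-over, scala dislocation, or trauma);
no middle ear (the stapes drive is prescribed, flat 10 nm by default, and
normalization removes its influence); no electrical stimulation or neural
response; and the round window enters only as an ideal pressure release,
though its membrane constants are in the table should a compliant-window
variant be wanted. The Greenwood comparison benchmarks the *map*, not
absolute sensitivity: normalized gains here characterize this reduced
model, not measured chinchilla gains.
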