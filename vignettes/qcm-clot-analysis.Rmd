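---
title: "Methods: QCM clot-formation analysis and fibrin-network image metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QCM clot-formation analysis and fibrin-network image metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcmclot)
```

## The measurement

A quartz crystal microbalance (QCM) is a shear-mode piezoelectric resonator.
Material coupling to its surface shifts the resonant frequency *f* and, when
the load is dissipative, broadens the conductance resonance; the half width
at half maximum of that peak is the bandwidth Γ. An unloaded sensor sits
near *f*~air~ ≈ 5 MHz with Γ~air~ of a few tens of Hz; a liquid sample
drops *f* by hundreds of Hz and raises Γ by roughly a kilohertz. When
platelet-poor plasma is activated with tissue factor, the growing fibrin
network stiffens the interfacial layer and both quantities trace out
sigmoidal time courses whose shape carries the kinetics of coagulation.

`qcmclot` implements the full analysis of such an experiment: peak fitting,
kinetic-parameter extraction, a viscoelastic "rigidity factor" model, and
spectral quantification of fibrin-network electron micrographs. All
user-facing functions take data frames and return tibbles, so results chain
with ordinary tidyverse verbs.

## Resonance-peak fitting

Each sweep is modelled as a four-parameter Lorentzian

$$G(x) = G_0 + A\,\frac{\Gamma^2}{(x - f)^2 + \Gamma^2},$$

the natural line shape of a conductance resonance, with offset $G_0$,
amplitude $A$, centre $f$ and half width Γ. `fit_resonance()` solves the
bounded nonlinear least-squares problem with Levenberg–Marquardt
(`minpack.lm::nls.lm`) using an analytic Jacobian. Two numerical choices
matter:

* **Centred frequencies.** The sweep is shifted so the centre parameter is
  of order of the span rather than 5 × 10⁶; without this the Jacobian is
  numerically rank-deficient because the parameters differ by seven orders
  of magnitude.
* **Data-driven starting values.** $f_0$ is the argmax of a 5-point moving
  average, Γ₀ the half distance between the half-maximum crossings, $A_0$
  the peak height above the median, $G_0$ the median. These are
  parameter-free, and the converged fit is independent of the start for
  well-posed peaks (asserted by tests). Convergence tolerances are 10⁻¹⁰
  (relative, on both parameters and objective) with at most 500 iterations;
  Γ is bounded positive and $f$ confined to the sweep.

Sweeps with no interior maximum — flat traces, monotone ramps, peaks cut by
the sweep edge — fail with an explicit "flat spectrum" error rather than a
garbage fit. `track_resonance()` chains fits over a sweep series and
converts to shift conventions: `dF(t) = f_air − f(t)` is stored as the
*magnitude of the down-shift*, so mass loading is positive and the effective
mass density below comes out positive; `dG(t) = Γ(t) − Γ_air`.

## Clot kinetics

The analysis is referenced twice. Shifts are first taken relative to the
in-air sensor, then re-referenced at the *z-snapshot* — the sample-loading
moment, before clot onset — giving the starred series
`dF*(t) = dF(t) − dF_z`, `dG*(t) = dG(t) − dG_z`. The z-snapshot defaults to
the first sample of the trace.

From a starred channel, `clot_kinetics()` extracts

* **maximum response** `max(dF*)` (or `dG*`), each channel using its own
  maximum;
* **clotting time (R-QCM)** — first time the channel reaches 10 % of its
  maximum, located by linear interpolation between samples;
* **MRCF and TMRCF** — maximum of the first derivative and the earliest
  time at which it is attained (ties broken to the earliest sample, with a
  10⁻⁸ relative tolerance so an exactly constant derivative is a tie, not
  float jitter).

The derivative is estimated by Savitzky–Golay local quadratic
differentiation (`signal::sgolayfilt`, order 2). The default window of 11
samples suits low-noise traces; it is configurable because the right window
scales with the data. For a logistic clot curve with growth rate *k* the
rate peak has full width at half maximum $2\ln(3+2\sqrt2)/k$ seconds, and a
window of about one third of that width balances smoothing bias (which grows
quadratically with the window) against noise variance. At *k* = 0.02 s⁻¹
and 1 s sampling this rule gives 61 samples. For noisy traces,
`smooth_series = TRUE` applies the same filter to the series itself before
the maximum and the threshold crossing are located. Series shorter than the
window fall back to central differences.

## The rigidity-factor model

Two measured channels cannot separate the three physical processes in a
coagulating sample (viscosity change, elasticity change, fibrin adhesion),
so the package implements a reduced viscoelastic description that assumes
serum viscosity is constant during coagulation. With the z-snapshot values
`dG_z`, `dF_z` characterising the purely viscous plasma, it computes per
time point

$$c(t) = \frac{\Delta\Gamma_z}{\Delta\Gamma(t)},\qquad
\mu_t = a\left(\Delta\Gamma^2 - c^2\Delta\Gamma_z^2\right),\qquad
M_t = b\left(\Delta f - c\,\Delta f_z\right),\qquad
\mathrm{RF} = \frac{\mu_t}{M_t},$$

where $\mu_t$ is a normalised effective elasticity, $M_t$ a normalised
effective mass density, and the rigidity factor RF their ratio — a
qualitative descriptor of the fibrin coupled to the sensor that stays
roughly constant through clot formation. The scaling constants default to
*a* = 2.5 × 10⁻⁷ Hz⁻² and *b* = 10⁻³ Hz⁻¹, which make all three
quantities dimensionless and of order one for typical plasma clots.

Design choices where the formulation was genuinely open:

* **`c` is evaluated per time point.** With `c = dG_z/dG(t)` the model is
  self-consistent: at the z-snapshot `c = 1` and both $\mu_t$ and $M_t$ are
  *exactly* zero (a test asserts bit-exact zeros for arbitrary input). A
  frozen `c` would break those definitional zeros. Note the consequence
  that the subtracted term $c^2\Delta\Gamma_z^2$ equals
  $\Delta\Gamma_z^4/\Delta\Gamma^2$.
* **RF guard.** Near the z-snapshot RF is 0/0. Points whose net frequency
  shift $|\Delta f - c\Delta f_z|$ is below `rf_floor` (default 1 Hz) are
  flagged undefined (`NA` + `rf_defined = FALSE`) instead of producing huge
  ratios.
* **Plateau summary.** Per-sample reporting reduces RF(t) to the mean of
  its defined values over an end-of-trace window, by default the last 20 %
  of the trace, where the clot has formed and $\mu_t$, $M_t$ have
  plateaued. `rigidity_summary()` requires at least three defined points in
  the window.

The algebra is verified end to end by construction: for any increasing
`dG(t)` and any constant ρ one can solve for the `dF(t)` that makes RF ≡ ρ;
the pipeline reproduces ρ to 10⁻⁶ at every defined point.

## Fibrin-network image metrics

Scanning electron micrographs of the final clot are quantified in two
passes. First, structure smaller than 2 pixels is treated as noise and
removed; the default filter is a sharp Fourier low-pass (all components
with wavelength under `min_size_px` pixels zeroed, DC untouched, so the
mean is preserved), with a 3×3 median filter available for salt-and-pepper
noise. The image is then binarized at its *mean* intensity: dark pixels
(−1) are pore space, bright pixels (+1) are fibre. Porosity **F.Por** is
the dark-pixel fraction.

Second, the binary image is Fourier transformed and its power collapsed to
a radially averaged spectrum: each non-DC coefficient at radial frequency
$r=\sqrt{u^2+v^2}$ (cycles/pixel) is assigned to the nearest bin on a grid
of width `1/max(dim)`, and per-bin mean power is reported (the binning
partitions total non-DC power exactly — a Parseval identity the tests
assert). The frequency of maximal mean power estimates the fibre density
**F.Dens** (one fibre per period), converted to µm⁻¹ with the pixel size.
The DC bin and, by default, the first radial bin (large-scale illumination
gradients) are excluded from the peak search; a peak in the highest bin or
a peak under five times the median bin power raises a flag
(`"unresolved"`, `"weak_peak"`). No window function is applied by default
— periodic-texture peaks sit at mid frequencies where leakage is minor.

Fibre diameter follows from the idealisation of the network as crossed
rectangular gratings of bar width *w* and period *P*, for which porosity is
$(1-w/P)^2$ and density $1/P$:

$$\mathrm{F.Diam} = \frac{1-\sqrt{\mathrm{F.Por}}}{\mathrm{F.Dens}}.$$

On ideal crossed gratings the chain recovers *w* within one pixel and
$1/P$ within one spectral bin across widths 2–6 px and periods 8–32 px
(the acceptance suite runs the full 125-cell grid at 192×192 px).

**Known limitation.** The mean-intensity threshold biases porosity toward
0.5 under additive noise when the bright fraction is far from one half: at
duty cycles $w/P \gtrsim 0.6$ (nearly solid) or $\lesssim 0.07$ (sparse),
10 % detector noise flips enough near-threshold pixels that the diameter
error can exceed one pixel. This is inherent to mean-threshold
binarization, not to the spectral step; the acceptance script reports the
noisy-grid recovery rate alongside the ideal one so the effect stays
visible.

## Synthetic data

The generators provide every input with closed-form ground truth:

* `simulate_shift_series()` — logistic clot curves (default; Gompertz
  optional for asymmetric traces) on top of a liquid-loading plateau.
  Defaults emulate a plasma clot: `dF_z` = 700 Hz, `dG_z` = 1000 Hz
  (aqueous loading of a 5 MHz crystal), amplitudes 2000/1500 Hz,
  *k* = 0.02 s⁻¹, midpoint 400 s, 1 s sampling over 800 s. The logistic is
  the canonical choice because every extracted parameter has a closed form
  (max = A, R = t₀ − ln 9/k, MRCF = Ak/4 at t₀). Noise is additive
  Gaussian; the z-snapshot sample is pinned to its noiseless value because
  the starred referencing treats the liquid-loading plateau as the known
  reference — a noisy single-sample reference would offset every starred
  value by one noise draw. No 1/f drift is modelled.
* `simulate_spectra()` — renders a shift series as Lorentzian sweeps on a
  common frequency window and round-trips through `track_resonance()` to
  10⁻⁴ relative error.
* `simulate_network_image()` — crossed rectangular gratings, optionally
  rotated, blurred and noised; ground truth is the closed-form porosity,
  density and diameter above.

All generators take a seed, restore the global RNG state afterwards, and
changing only the seed changes only the noise. What the generators do *not*
emulate — real fibrin branch points, fibre curvature, depth-of-field
effects in SEM, sensor drift — bounds what passing tests show: they
validate the algebra and the recovery properties of the estimators, not
instrument-specific artefacts.

## Problem sizes and determinism

The test and acceptance workloads use 601–901-point sweeps and traces,
100 noisy kinetic replicates, a 125-cell grating grid at 192×192 px, and a
brute-force Lorentzian grid search (0.1 Hz × 1 Hz resolution) as the
independent oracle for 20 noisy fits; the whole suite runs in well under a
minute. Pipeline reports are deterministic for fixed config and inputs
(config-hash provenance, no timestamps), and `run_image_pipeline()`
isolates per-image failures to their own report rows.
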