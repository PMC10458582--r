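---
title: "Fabry-Perot cavity-length sensing: model, demodulation and expansion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fabry-Perot cavity-length sensing: model, demodulation and expansion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpsense)
```

## The measurement problem

A low-finesse fiber-optic Fabry-Perot (F-P) displacement sensor is a
cleaved fiber end face (reflectivity $R_1 \approx 0.04$) facing a
mirrored reflector ($R_2 \approx 0.99$) across an air gap of physical
length $d$, a few hundred micrometres. Mounted across the two halves of
a screw-driven palatal expander, the gap length tracks the opening of
the midpalatal suture during rapid palatal expansion (RPE): each
fractional turn of the expansion screw opens the suture, and with it the
cavity, by a discrete step. Two such sensors placed a known distance
apart along the anteroposterior axis turn the pair of opening
displacements into an estimate of the suture's opening *angle* —
distinguishing parallel expansion from V-type (wedge) expansion.

`fpsense` implements the full chain: a forward optical model of the
reflected spectrum, recovery of absolute cavity length from the
spectrum's interference peaks, time-series tracking, activation-step
detection, and the two-sensor expansion summary, plus a ground-truthed
synthetic experiment generator so that every stage is testable without
an instrument.

## Forward model

Two beams interfere in reflection: one from the fiber end face, one
from the reflector, with phase difference

$$\delta(\lambda) = \frac{4\pi n d}{\lambda} + \varphi_0,$$

for wavelength $\lambda$, cavity index $n$ and additional phase
$\varphi_0$. The normalized reflected intensity of the two-beam cavity
is

$$\frac{I_r}{I_i} =
  \frac{R_1 + q^2 R_2 - 2q\sqrt{R_1 R_2}\cos\delta}
       {1 + q^2 R_1 R_2 - 2q\sqrt{R_1 R_2}\cos\delta},$$

where $q$ is the coupling coefficient of the reflector beam back into
the lead-in fiber. The expression is monotone decreasing in
$\cos\delta$, so reflected maxima sit exactly at odd multiples of $\pi$
and minima at even multiples; for the default parameters the fringe
swings between about 0.985 and 0.993 (contrast $\approx 0.008$).
Higher-order internal reflections (the full Airy response),
polarization and dispersion of $n$ are deliberately outside the model:
at $R_1 = 0.04$ the two-beam approximation is accurate to the third
decimal and is the standard treatment for low-finesse fiber sensors.

Assumptions and defaults, all exposed as `fp_cavity()` parameters:

| parameter | default | meaning |
|---|---|---|
| `R1` | 0.04 | cleaved silica end-face reflectivity |
| `R2` | 0.99 | coated reflector reflectivity |
| `q`  | 1    | coupling coefficient; no published value exists for the modelled appliance, and since `q` rescales fringe contrast without moving peak wavelengths, the idealized value is the neutral choice |
| `n`  | 1    | air-filled gap |
| `phi0` | 0  | additional phase; the demodulation algebra below assumes it negligible, and it is kept configurable for robustness experiments |

### Thermal drift

The mounted sensor spans a gauge length $l$ of expander material (CTE
$\alpha_1$) of which $l - d$ is fiber (CTE $\alpha_2$); temperature
changes the gap at

$$\frac{\Delta d}{\Delta T} = l\,\alpha_1 - (l - d)\,\alpha_2 .$$

With $l = 6$ mm, $\alpha_1 = 15\times10^{-6}/^\circ$C,
$\alpha_2 = 5.5\times10^{-7}/^\circ$C and $d = 0.3$ mm this is
0.087 µm/°C — negligible against activation steps of 130 µm, which is
the design argument for ignoring temperature in the expansion analysis.
`apply_temperature()` integrates the drift linearly. The model leaves
open whether $d$ on the right-hand side should be the initial or the
instantaneous cavity length when integrating over large temperature
swings; the package uses the initial length, because over any realistic
swing the induced change in $d$ (a few µm) perturbs the sensitivity by
less than $10^{-3}$ of its value, far below the model's own accuracy.

```{r}
temperature_sensitivity(thermal_params(6, 15e-6, 5.5e-7), d_um = 300)
```

## Demodulation

The interference maxima of one spectrum are at wavelengths
$\lambda_i$ satisfying $4\pi n d/\lambda_i = (2(k - (i-1)) + 1)\pi$,
with $\lambda_1$ the *shortest*-wavelength peak and $k$ its integer
fringe order. (Order necessarily decreases as wavelength grows — the
algebra forces this orientation.) Eliminating $d$ between the first and
$i$-th peak gives the fringe order

$$k = \frac{(2i-3)\lambda_i + \lambda_1}{2(\lambda_i - \lambda_1)},$$

which must come out near an integer; the absolute cavity length then
follows from the single shortest-wavelength peak,

$$d = \frac{(2k+1)\,\lambda_1}{4n}.$$

`demodulate()` runs `detect_peaks()` and applies the first and last
detected peaks, the standard interrogation recipe. Because $k$ is
an integer, the method has a self-check: `fringe_order()` reports how
far the raw value lies from the nearest integer and refuses to commit
when the residual exceeds `residual_tolerance` (default 0.3, half-way
between "clearly consistent" and "coin toss"). An opt-in
`method = "consensus"` instead lets every (first, $j$-th) pair vote and
takes the modal order — useful for low-quality spectra, where single
pairs become unreliable.

### Peak detection and refinement

Numerical choices that matter, in the order they are applied:

* **Candidate detection on a smoothed copy.** A Savitzky-Golay filter
  (order 2, window ≈ 0.4 nm) suppresses sample-scale intensity noise
  before local maxima are collected. The window is an order of
  magnitude below any resolvable fringe, so fringe shape is untouched.
* **Topographic prominence filtering.** A candidate must rise at least
  `min_prominence` (default 0.25) of the fringe amplitude above the
  higher of its two flanking valleys, where valleys are found by
  walking outward until a higher candidate appears. Candidates whose
  outward walk hits the span boundary keep their inner-side reference
  only: the outermost fringes may be truncated by the span and would
  otherwise be lost. Spectra whose total amplitude falls below
  `min_amplitude` (default 0.002, a quarter of the expected fringe
  contrast) are declared fringe-free.
* **Sub-sample refinement.** Each retained peak is refined by a
  least-squares parabola fitted to the raw intensity over ±30 % of the
  local fringe spacing (falling back to the classic 3-point quadratic
  for very small windows). Near its maximum the fringe is symmetric in
  phase, so the parabola vertex is unbiased to well below a picometre;
  the windowed fit rather than a bare 3-point stencil is what keeps
  localization near the noise floor when intensity noise is present.
  On the default grid, noiseless refinement lands within 0.2 pm of the
  analytic resonance.
* **Edge flagging.** Peaks within half a local fringe spacing of the
  span boundary are kept but flagged; `demodulate()` skips them when at
  least two interior peaks remain, since a truncated fringe biases
  interpolation and — worse — can corrupt the integer order.

The default wavelength grid is 1510–1590 nm with 16001 samples (5 pm
spacing, ≈ 780 samples per fringe at $d = 300$ µm). Grids that resolve a
fringe with fewer than 10 samples trigger a warning (or an error if
requested): peak interpolation degrades long before fringes alias.

Error propagation is transparent: a wavelength error
$\varepsilon$ on $\lambda_1$ maps to a cavity-length error
$(2k+1)\varepsilon/4$ — about 0.4 nm for the 2 pm repeatability of a
telecom interrogator at $d = 300$ µm ($k = 396$).

```{r}
s <- fp_spectrum(fp_cavity(d_um = 300))
demodulate(s)
```

### Tracking

`track()` demodulates frame sequences independently; frames that fail
(too few fringes, ambiguous order) become flagged gaps, never
interpolated values, so a corrupted frame cannot leak into its
neighbours. Continuity is *not* enforced — activation steps are genuine
signal — but jumps above `jump_threshold_um` (default 200 µm, above any
legitimate 130 µm activation step) are advisory-flagged as possible
order slips.

## Expansion analysis

`detect_steps()` segments a series into plateaus at frame-to-frame
changes above `min_step_um`, then sizes each step as the difference of
plateau *medians* over 30 s windows (clipped at neighbouring
transitions). Medians rather than means because the loading transient
and occasional demodulation outliers should not leak into step sizes.

`summarize_expansion()` assembles the experiment outputs: per
activation the anterior and posterior displacement, their average, the
expected screw-driven displacement (pitch × turn fraction — computed
from geometry, never hard-coded), the cumulative anterior−posterior
difference, and the opening angle under the rigid-wedge small-angle
model with assumed left–right symmetry:

$$\theta = \frac{\Delta_{\mathrm{ant}} - \Delta_{\mathrm{post}}}{s},$$

with $s$ the sensor separation (default 900 µm). No arc-length
correction is applied: at $\theta \approx 0.03$ rad it would change the
third significant digit. Which channel is anterior is a required
configuration fact (`roles =`); it is never inferred from the data,
because the sign of $\theta$ — V-type versus inverted wedge — hinges on
it. `baseline_noise()` reports the quiet-window standard deviation of
the demodulated series (the effective displacement resolution) and
refuses windows that span a step.

## The synthetic experiment generator

`experiment_config()` encodes the emulated bench protocol, and its
defaults are the study conditions, not tuning knobs:

* two sensors with initial cavity lengths 285 µm (posterior) and
  300 µm (anterior);
* three screw activations of a 0.8 mm-pitch screw at 1/6 turn each
  (≈ 130 µm per activation, 0.4 mm total over the half turn);
* the first load split 116.5 / 143.5 µm so the anterior sensor opens
  27 µm wider (the asymmetry is apportioned symmetrically, ±13.5 µm
  about the mean, since no finer attribution is available), giving a
  first-load angle of 27/900 = 0.03 rad; later loads are symmetric, so
  the angle holds constant;
* an interrogator with 2 pm wavelength repeatability at 1 Hz over
  1510–1590 nm, modelled as a per-frame rigid spectral shift — at peak
  level this is equivalent to jittering every reported peak wavelength,
  which is what a repeatability specification describes — plus
  additive intensity noise of SD 0.001 (normalized units; no published
  figure exists, and 0.001 is a realistic photodetector noise floor
  that still leaves the 0.008 fringe contrast at 8:1);
* a 60 s quiet baseline, activations at 60 s, 120 s and 180 s (about
  one minute apart), 240 s total.

Steps are instantaneous by default — the bench observation is that each
load transfers at once and holds without relaxation — with an optional
settling model deliberately left out of the default path.
`simulate_translation_stage()` reproduces the bench calibration
scenario (equal 0.2 mm increments from a precision stage);
`calibrate_displacement()` fits measured against configured
displacement, which must come out at unit slope and zero intercept.

What the generator does *not* emulate, and what green tests therefore
do not certify: mechanical compliance of bone or suture (no
load-deflection physics), epoxy-bond creep, source-spectrum shape and
intensity calibration, polarization fading, or the ±2.5 µm
environmental baseline fluctuation seen on a real bench — our noise
model reproduces the interrogator's repeatability, not the lab's
vibration environment. Quantities tied to those effects (empirical
temperature slope, field baseline SD) are treated as inputs to be
measured, never as reproducible outputs.

```{r, eval = FALSE}
cfg <- experiment_config(seed = 1)
ds <- simulate_experiment(cfg)
series <- track(ds)
summ <- summarize_expansion(series, geometry = cfg$geometry,
                            roles = cfg$roles)
tidy(summ)
glance(summ)
autoplot(summ)
```

## Verification strategy and problem sizes

The test suite checks every stage against independent oracles: the
closed-form odd-order resonance enumeration (peak counts and
wavelengths), hand-evaluated reflectance extrema, the algebraic
identity behind the fringe-order formula, and full round trips
`simulate → demodulate → summarize` against constructed ground truth.
Standard scales used by the suite: round-trip identity on a 0.5 µm
lattice over $d \in [100, 500]$ µm (tolerance 1 nm noiseless), 100
jittered frames at $d = 300$ µm (SD ≤ 0.5 µm), five 0.2 mm stage steps
(slope within $10^{-3}$ of 1), and the full 240-frame two-channel
default experiment. These sizes were chosen to cover the sensor's
working range at the lattice resolution where fringe-order errors would
first appear.

## Known limitations

* The demodulator assumes $\varphi_0$ negligible, as the cavity-length
  formulas require; a genuinely nonzero additional phase biases $d$ by
  up to $\varphi_0 \lambda / (4\pi)$ (≈ 0.12 µm/rad) — common-mode for
  displacement *changes*, but visible in absolute length.
* Absolute cavity length from published fringe spacings alone is
  ill-conditioned: free spectral ranges quoted to two digits are
  consistent with a range of initial lengths several micrometres wide.
  The package therefore validates absolute recovery by round-trip
  simulation, not against published spacing figures.
* With the default intensity noise, roughly 1 frame in 20 fails the
  integer-order residual check and is reported as a gap; this is the
  designed behaviour (a wrong absolute length is worse than a missing
  frame). The consensus mode trades a little bias robustness for fewer
  gaps.
* Step detection assumes plateaus at least as long as the plateau
  window between activations; protocols with activations a few seconds
  apart would need a shorter `plateau_window_s`.
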