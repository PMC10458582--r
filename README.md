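# fpsense

Fiber-optic Fabry–Perot (F–P) cavity-length sensing for monitoring
rapid palatal expansion (RPE).

## What problem this solves

Screw-driven palatal expanders open the midpalatal suture in discrete
steps of ~0.13 mm, and clinicians and biomechanics researchers want to
know *how much* the suture actually opened at each activation and
*whether* it opened in parallel or as a V-shaped wedge. A low-finesse
fiber-optic F–P sensor — a cleaved fiber end face facing a mirrored
reflector across an air gap — measures the gap between the two expander
halves interferometrically: the gap length `d` modulates the reflected
spectrum, and tracking `d` over time gives the opening displacement
with sub-micrometre resolution. Two sensors a known distance `s` apart
along the anteroposterior axis give the opening angle.

`fpsense` is the complete desk toolkit for this measurement:

* **Forward model** — two-beam reflectance of the cavity,
  `Ir/Ii = (R1 + q²R2 − 2q√(R1R2)·cos δ) / (1 + q²R1R2 − 2q√(R1R2)·cos δ)`
  with phase `δ = 4πnd/λ + φ0`, plus the thermal-drift model
  `Δd/ΔT = l·α1 − (l−d)·α2` of the mounted sensor.
* **Demodulation** — peak detection with sub-picometre refinement,
  integer fringe-order recovery from peak wavelength pairs,
  `k = [(2i−3)λi + λ1] / [2(λi − λ1)]`, and absolute cavity length
  `d = (2k+1)·λ1/(4n)`; frame-sequence tracking with fault isolation.
* **Expansion analysis** — activation-step detection via robust plateau
  medians, comparison with the expected screw-driven displacement
  (pitch × turn fraction), baseline-noise resolution, and the
  small-angle wedge estimate `θ = (Δant − Δpost)/s`.
* **Synthetic experiments** — ground-truthed spectrum-frame datasets
  emulating a two-sensor bench protocol (activation staircases,
  interrogator wavelength jitter, intensity noise, thermal ramps,
  translation-stage calibration runs), so the whole pipeline is
  testable without hardware.
* **Files + CLI** — plain-text spectrum/peak-table/time-series formats,
  JSON summary reports, and an `fpsense` command-line wrapper
  (`inst/cli/fpsense.R`) with `simulate`, `demod`, `track`, `analyze`
  and `report` subcommands.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for result objects, and `autoplot()` methods for
spectra, time series, summaries and calibration fits.

## Worked example

Simulate the default two-sensor experiment — initial cavity lengths
285 µm (posterior) and 300 µm (anterior), three 1/6-turn activations of
a 0.8 mm screw with the first load split 116.5/143.5 µm, a 2 pm-jitter
interrogator at 1 Hz — then demodulate and summarize:

```r
library(fpsense)

# one frame: 20 interference peaks over 1510-1590 nm at d = 300 um
demodulate(fp_spectrum(fp_cavity(d_um = 300)))
#>   timestamp_s channel  d_um     k opd_um k_residual n_peaks_used ...
#> 1          NA <NA>     300.   396   600.  0.0000529           19

cfg <- experiment_config(seed = 1)
ds  <- simulate_experiment(cfg)            # 2 channels x 240 frames
ser <- track(ds)                           # per-frame cavity length
summ <- summarize_expansion(ser, geometry = cfg$geometry,
                            roles = cfg$roles)
summ
#> Expansion summary - 3 activation(s)
#>   roles: anterior = ch2, posterior = ch1 (separation 900 um)
#>   activation onset_s anterior_um posterior_um average_um expected_um error_um
#> 1          1      60       143.5        116.5        130       133.3   -3.333
#> 2          2     120       130.0        130.0        130       133.3   -3.334
#> 3          3     180       130.0        130.0        130       133.3   -3.334
#>   diff_cum_um theta_rad theta_deg
#> 1          27      0.03     1.719
#> 2          27      0.03     1.719
#> 3          27      0.03     1.719
#>   average - expected: -3.33 +/- 0.000467 um (mean +/- SD)
#>   baseline SD: anterior 0.00407 um, posterior 0.00336 um
```

Reading the output: each activation opened the suture by 130 µm on
average against an expected 133.3 µm (0.8 mm / 6); the first load
opened the anterior sensor 27 µm wider than the posterior one, a
V-type opening angle of 27/900 = 0.03 rad (1.72°) that stays constant
over the later, symmetric loads; and on a quiet plateau the demodulated
length fluctuates by only a few nanometres, the instrument-limited
resolution of the simulated interrogator. `tidy(summ)` returns the
per-activation table, `glance(summ)` the one-row overview, and
`autoplot(summ)` the per-load bar chart.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/fpsense.R simulate --seed 1 --out data/
Rscript inst/cli/fpsense.R track --out series.csv data/
Rscript inst/cli/fpsense.R analyze --series series.csv --out report/
Rscript inst/cli/fpsense.R report report/summary.json
```

## Package layout

| path | contents |
|---|---|
| `R/fp_model.R` | phase, reflectance, spectrum generation, thermal model |
| `R/peaks.R`, `R/demod.R` | peak detection/refinement, fringe order, tracking |
| `R/expansion.R` | step detection, angles, two-sensor summary |
| `R/synthetic.R` | experiment generator, translation-stage scenario, calibration fit |
| `R/io.R`, `R/cli.R` | file formats, dataset directories, CLI |
| `vignettes/fp-cavity-sensing.Rmd` | methods: model, algorithms, design choices, limitations |
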