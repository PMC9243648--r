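# lrbc

Quantitative optical index of skin red-blood-cell content.

`lrbc` estimates **L<sub>RBC</sub>**, the mean pathlength of detected
light through the red blood cells of skin microvasculature between the
loci of illumination and detection, in micrometers.  It is aimed at
tissue-optics researchers building or validating two-wavelength diffuse
reflectometers: unlike laser-Doppler perfusion indices, L<sub>RBC</sub>
has physical units of length and tracks the local *amount* of red cells
(vascular recruitment, venous pooling), not their velocity.

The package contains the full simulation and estimation chain:

* **Layered skin models** — the canonical seven-layer forearm model
  (stratum corneum through semi-infinite muscle) with per-layer blood
  fractions, and linear blood/tissue absorption mixing
  (`canonical_skin_model()`, `mix_absorption()`).
* **Monte Carlo photon transport** — a weighted-packet kernel in C++
  (MCML conventions: Henyey–Greenstein scattering, Fresnel boundaries,
  Russian roulette) tallying diffuse reflectance by radial exit distance
  (`run_transport()`, `average_runs()`, `annulus_intensity()`).
* **The estimator core** — the modified Beer–Lambert two-wavelength
  formula

  L<sub>RBC</sub> = [ ln(I₀(590)/I₀(780)) + ln(I<sub>e</sub>(780)/I<sub>e</sub>(590)) ] /
  [ PF(590)·μ<sub>eff</sub>(590) − RPF·μ<sub>eff</sub>(780) ]

  with PF(590) = 1, the differential pathlength factor RPF = PF(780)/PF(590)
  (default 2.20), and μ<sub>eff</sub>(590)/μ<sub>eff</sub>(780) = 14.87
  (`lrbc_from_intensities()`, `lrbc_from_voltages()`).
* **Calibration** — the two-stage incident-intensity voltage-ratio bench
  arithmetic (`v0_ratio()`) and RPF estimation from venous-occlusion
  traces by regression of Δln V<sub>e</sub>(780) on Δln V<sub>e</sub>(590)
  (`estimate_rpf()`).
* **A synthetic reflectometer** — modulated dual-wavelength waveform
  generation (1100/1000 Hz carriers, 50 k-samples/s) under occlusion
  scenarios, with a software lock-in demodulator, so the whole
  experimental pipeline is testable without hardware
  (`generate_recording()`, `lock_in_demodulate()`).

See the vignette (`vignettes/lrbc-methods.Rmd`) for the model, its
assumptions and every numerical choice.

## Worked example

Synthesize a venous-occlusion recording whose ground-truth pathlength
rises from 17 μm at 4 μm/min during the cuff inflation, demodulate it,
and recover the trajectory and the differential pathlength factor:

```r
library(lrbc)

sc <- occlusion_scenario(baseline_duration = 20, occlusion_duration = 80,
                         release_duration = 10, sample_rate = 10000,
                         mode = "lrbc", lrbc_baseline_um = 17,
                         lrbc_slope_um_per_min = 4, noise_sd = 0.01, seed = 1)
rec    <- generate_recording(sc)
demod  <- lock_in_demodulate(rec)          # 50 samples/s envelopes
series <- lrbc_from_voltages(demod, sc$constants)

base <- series$lrbc_um[series$phase == "baseline"]
sprintf("baseline LRBC: %.2f um (sd %.2f)", mean(base), sd(base))
#> "baseline LRBC: 17.00 um (sd 0.05)"

occ <- series$time >= 20 & series$time <= 80
sprintf("occlusion slope: %.2f um/min",
        60 * coef(lm(series$lrbc_um[occ] ~ series$time[occ]))[2])
#> "occlusion slope: 4.00 um/min"
```

The configured baseline and slope come back exactly, with the ~0.05 μm
jitter implied by the 1% channel noise.  An occlusion generated with a
known differential pathlength factor is recovered by the regression
estimator:

```r
sc2 <- occlusion_scenario(baseline_duration = 20, occlusion_duration = 80,
                          release_duration = 10, sample_rate = 10000,
                          mode = "rpf", rpf_true = 2.20,
                          noise_sd = 0.01, seed = 1)
estimate_rpf(lock_in_demodulate(generate_recording(sc2)))
#> 2.195  (truth 2.20)
```

And the bench calibration arithmetic, from mean readings
V₀′/V<sub>R</sub>′ = 1840 (590 nm), 2880 (780 nm) and
V<sub>R</sub>(590)/V<sub>R</sub>(780) = 1.89:

```r
v0_ratio(calibration_readings(1840, 1, 2880, 1, 1.89, 1))
#> 1.2075   # 1.21 to two decimals
```

A command-line wrapper is installed as `exec/lrbc`
(`lrbc simulate --blood-scale 1 --wavelength 590 --seed 1 --out sim`,
plus `profile`, `lrbc`, `synth`, `rpf`, `calibrate`); every run writes a
JSON manifest sufficient to reproduce its outputs bit-identically.

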