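---
title: "Estimating skin red-blood-cell content from two-wavelength diffuse reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating skin red-blood-cell content from two-wavelength diffuse reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrbc)
```

## The quantity being estimated

Skin perfusion is organized in two blood-rich horizontal layers, the upper
and deep vascular plexus.  When visible light enters the skin and is
detected a millimeter or so away, part of its path runs through red blood
cells, whose hemoglobin absorbs strongly in the yellow-green band and only
weakly in the near infrared.  The package estimates `L_RBC`, the mean
pathlength of detected light through red blood cells between the
illumination and detection loci, in micrometers.  Unlike laser-Doppler
indices, `L_RBC` has physical units and tracks the *amount* of red cells in
the sampled microvasculature (not their velocity), which makes it useful
for monitoring vascular recruitment, venous pooling, or as a calibration
factor for transcutaneous dye-dilution measurements.

The estimator is a modified Beer-Lambert argument.  The attenuation
`A(lambda) = ln(I0/Ie)` of diffusely reflected light decomposes into a
blood term, a bloodless-tissue term and a geometry term.  Between 550 and
900 nm the latter two are nearly wavelength independent, so the
*difference* of attenuations at two wavelengths isolates the blood term:

    A(l1) - A(l2) = L_RBC * [ PF(l1) mueff(l1) - PF(l2) mueff(l2) ]

where `mueff(lambda)` is the effective attenuation coefficient of red
blood cells and `PF(lambda)` a wavelength-dependent pathlength factor.
Solving for `L_RBC` gives the working formula implemented by
`lrbc_from_intensities()` (and its voltage form,
`lrbc_from_voltages()`).  The working wavelengths 590 and 780 nm sit near
hemoglobin isosbestic points, removing the oxygen-saturation dependence.

Two conventions fix the scale:

* `PF(590) = 1`: the estimate is expressed in units of 590 nm geometric
  pathlength, and only the *ratio* `RPF = PF(780)/PF(590)` enters.  The
  default `RPF = 2.20` is the scale measured by venous-occlusion
  regression (see below), and it is configurable.
* Natural logarithms throughout.  A base-10 variant would rescale every
  value by `ln 10`; the package never mixes bases.

### The attenuation constants

Only the ratio `mueff(590)/mueff(780) = 14.87` is well constrained by the
hemoglobin/whole-blood literature at these wavelengths.  The absolute
values are not: the package defaults to `mueff(590) = 31 mm^-1` — the
scale of packed-red-cell effective attenuation at 590 nm — with
`mueff(780)` fixed by the ratio.  These defaults should *not* be read as
measured constants; any reported `L_RBC` is proportional to
`1/mueff(590)` and `lrbc_constants()` records the values used alongside
every series.  Ratios of `L_RBC` between conditions are independent of
this choice, which is why the blood-scale response (halving under
hypoperfusion, ~1.5x under hyperemia) is the more robust validation
quantity.

## The seven-layer skin model

`canonical_skin_model()` builds the reference forearm-skin model: stratum
corneum, vital epidermis, upper vascular plexus, reticular dermis, deep
vascular plexus, subcutaneous fat and a semi-infinite muscle layer.  Each
layer carries a thickness, blood volume fraction, absorption and
scattering coefficients, anisotropy and refractive index; scattering and
anisotropy are treated as wavelength- and blood-independent.  The
tabulated absorption columns at 0.1x, 1x and 3x baseline blood content are
reproduced verbatim — including the isolated 780 nm epidermis value that
reads 0.339 in the baseline column but 0.338 in the other two, which is
reproduced per column rather than smoothed.

Layers mix absorption linearly in the blood fraction:
`mua = cb * mua_blood + (1 - cb) * mua_tissue` (`mix_absorption()`).  The
tabulated columns, however, are *not* exactly linear: fitting the blood
and tissue coefficients to the 0.1x and 1x columns over-predicts the 3x
column (e.g. 0.64 vs the printed 0.471 mm^-1 for the upper plexus at
590 nm), presumably a vessel-packaging-type correction that the source
table does not document.  The package resolves this in favor of the
printed data: at the three tabulated scales the printed values are used
verbatim; at intermediate scales `mix_absorption()` interpolates from the
0.1x/1x fit and a message notes that scales above 1x run above the
tabulated 3x trend.  No attempt is made to reverse-engineer the
nonlinearity.

The muscle layer keeps constant properties at every blood scale, and the
blood fraction saturates at 1 under extreme scaling.  Models round-trip
bit-exactly through a key/value block config (`write_skin_model()` /
`read_skin_model()`), with numbers serialized at 17 significant digits.

## Monte Carlo transport

`run_transport()` implements the standard weighted-photon-packet transport
for layered media (the MCML conventions), in C++:

* step length `s = -ln(xi)/mut` with leftover dimensionless pathlength
  carried across layer boundaries;
* weight deposition `dW = W mua/mut` per interaction;
* Henyey-Greenstein polar scattering (isotropic when `g = 0`), uniform
  azimuth;
* unpolarized Fresnel reflection/refraction at every index mismatch,
  including total internal reflection, and normal-incidence specular loss
  at entry;
* Russian roulette below weight 1e-4 with survival probability 1/10 and
  weight x10 on survival (both configurable via `transport_config()`).

Geometry is cylindrically symmetric about the entry axis; packets exiting
the top surface are tallied by exit radius, both raw (for exact annular
windows) and in 0.1 mm bins centered on multiples of 0.1 mm with an
overflow bin beyond `max_radius`.  The tally identity
`Rsp + Rd + T + A + roulette_net = 1` holds to rounding for every run,
and `Rsp + Rd + T + A` alone is within 0.5% of 1 at 1e5 packets.

Randomness comes from a Mersenne-Twister 64 stream owned by the kernel
and seeded explicitly, so identical `(model, config)` pairs give
bit-identical results on any platform; `average_runs()` derives per-run
seeds as `base + run index`.

The kernel is verified against three independent references in the test
suite: the Beer-Lambert law for unscattered slabs; the exact
Chandrasekhar H-function plane albedo 0.41495 for a semi-infinite
isotropic medium of single-scattering albedo 0.9; and energy conservation.
During development it was additionally cross-checked against a separate
vectorized implementation using the alternative step-resampling
convention, which agreed on the seven-layer model within Monte Carlo
error.

### Detection window and averaging order

The detected intensity `Ne(lambda)` is the exited weight per incident
packet with exit radius in the 0.5-1.2 mm annulus — the simulated
counterpart of a probe whose collection fibers sit 0.85 mm from the
590 nm illumination fiber — computed from raw exit radii, not from the
binned profile, and identically for both wavelengths.  Collection is not
restricted by numerical aperture: all exiting packets count, whatever
their exit angle.  `lrbc_vs_blood_scale()` averages `Ne` across the
independent runs first and computes a single `L_RBC` from the averaged
values (the alternative — per-run `L_RBC`, then averaging — differs only
at second order in the run-to-run spread; the averaged-`Ne` order matches
a protocol in which averaging precedes the estimator).  The quoted
standard error propagates the run-to-run `Ne` variability through the
log-ratio by the delta method.

Because both wavelengths launch equal packet counts, the incident-ratio
term `ln[I0(590)/I0(780)]` is exactly zero in simulation; the term stays
in the signature for experimental inputs.

### What the simulation reproduces, and what it does not

At 590 nm, lowering the blood content increases the remitted light at all
radii, and the relative change grows with distance from the illumination
axis; at 780 nm the remitted light barely depends on blood content.  Both
trends, and the near-proportional growth of `L_RBC` with blood scale, are
reproduced and asserted in the tests.  Two quantitative caveats are worth
stating plainly.  First, the absolute baseline `L_RBC` depends on the
unprinted `mueff(590)`; with the 31 mm^-1 default the baseline simulation
gives ~21 um, at the edge of the expected 16 +/- 5 um band.  Second, the
baseline 780/590 detected-intensity ratio of the printed seven-layer model
is what fixes the hypoperfusion *ratio* `L_RBC(0.1x)/L_RBC(1x)`; two
independent transport implementations agree on that ratio (~0.65), which
sits above the ~0.5 expected from the original description of this model
— the absolute intensity *changes* under hypoperfusion agree well, so the
difference traces to the baseline intensity ratio itself, most plausibly
an undocumented detection detail (e.g. collection aperture) rather than
the transport physics.  The package reports what the printed model
produces rather than adjusting constants to match.

## Differential pathlength factor from occlusion traces

Inflating an arm cuff to diastolic pressure blocks venous outflow while
arterial inflow continues, so red cells accumulate and both detected
intensities fall — by about 25% at 590 nm and 3% at 780 nm over three
minutes.  Because the pathlength change is common to both wavelengths,
the slope of `dln Ve(780)` against `dln Ve(590)` (each referenced to its
pre-inflation baseline mean) times the attenuation ratio 14.87 estimates
`RPF` (`estimate_rpf()`).  The regression is ordinary least squares with
an intercept, slope only retained; baseline reference is the arithmetic
mean over the pre-inflation window; and the first 10 s after inflation
are blanked to skip the inflation transient (window 10-70 s by default,
both windows configurable).  Per-channel gain shifts `ln Ve` by a
constant and cancels in the differences, which the tests assert.

## The synthetic reflectometer

`generate_recording()` stands in for the instrument: each channel is an
amplitude envelope times a sinusoidal carrier (1100 Hz for 590 nm,
1000 Hz for 780 nm) sampled at 50 k-samples/s, plus white Gaussian noise
proportional to the envelope (default 1% relative, a realistic
photodetection SNR for this hardware class).  The full analog chain — DC
offsets, 200 Hz high-pass, photodiode gains — is collapsed into this
envelope-times-carrier model because every estimator downstream is
gain-invariant.  Envelopes are constant during baseline, ramp down during
occlusion (biphasic shapes take a configurable fraction of the drop as an
initial step), and recover exponentially after release (default time
constant 10 s, matching the rapid post-deflation return).  Default drops
are 25% (590 nm) and 3% (780 nm) at end of occlusion, and the default
phase durations are 180 s each, the occlusion protocol the generator
emulates.  Not modeled: 1/f noise, mains interference, arterial
pulsation, or cuff-pressure physiology — so passing recovery tests shows
estimator correctness under the stated noise model, not robustness to
every artifact of real recordings.

Two inverse modes give recovery tests exact ground truth: `"rpf"` mode
slaves the 780 nm envelope to the 590 nm one so the implied `RPF` is a
chosen constant at every instant; `"lrbc"` mode takes a target pathlength
trajectory (default: 17 um baseline rising at 4 um/min during occlusion,
typical forearm values) and inverts the voltage estimator for the 590 nm
envelope while the 780 nm envelope keeps its small fixed drop.

`lock_in_demodulate()` extracts envelope amplitudes per window as
`2 sqrt(mean(x sin)^2 + mean(x cos)^2)`.  The 20 ms window (1000 samples
at 50 kHz) holds exactly 22 cycles of 1100 Hz and 20 cycles of 1000 Hz,
so the two carriers are exactly orthogonal over each window and
cross-talk is at numerical precision (< 1e-6 asserted).  Integer-cycle
window averaging was chosen over an IIR low-pass because it makes the
orthogonality exact; the original instrument's filter is undocumented,
so the fidelity of this choice to the hardware is unknown.  The output
rate is 50 samples/s.

## Problem sizes and numerical choices

The canonical simulation protocol is 1e6 packets x 10 runs per wavelength
and blood scale.  The package's own validation uses scaled-down sizes
chosen to keep Monte Carlo standard errors a few percent of the
quantities asserted: 1e5 packets with 10 averaged runs for the baseline
pathlength (standard error ~1%), 1e5 x 5 runs per scale for the
blood-scale ratios, and 2e4 x 4 runs for the five-point monotonicity
curve.  The acceptance script uses 1e5 x 5 runs per scale and wavelength.
Property tests of the instrument chain run at a reduced 10 k-samples/s
(the 20 ms window then holds 200 samples and still an integer number of
both carrier cycles), with one full-rate 50 kHz check.

Degenerate inputs are handled explicitly rather than silently: negative
pathlengths are returned with a warning (clipping would hide instrument
drift), non-positive voltage samples are flagged invalid but keep their
time slot, zero-variance occlusion regressions and empty analysis windows
are errors, and bloodless layers are never rescaled by the blood-scale
machinery.

## Command-line surface

The installed `exec/lrbc` script exposes `simulate`, `profile`, `lrbc`,
`synth`, `rpf` and `calibrate` subcommands over the same functions.
Every file-writing run also writes a JSON manifest with the package
version, all parameters and every seed, sufficient to reproduce the
outputs bit-identically.
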