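---
title: "Time-gated wide-field imaging of deep tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-gated wide-field imaging of deep tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatednirs)
```

`gatednirs` simulates and analyses a camera-based alternative to
probe-based functional near-infrared spectroscopy: nanosecond square
laser pulses illuminate the head wide-field, and a gated image sensor
opens an 11-ns electronic shutter only after the falling edge of the
surface-reflected pulse, so that the accumulated charge is dominated by
late-arriving photons that travelled deep. This vignette documents the
models behind each stage, the defaults and their rationale, the
numerical choices, and what the synthetic studies do and do not show.

## Photon transport model

The head is a stack of horizontal layers (z downward, surface at z = 0,
lengths in mm, times in ns). The engine is a weighted Monte Carlo
random walk with the following modelling choices:

* **Similarity relation.** Only transport (reduced) scattering
  coefficients are specified, so scattering is isotropic with step rate
  μs′ and no anisotropy parameter. This reproduces diffuse transport
  while keeping the layer table to two optical coefficients.
* **Continuous absorption.** Weight is attenuated by `exp(-μa·ℓ)` along
  every segment rather than by terminating photons. This keeps variance
  manageable in the extreme tail of the temporal point spread function
  (TPSF), which is where all of the gated signal lives.
* **Index-matched boundaries.** Refractive indices are unstated in the
  usual layer tables; all layers default to n = 1.4 and boundaries are
  index matched (no Fresnel reflection). The index enters only through
  the speed c/n per layer in the time of flight. Both are configurable
  per layer.
* **Termination.** Russian roulette below weight 1e-4 with survival
  probability 0.1, and a total path cap (default 5,000 mm ≈ 23 ns at
  n = 1.4) that terminates the rare walker that diffuses deep and never
  returns. The realised roulette gains/losses and the capped weight are
  tallied, so `launched = detected + escaped + absorbed + capped +
  roulette_net` closes to floating-point precision — this identity is
  asserted in the tests rather than assumed.
* **Detection.** Any upward crossing of z = 0 inside the detector
  rectangle is tallied regardless of exit angle; the restriction to a
  lens aperture is applied separately as the Ω/2π factor of the signal
  budget. The low-scattering CSF layer is propagated with the same
  step logic as every other layer (no void-region special case).

Per detected photon the engine records exit time (origin = the photon's
own entry), exit position, survival weight, per-layer partial paths, the
partial path inside a configurable depth slab (e.g. the first 4 mm of
the brain layer), and the partial path through an optional embedded
cylinder. Partial paths are exact segment clippings, not voxel sums.

The default phantom (`make_phantom_scene()`) is the tissue-equivalent
adult-head stack: scalp+skull 10 mm (μs′ = 1.8, μa = 0.019 mm⁻¹), CSF
2 mm (0.3, 0), semi-infinite brain (2.1, 0.04), with a ϕ10 mm rod of
Δμa = 0.01 mm⁻¹ embedded in the brain. The rod axis defaults to the
viewing axis (z) starting flush with the brain top, so it projects as a
10-mm disc; axis, depth, length and contrast are parameters.

## Time gating and superimposition

An impulse TPSF binned at 25 ps (configurable) is converted to a
square-pulse response by superimposing shifted copies over the pulse
duration (`convolve_pulse()`); at fixed peak power an 11-ns pulse
carries 11 ns / 10 ps = 1,100 impulse-equivalents of energy, and the
convolution conserves total weight times exactly that factor. The time
origin moves from "photon entry" to "pulse-off edge", which for an
ideal square pulse coincides with the half-maximum of the falling edge
of the surface reflection — the gate reference. The shutter is an
ideal top-hat: `gated_fraction()` integrates the histogram over
[t, t+width] with linear interpolation of partial bins. Two
independent routes avoid binning error altogether and are used to
cross-check the convolution: an analytic per-photon emission-interval
overlap (`square_gate_weight()`) and Monte Carlo emission-time sampling
(`sample_emission_times()`).

The gated reflection ratio R(t) is defined per unit input energy per
unit area: the gated detected fraction scaled by the
illuminated-to-detector area ratio. This is the dimensionless R(t) that
the signal budget multiplies by the pixel's input fluence.

A structural note on the superimposition gain (square-pulse gated
signal over impulse gated signal at equal peak power): for a tail of
effective decay time τ the gain is (τ/w₀)(1−e^(−W/τ)) with w₀ = 10 ps —
the package verifies this closed form. The gain is therefore bounded by
the TPSF tail's persistence: under the default head model's absorption
the measured tail decay constant is ≈ 0.17–0.19 ns, which caps the gain
near twenty. Long gains of many hundreds require an essentially
absorption-free tail persisting for ≥ 1 ns; the acceptance script
reports the gain actually computed under the default optical properties.

## Per-pixel photon and electron budget

`signal_energy()` evaluates
Iₛ(t) = (P/A_spot)·n·S·R(t)·Ω/2π·a
with P the single-pulse energy spread uniformly over the flat-top spot
(ϕ given), n light sources, S the projected pixel area, Ω = π(D/2)²/L²
the lens solid angle, and a the captured pulses per frame. Electrons
follow as responsivity × energy / e with e = 1.602176634e-19 C; shot
noise is √N. Reference values (`reference_budget()`): P = 4.8e-10 J at
ϕ7 mm, n = 2, S = 0.07 × 0.07 mm², R = 2.5e-6 at a 0.8-ns gate delay,
D = 4 mm at L = 100 mm, a = 440,000, responsivity 0.3 A/W, 11-ns
window.

`noise_report()` exposes two chains. The *exact* chain carries full
precision (51 e⁻ to within one electron). The *printed* chain rounds
the energy to two significant figures before deriving electrons,
reproducing arithmetic that is chained through two-significant-figure
intermediate values; rounding conventions are nearest integer for
signal electrons and floor for shot noise. Dark current is a
configurable rate (default 500 e⁻/s) over the ~4.8-ms per-frame shutter
open time — "a few electrons" — and enters the SNR as
N/√(N + N_dark).

## ΔOD image synthesis and the binning study

`render_delta_od()` forms per-pixel ΔOD = −ln(I_active/I_rest) over the
camera's field of view from a *single* wide-field simulation: flat-top
illumination covers the FOV, exits are binned by position, and each
photon's gate weight under the square pulse is the analytic emission
overlap, so one run yields all gate delays. Two modes are provided:

* **perturbation** (default): one baseline run records each photon's
  path through the inclusion; the active image reweights by
  `exp(-Δμa·L_inc)`. This is exact within the recorded-path model and
  first-order (Born/Rytov-like) in the sense that trajectories are not
  re-drawn under the added absorption.
* **direct**: two full runs with and without the inclusion's absorption
  applied along the walk. The tests verify that with roulette disabled
  and a shared seed the two modes coincide exactly, and that with
  independent seeds their gated intensities agree within Monte Carlo
  error for Δμa·⟨L⟩ ≪ 1.

Pixels with no detected baseline weight are `NA` (missing), never zero.
Rendering at the native 320 × 240 grid is supported but desk-scale runs
use a coarser grid (64 × 44, i.e. 1-mm pixels) for per-pixel
statistics; the published 18-px spatial Gaussian is rescaled
accordingly (18 × 64/320 = 3.6 px). Smoothing uses a separable kernel
with reflective (half-sample symmetric) padding, which preserves the
image mean — asserted to 1e-6 — and handles `NA`s by normalized
convolution.

`bin_resample()` emulates sparse probe-grid sampling: block averaging
at a 10/20/30-mm pitch (partial edge blocks average over their
available pixels), bicubic interpolation (Keys cubic convolution,
a = −0.5, replicated edges) back to the original pixel count, then
normalization by the result's own maximum. Blob distortion is
quantified by `blob_metrics()`: area-equivalent FWHM of the
half-maximum region and the intensity-weighted centroid above half
maximum.

## Dual-wavelength haemodynamic chain

The in-vivo-style chain (`process_invivo()`) mirrors the hardware's
data layout: odd/even sensor rows carry 750/855 nm and are
de-interleaved into two half-height stacks; matching dark frames are
subtracted (negatives clipped at 0); ΔOD(t) = −ln(I/Ī_baseline) against
the mean of the pre-task rest window; a square region of interest is
averaged before inversion. The modified Beer–Lambert inversion solves
the 2 × 2 system per sample for ΔHbO·L and ΔHbR·L (concentration ×
path length, mM·mm — no differential pathlength factor is applied).
Extinction coefficients at 750/855 nm are a configuration input; the
defaults derive from the standard compiled haemoglobin spectra
(log₁₀ molar extinction × ln 10, converted to mm⁻¹ mM⁻¹), giving the
expected sign structure (HbR-dominant at 750 nm, HbO-dominant at
855 nm). Because the synthetic generator forward-projects through the
same matrix, recovery tests are insensitive to the absolute calibration
of these defaults.

Filtering choices that the source material leaves open, fixed here as
package defaults: the 0.01–0.1 Hz band-pass is a 3rd-order Butterworth
applied forward–backward (zero phase, DC removed); the "baseline
correction at 30- and 85-s intervals" is interpreted as subtracting the
straight line through the series means in ±2-s windows centred at
t = 30 s (task onset) and t = 85 s (end of trial). Trials are split on
the 30/25/30-s protocol, each normalized by its own maximum ΔHbO·L
(non-positive maxima are excluded with a warning; an all-degenerate
record falls back to unnormalized averaging), then averaged pointwise
with standard errors sd/√n. Power spectra are periodograms of the
demeaned series normalized to unit maximum.

## Synthetic in-vivo generator

`make_invivo_stack()` is the ground-truth data source for the chain. It
emulates: a 5-trial block design (30 s rest / 25 s task / 30 s rest) at
5 fps; a trapezoidal task response (5-s ramps) in ΔHbO·L with a
negative ΔHbR·L counterpart (ratio −0.3); a 0.1-Hz low-frequency
(Mayer-wave-like) oscillation and a 1.1-Hz cardiac component carried by
the superficial compartment; Poisson shot noise at the electron scale
of the reference budget (≈51 e⁻ per pixel per frame); interleaved
odd/even wavelength rows; and matching dark frames (mean 10 e⁻). The
late-gate channel carries the task response plus half of the
superficial components (`superficial_share = 0.5`); the early-gate
channel carries the superficial components only. Defaults chosen once:
task amplitude 0.2 mM·mm (peak ΔOD ≈ 0.04 at 855 nm, roughly ten times
the post-smoothing shot-noise level of the processed series) and LFO
amplitude 0.1 mM·mm — superficial contamination of the same order as
the evoked response, which is the regime that makes the early/late
contrast and the band-pass + trial-averaging stages meaningful.

What the generator does *not* emulate: spatially structured superficial
physiology, motion, optode-free geometry drift, sensor fixed-pattern
noise beyond a constant dark offset, or any true photon-transport
coupling between compartments (the forward model is log-linear in the
chromophore products). Passing recovery tests therefore demonstrates
the correctness and conditioning of the processing chain, not its
robustness to real physiological confounds.

The activation is a Gaussian blob centred in a small cropped frame
(24 × 24 px by default) rather than a full 320 × 240 sensor; row
interleaving and all chain stages are exercised identically, at a
fraction of the memory.

## Problem sizes and numerical tolerances

Simulation sizes were chosen so the full study suite runs on a single
CPU in minutes: 2e7 photons for the gated-detection quantities (the
0.8-ns gated ratio then carries a Monte Carlo standard error of ~1–2%),
6e6 photons for the three-gate image rendering on the 1-mm grid, and
2e6-photon fixtures in the test suite. Monte Carlo comparisons use 2–3
standard-error bands computed from per-photon contribution variances;
deterministic identities (weight balance, layer-path sums, MBLL
round-trips) are asserted at 1e-6 relative or tighter. TPSF binning is
25 ps; emission-offset discretization is centred to avoid half-bin
bias, cross-checked against the analytic per-photon gate overlap at 2%.

## Known limitations

* No refractive-index mismatch (Fresnel) physics; angular acceptance at
  the surface is hemispherical with the lens aperture handled as a
  solid-angle factor.
* No polarization, fluorescence, or mesh-based diffusion solver; no
  tomographic inverse reconstruction — images are topographic ΔOD maps.
* The shutter and laser edges are ideal; measured sub-ns fall times are
  not convolved into the gate.
* The perturbation image mode shares one photon set across all pixels
  and gates, so pixel-to-pixel noise is correlated; the direct mode is
  available when independence matters.
* At desk-scale photon counts, millimetre-scale detectors are
  photon-starved in late time bins; the gated studies use the
  10 × 10 mm detector geometry for resolved arrival-time statistics.
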