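# gatednirs

Toolkit for **time-gated, non-contact diffuse optical brain imaging**:
an image sensor with a nanosecond electronic shutter, synchronized to
square-pulsed laser diodes, captures only the late-arriving tail of
light scattered back from a head — photons that, having arrived late,
probabilistically travelled deep. Opening an 11-ns gate a fraction of a
nanosecond after the falling edge of the surface-reflected pulse turns
an ordinary CMOS-style sensor into a wide-field depth-selective
detector, with thousands of measurement points per cm² instead of the
few per cm² that probe-based fNIRS/HD-DOT grids achieve.

The package is written for researchers in diffuse optics and fNIRS
signal processing who want a desk-scale, fully synthetic reproduction
of such a system: every input is generated in code, no external data
are required.

It provides, end to end:

* **Monte Carlo photon transport** (`mc_simulate()`, compiled core) in
  layered head models with time-resolved surface detection and exact
  partial-pathlength tallies per layer, per depth slab, and through an
  embedded absorbing rod. Isotropic scattering at the transport rate
  μs′ (similarity relation), continuous absorption weighting
  exp(−μa·ℓ), index-matched boundaries, speed c/n per layer.
* **Time gating** (`tpsf()`, `convolve_pulse()`, `gated_fraction()`):
  impulse TPSFs, square-pulse responses by superimposition, top-hat
  shutter windows referenced to the pulse-off edge, and the gated
  reflection ratio R(t) entering the signal budget.
* **Photon/electron budget** (`signal_energy()`, `noise_report()`):
  Iₛ(t) = (P/A_spot)·n·S·R(t)·Ω/2π·a, electrons = responsivity·Iₛ/e,
  shot noise √N, dark charge over the per-frame shutter-open time.
* **ΔOD image synthesis** (`render_delta_od()`): per-pixel
  −Δln I maps of a deep absorbing rod under gated wide-field detection,
  a perturbation (path-reweighting) and a direct two-run mode, Gaussian
  smoothing, and the sampling-pitch binning study
  (`bin_resample()`, block average + bicubic upsampling) that shows how
  sparse probe grids blur and mislocalize deep activations.
* **Haemodynamic signal chain** (`process_invivo()` and its parts):
  odd/even-row wavelength de-interleaving (750/855 nm), dark-frame
  subtraction, ΔOD time series, modified Beer–Lambert inversion to
  ΔHbO·L / ΔHbR·L, anchored baseline correction, zero-phase
  0.01–0.1 Hz band-pass, normalized 5-trial averaging with standard
  errors, and unit-normalized power spectra.
* **Synthetic fixtures** (`make_phantom_scene()`,
  `make_invivo_stack()`): the three-layer adult-head phantom with a
  ϕ10 mm Δμa = 0.01 mm⁻¹ rod, and dual-wavelength block-task frame
  stacks (30 s rest / 25 s task / 30 s rest × 5 trials at 5 fps) with a
  trapezoidal haemodynamic response, 0.1-Hz Mayer-wave and 1.1-Hz
  cardiac oscillations, Poisson shot noise at the sensor's electron
  scale, and known ground truth for recovery testing.
* **Workbench** (`run_experiment()`, `inst/cli/gatednirs.R`): YAML-
  configured experiment runner writing CSV/TIFF/JSON bundles.

See `vignettes/time-gated-imaging.Rmd` for the models, defaults and
numerical choices.

## Worked example

```r
library(gatednirs)

## the sensor's per-pixel signal chain at the reference parameters
print(noise_report(reference_budget()))
#> Per-pixel per-frame energy: 2.69e-17 J (printed chain 2.7e-17 J)
#> Signal electrons: 50.35 (rounded 50; printed chain 51)
#> Shot noise: 7.1 e- (floor 7), dark 2.42 e-, SNR 6.93
#> Shutter open per frame: 4.84 ms

sampling_density(c(64, 44), c(320, 240))
#> [1] 2727.273   # measurements per cm^2 of field of view

## time-gated detection on the layered head phantom
sc <- make_phantom_scene()
tl <- mc_simulate(sc$model_rest, sc$source, sc$detector_10mm,
                  slab = sc$slab, n_photons = 1e6, seed = 1,
                  keep_layer_paths = FALSE)
print(tl)
#> Photon tally: 78791 detected / 1e+06 launched (detected weight 6.444e+04)
#>   escaped 6.841e+05, absorbed 2.514e+05, capped 0, roulette 0.0992

gated_reflection_ratio(tl, shutter_window(0.8, 11), sc$pulse)
#> 4.2e-06 (attr "se" 1e-07)

mean_partial_path_vs_time(tl, c(0, 0.25, 0.5, 0.75, 1, 1.25))
#>   t_mid mean_path    se     n
#> 1 0.125     0.000 0.000 71913
#> 2 0.375     0.012 0.006  3556
#> 3 0.625     0.497 0.075  1407
#> 4 0.875     3.308 0.337   715
#> 5 1.125     7.500 0.695   454
```

Reading the numbers: of 10⁶ launched photons, a weight fraction
6.4 × 10⁻² exits inside the central 10 × 10 mm detector footprint.
Gating an 11-ns square pulse 0.8 ns after its falling edge leaves a
detected-to-input intensity ratio of ~4 × 10⁻⁶ per unit area — faint,
which is exactly why the budget above sizes the electron count (~50 e⁻
per pixel per frame after 440,000 accumulated gate openings) against
its √N shot noise (~7 e⁻). The last table shows *why* gating buys
depth: detected light arriving later carries a monotonically longer
mean partial path through the first 4 mm of the brain layer (0 → 7.5 mm
as arrival time grows to ~1.1 ns).

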