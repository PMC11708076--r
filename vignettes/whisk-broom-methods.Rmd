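---
title: "Whisk-broom hyperspectral imaging: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whisk-broom hyperspectral imaging: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskbroom)
```

## The measurement problem

Quantifying the light environment — for visual ecology, for plant science,
and especially for artificial-light-at-night (ALAN) work — needs spectral
radiance resolved over the whole scene: low light levels (down to moonless
night skies), wavelengths from the ultraviolet through the near infrared,
and within-scene contrasts of many orders of magnitude between point-like
lamps and dark backgrounds. Camera-based systems hit optical contrast limits
(glare, internal reflections) and spectral-resolution limits; conventional
hyperspectral cameras must expose space and spectrum together, capping
dynamic range.

A *whisk-broom* imager sidesteps this: a single-point micro-spectrometer
(288 photosites, roughly 320–880 nm) rides a pan/tilt gimbal and builds the
image pixel by pixel, exposing **every pixel independently**. With
integration times from 500 µs to 30 s the exposure ladder alone spans a
60,000:1 range, before the sensor's own dynamic range is counted.

This package implements the complete computational stack of such an
instrument — sensor calibration, per-pixel HDR auto-exposure, scan planning
and projection, and radiometric/visual rendering — against a *simulated*
instrument with exactly known ground truth, so every stage is testable
without hardware.

## The sensor model

Raw counts `r` at integration time `t` relate to ideal linear counts
`c` through the linearisation model

$$c_t = e^{\ln(r_t - d_t)\,a + b}$$

where `d_t` is the dark count at the same integration time and `(a, b)` are
per-unit linearisation coefficients. Real units of this sensor family are
close to linear (`a` near 1) but over-estimate radiance at low counts; the
model corrects this.

The virtual instrument (`instrument_model()`) is the exact forward inverse:
ideal linear counts `c(λ) = s(λ)·Le(λ)·t` (sensitivity `s` in counts µs⁻¹
per W sr⁻¹ m⁻² nm⁻¹) are pushed through `exp((ln c − b)/a)`, a dark level
affine in integration time is added, Gaussian noise with a shot-noise-like
standard deviation `sqrt(gain·µ + read²)` is applied, and the result is
clipped at the ADC ceiling and quantised to integer counts. Defaults:
`gain = 1`, `read = 6` counts, dark offset 100 counts, dark slope 5e-5
counts/µs, ceiling 65535 on a 16-bit scale. These were chosen once on
physical plausibility (unit conversion gain; a few counts of read noise; a
dark level a fraction of a percent of full scale); notably they make the
simulated sensor substantially *quieter* than the physical instrument's
reported fit quality, so green calibration tests here do not certify a real
unit. The ADC bit depth of the original hardware is not published; the
ceiling is configurable everywhere and only needs to be consistent between
the simulator and the exposure logic.

Each instrument carries a private RNG stream (`rng_seed`): identical seed
and call sequence give bit-identical frames, and instrument noise never
perturbs the caller's RNG.

## Acquisition logic

**Auto-exposure.** Integration times start at the 500 µs minimum and double
(octaves) until any photosite saturates or the user ceiling (default 2 s,
hard cap 30 s) is reached; the last unsaturated frame is kept. A pixel that
saturates even at 500 µs is stored with its saturated flag set and surfaces
in the saturation preview. The ladder restarts at 500 µs for every pixel —
exposures are calculated independently at each gimbal position, statelessly.

**Dark scheduling.** The gimbal parks the spectrometer inside its housing
for dark frames. `run_scan()` takes darks after every `dark_interval`
panning passes and always at scan end, at *every* integration time used
since the previous dark set; radiance conversion later uses the temporally
nearest dark at the matching integration time. (Whether the original
firmware scales one dark across integration times is not documented; one
dark per used time is the safe reading.)

**Projection and pole skipping.** Pan maps to image x and tilt to image y
(Mercator), which over-samples azimuth at high elevation. For a row at
elevation `e` only `max(1, round(n_cols·cos e))` columns are measured
(round-half-up), spread uniformly by linspace-rounding; the rest are filled
by per-channel linear interpolation and flagged `interpolated`.
Interpolation operates on linearised, exposure-normalised counts (counts per
microsecond), not raw counts, so pixels measured at different integration
times interpolate correctly; the synthesised raw frames take the nearest
measured neighbour's integration time and dark, keeping the stored cube
self-consistent. Backlash compensation (overshoot 8 steps, return, at each
new panning pass) is recorded as an event log only — the simulated gimbal
has no mechanical play, but ports driving real hardware must keep the
behaviour.

**Gimbal geometry.** Degrees per step are `360 / (2048 · gear_ratio)` per
axis. The original instrument's quoted best resolution implies an
undocumented printed-gear reduction; rather than guess it, `gear_ratio`
defaults to 1 and is configurable per axis.

## Calibration

**Linearisation ladder.** `collect_linearisation_ladder()` auto-exposes
once against a stable source to find the base time `T`, then takes light
and dark frames at 16 log-spaced fractions of `T` spanning 0.005–1.5 (the
stated range; count and spacing are this package's choice). Upper times
around 200,000–800,000 µs give the most useful ladders. `fit_linearisation()`
removes saturated exposures, smooths each recording (Gaussian, σ = 3
channels), subtracts dark, selects the single peak wavelength bin, and
least-squares fits `ln(c_expected) = a·ln(r − d) + b` with expected counts
proportional to the known integration times, reporting the log–log R².

*Identifiability of b.* Only count *ratios* are observable, so `b` is
defined only relative to a count scale; any global gain is absorbed by `b`.
The default scale makes the ladder point nearest the median integration
time satisfy `c_expected = r − d`, so a perfectly linear sensor fits exactly
`a = 1, b = 0`. To compare a fitted `b` against a simulator's ground truth
you must fit in the simulator's count unit: pass `scale =` the true linear
counts per microsecond at the peak bin. Note also that the intercept sits
~9–10 natural-log units from the data centroid, so its per-fit scatter is
~10× that of the slope: single ladders pin `a` to well under 2% but `b`
only to ~10%; `b` is unbiased (the residual noise-free offset, ~0.4%, comes
from quantisation and the prescribed smoothing slightly flattening the peak
bin) and averages to well under 1% over replicated ladders. Since any
constant offset in `b` is a pure gain that cancels against the sensitivity
calibration below, this has no radiometric consequence.

**Spectral sensitivity.** `fit_sensitivity()` images a white standard under
a stable broadband source, averages raw counts over the standard pixels
(the canonical procedure uses 35; averaging reduces curve noise by ≈ √35),
averages the dark frames taken before and after at the matching integration
time, linearises, and divides by integration time and by the calibrated
reference radiance interpolated onto the unit's wavelength grid:
`s(λ) = c(λ)/(t·Le_ref(λ))`. Negative values are floored at zero;
photosites outside the reference's coverage are marked undefined. A
daytime light-reducer aperture is represented as a named attenuation
profile on the calibration record, because sensitivity calibration is only
valid for the optical train it was measured with.

Calibration records (wavelength polynomial — up to degree 5, the
manufacturer's convention, zero-padded; `a`, `b`; sensitivity curve) are
stored per unit in a line-oriented `calibration_data.txt` supporting
multiple units per file, blank lines and `#` comments.

## Radiometry and rendering

`cube_to_radiance()` computes per pixel
`Le(λ) = linearise(raw, dark, a, b)/(t·s(λ))` in W sr⁻¹ m⁻² nm⁻¹.
Small negative excursions from noise subtraction are preserved in the data
and clipped to zero only for rendering. `to_reflectance()` divides by an
in-scene standard pixel (percent, optionally scaled by the standard's known
reflectance; default purely relative), masking channels where the
standard's radiance is ~0.

Rendering choices, where the design was genuinely open:

- **sRGB preview**: Le is integrated against the CIE 1931 2° colour-matching
  functions (the published multi-lobe piecewise-Gaussian analytic
  approximation; error negligible at preview precision) with non-uniform
  trapezoid Δλ weights from the wavelength polynomial. The XYZ→sRGB matrix
  is balanced to an *equal-energy* white (rows normalised to unit sum) so
  spectrally flat radiance renders neutral — a display choice, not a
  chromatic-adaptation model (those are out of scope). Display scaling
  anchors the 99.5th-percentile luminance at white, preventing single
  bright lamps from crushing night scenes; then the sRGB transfer curve.
- **Extended-range preview**: R = near-infrared band, G = CIE Y, B =
  ultraviolet band. Band edges (UV 320–400, red 620–700, NIR 750–850 nm)
  are configurable defaults; each channel normalises to its own
  99.5th percentile since the bands' absolute scales are incommensurate.
- **NDVI**: `(NIR − Red)/(NIR + Red)` on band-integrated radiance, with
  0/0 → 0.
- **Cone catches**: `Q_i = Σ Le(λ)·λ·S_i(λ)·Δλ` — the λ factor converts
  energy to quantal units, constants dropped because only relative catches
  are output (von Kries or receptor-noise normalisations are downstream
  concerns). Receptors come from a `sensitivity_data.csv`-format table and
  are zero outside their tabulated support. Output is one 32-bit float
  TIFF per receptor.
- **Peak ratio**: the scene's dynamic-range statistic is the highest
  per-pixel spectral peak over the lowest, taken over *measured,
  unsaturated* pixels on both ends — interpolated pixels carry no
  independent information, and saturated pixels carry no valid radiance
  (a clipped lamp would understate the true maximum, so including it would
  not be conservative either).

## The synthetic world

`make_reference_scene()` provides deterministic ground-truth scenes: flat
and blackbody-like fields for identities and calibration; a narrowband
source set; and `hdr-night`, a night scene with a dim skyglow-like
background and point-like lamps with distinct emission spectra (sodium-like
narrow 589 nm, blue-pump LED-like, line-spectrum-like). The brightest
lamp's spectral peak is a constructed 70,000× the background peak —
"over 50,000:1", the contrast class this instrument exists to measure — and
an optional flare source saturates even at 500 µs to exercise saturation
handling (it is excluded from the constructed ratio because its radiance is
unmeasurable by design). Sources are hard discs 3° in radius at
grid-friendly azimuths; the pinhole approximation evaluates radiance at the
pose's central direction only.

What the generator does **not** emulate: optical point spread and glare
(the real optic's ~0.7°/cycle contrast limit), temperature dependence of
dark current and wavelength registration, source flicker, and motion
timing. A green test here therefore establishes the correctness of the
*decision logic and arithmetic* — exposure control, dark bookkeeping,
projection, calibration estimators, radiometric conversion — not the
radiometric accuracy of any physical unit, which requires a traceable
reference instrument.

## Numerical choices and degenerate inputs

- Boxcar compression averages a trailing partial window over its actual
  members (no padding), so the output length is `ceiling(n/window)`;
  window 1 is the identity. Window 2 halves 288 channels to 144 with
  minimal resolution loss given the sensor's ~9 nm FWHM.
- Gaussian smoothing truncates the kernel at 4σ, renormalises (constants
  are conserved exactly), and reflects at the boundaries, preserving the
  local mean near spectrum edges; σ = 0 is the identity.
- `r − d ≤ 0` linearises to 0 — negative noise excursions at low light are
  expected, not errors.
- Pole-skip counts use round-half-up (base R's `round()` is half-even);
  a row at the pole degenerates to its single middle column.
- Scan files are plain text, versioned from v1, with counts as integers
  (exact for the quantising ADC) and derived floats at 9 significant
  digits; writes are deterministic byte-for-byte. The original project's
  file layout is unpublished, so this format is newly specified here.
- The runtime backlash event log is not serialised in scan files (it
  documents mechanical behaviour, not data).

## Known limitations

- `b` from a single ladder is precise only to ~10% (see above); replicate
  ladders if the coefficient itself, rather than radiometric output, is of
  interest.
- The simulator's noise is Gaussian; true ADC quantisation is modelled but
  photon-counting statistics at extremely low counts are not.
- No compatibility with the original project's undocumented serial/file
  formats; a converter could be added if upstream documents them.
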