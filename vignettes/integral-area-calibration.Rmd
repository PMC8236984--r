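---
title: "Estimating chlorophyll a, cell density and primary productivity from OJIP integral areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chlorophyll a, cell density and primary productivity from OJIP integral areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojipcal)
```

## The method

Dark-adapted photosynthetic cells exposed to saturating light show the fast
chlorophyll-fluorescence induction rise, with characteristic inflections O
(origin), J (about 2 ms), I (about 30 ms) and P (the peak). Because both the
minimal fluorescence Fo and the variable fluorescence Fv = Fm − Fo scale with
the amount of photosynthetic pigment in the measuring volume, the **area under
the whole transient** — the integral area, in a.u.·µs — is a proxy for
phytoplankton chlorophyll *a*, for photosynthetic cell density, and (through
chlorophyll) for volumetric primary productivity. The workflow is:

1. record OJIP transients on water samples (`read_transient()`),
2. compute integral areas (`integral_area()`),
3. fit site-specific straight lines of the measured quantity on the integral
   area (`fit_linear()`), testing significance with Pearson's correlation
   (`correlation_test()`),
4. predict the quantity for new samples from their areas (`predict()`), and
5. for productivity, optionally anchor the OJIP-based estimates to light/dark
   bottle oxygen incubations (`cross_calibrate()`).

Calibrations are ordinary least-squares regressions of y on x, the direction
in which they are used for prediction. The p-value uses the exact
t-distribution with n − 2 degrees of freedom, because field calibrations
typically rest on small n.

## Units and display scales

The canonical internal time unit is the microsecond; integral areas are
stored in a.u.·µs. Field instruments recording ~10^4 a.u. over ~2 s spans
give areas of order 10^10–10^11, so calibration equations are conventionally
written with the area on a 1e10 display scale; `area_to_display()` /
`display_to_area()` convert explicitly, and calibrations carry labelled
`quantity()` objects for both axes so slopes keep their units. Chlorophyll
*a* is stored in mg L⁻¹ (the unit of calibration tables) with
`chla_mgL_to_mgm3()` for the mg m⁻³ that the empirical productivity formula
expects; productivity is mg C m⁻³ d⁻¹, with 1e2 / 1e5 display scales treated
as presentation metadata only.

## Productivity routes

Two routes are supported and deliberately kept separate:

* **Empirical formula**: P = K · r · c(Chl a) · DH, with K an experience
  constant, r the assimilation coefficient (mg biomass h⁻¹ mg⁻¹ Chl a) and
  DH the daily sunshine hours. K and r are site- and community-specific and
  are **not defaulted** — inventing values would fabricate results, so
  `productivity_params()` requires all three.
* **Direct calibration**: regress measured productivity on the integral area,
  then optionally compose with a correction line fitted against the oxygen
  method. `compose_linear()` composes two affine maps exactly
  (slope = a₂a₁, intercept = a₂b₁ + b₂); the composite carries no R² or
  p-value because fit statistics do not compose — refit on data if you need
  them.

The light/dark-bottle oxygen method converts net O₂ production to carbon with
0.375/PQ mg C per mg O₂; the photosynthetic quotient PQ defaults to 1.25, the
customary value for natural phytoplankton communities
(`oxygen_to_carbon()`). Negative net production (net heterotrophy) is
converted with a warning rather than rejected.

The methanol-extract chlorophyll determination uses the standard
two-wavelength formula 16.72·OD₆₆₅.₂ − 9.16·OD₆₅₂.₄ (µg mL⁻¹ of extract);
slightly negative results from noisy blanks are clamped to zero with a
warning because samples near the detection limit are a normal use case.

## Worked example

```{r worked}
# a published natural-water calibration: Chl a (mg/L) on integral area (1e10)
cal <- linear_calibration(0.594, -0.9021,
  x_quantity = quantity("integral area", "1e10 a.u.*us", 1e10),
  y_quantity = quantity("Chl a", "mg L-1"))
predict(cal, 12.40)   # -> 6.4635 mg/L

# oxygen-method anchoring of a productivity calibration
base <- linear_calibration(0.4576, -0.9835,
  x_quantity = quantity("integral area", "1e10 a.u.*us", 1e10),
  y_quantity = quantity("productivity (OJIP)", "1e2 mg C m-3 d-1"))
ojip <- c(0.8, 1.4, 2.2, 2.9, 3.6)
oxy  <- 12.199 * ojip + 8.1251
modified <- cross_calibrate(ojip, oxy, base)
equation_string(modified)   # y = 5.58226x - 3.87262
predict(modified, 6.38)     # -> 31.74 (1e2 mg C m-3 d-1)
```

## Numerical choices

* **Integration**: trapezoidal rule on *linear* time over the recorded span
  only, with no extrapolation to t = 0 or beyond the last sample. Instruments
  sample log-spaced, and the trapezoid on the recorded grid is the estimator
  whose magnitudes (10^10–10^11 a.u.·µs) the display convention assumes. On a
  smooth three-phase rise sampled at 256 log-spaced points it agrees with the
  analytic integral to well under 0.5%.
* **Fo**: the earliest recorded sample (the instrument's first reliable
  point), not an extrapolation to t = 0; `extract_features(f_o_points = k)`
  exposes averaging over the first k samples for noisy records.
* **J/I steps**: fixed nominal times of 2 ms and 30 ms with linear
  interpolation; values outside the recorded span are an error naming the
  step.
* **Non-monotone time is an error**, never silently sorted — shuffled rows
  usually mean a corrupted export.
* **Deviation columns**: validation tables in this field use both
  denominator conventions (reference measurement or OJIP estimate), so
  `relative_deviation()` requires the convention explicitly.

## The synthetic generator

`simulate_transient()` models the rise as
F(t) = Fo + Fv · Σₖ wₖ (1 − e^(−t/τₖ)) with three phases
(τ defaults 300, 10⁴, 2×10⁵ µs; weights 0.4/0.3/0.3), both Fo and Fv
proportional to chlorophyll *a* (defaults 2000 and 6000 a.u. per mg L⁻¹,
i.e. Fv/Fm = 0.75), sampled on 256 log-spaced points over 10 µs–2 s. Noise is
multiplicative Gaussian (1% default, detector shot-like) plus an additive
floor (sd 5 a.u., electronics/baseline), clamped at zero; everything is
seeded and bit-reproducible. The defaults place simulated areas in the
10^10–10^11 a.u.·µs range at mg L⁻¹ chlorophyll levels, commensurate with
field magnitudes, and make chlorophyll *a* down to 0.5 µg L⁻¹ detectable by
three-sigma screening against blanks (`detection_limit()`).

This is a *statistical* emulator, not a mechanistic PSII model: it guarantees
by construction the amplitude proportionality that integral-area calibration
relies on, and adds realistic noise. It does not reproduce state transitions,
stress-induced Fo rises, non-photochemical quenching, reabsorption at high
biomass, or species-dependent kinetic differences beyond what
`strain_profile()` kinetics overrides express. Passing recovery tests on
synthetic data therefore demonstrates correctness of the estimation chain,
not that any real water body is linear over an arbitrary biomass range.

Validation studies in the test suite use desk-scale problem sizes chosen to
exercise the statistics adequately: 30-point calibrations at 1% noise with
200 seeded replicates for slope-recovery coverage, 256-point grids for
integration accuracy, and 20 seeds for detection-limit monotonicity.

## Known limitations

* No depth-integrated water-column productivity, surface-light or mixed-layer
  corrections: the estimates are volumetric, at the sampled depth.
* No weighted, orthogonal or robust regression; calibrations are plain OLS
  of y on x.
* No full JIP-test parameter battery (energy fluxes, performance indices)
  and no curve smoothing or deconvolution.
* Binary instrument-native exports are out of scope; transients are exchanged
  as two-column delimited text with `#` metadata headers.
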