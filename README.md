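# ojipcal

Non-invasive estimation of phytoplankton chlorophyll *a*, photosynthetic
cell density, and aquatic primary productivity from the **integral area of
the OJIP chlorophyll-fluorescence transient**.

When dark-adapted algae are exposed to saturating light, fluorescence rises
through the characteristic O–J–I–P inflections within ~2 s. Both the minimal
(Fo) and variable (Fv) fluorescence scale with the photosynthetic pigment in
the measuring volume, so the area under the whole transient is a fast,
reagent-free proxy for biomass. `ojipcal` implements the full estimation
chain for people who monitor ponds, aquaculture systems and bloom-prone
waters with a handheld fluorometer:

* **I/O** — instrument-export-style readers/writers for transients
  (two-column delimited text, `#` metadata headers, explicit dialect and
  time-unit options) and for validation-style sample tables with display
  scales (`read_transient()`, `write_transient()`, `read_sample_table()`).
* **Features** — the trapezoidal integral area on linear time plus the basic
  JIP-test descriptors Fo, Fm, Fv/Fm, FJ (2 ms), FI (30 ms)
  (`integral_area()`, `extract_features()`).
* **Calibration** — OLS lines y = ax + b of the measured quantity on the
  integral area, with Pearson r, R², exact small-n p-values, significance
  labels, JSON persistence, prediction, inversion and percent-deviation
  utilities (`fit_linear()`, `predict()`, `invert()`, `correlation_test()`,
  `relative_deviation()`, `save_calibration()`).
* **Productivity** — the methanol-extract chlorophyll formula
  16.72·OD₆₆₅.₂ − 9.16·OD₆₅₂.₄, the empirical formula
  P = K·r·c(Chl a)·DH, light/dark-bottle oxygen-to-carbon conversion
  (0.375/PQ, PQ = 1.25 by default), and cross-calibration of OJIP
  productivity estimates against the oxygen method by exact composition of
  affine calibrations (`chl_a_from_absorbance()`, `productivity_from_chla()`,
  `oxygen_to_carbon()`, `compose_linear()`, `cross_calibrate()`).
* **Synthetic data** — a seeded three-phase-rise transient generator whose
  integral area is affine in chlorophyll by construction, with multiplicative
  and additive noise, community mixing and detection-limit estimation
  (`simulate_transient()`, `simulate_community()`,
  `generate_calibration_dataset()`, `detection_limit()`).
* **CLI** — `exec/ojip` with `simulate`, `features`, `calibrate`, `predict`
  and `productivity` subcommands over the same functions.

## Worked example

Applying a published natural-pond calibration (Chl *a* in mg/L on the
integral area in 1e10 a.u.·µs) to a validation sample, and anchoring a
productivity calibration to the oxygen method:

```r
library(ojipcal)

cal <- linear_calibration(0.594, -0.9021,
  x_quantity = quantity("integral area", "1e10 a.u.*us", 1e10),
  y_quantity = quantity("Chl a", "mg L-1"))
predict(cal, 12.40)
#> [1] 6.4635

base <- linear_calibration(0.4576, -0.9835,
  x_quantity = quantity("integral area", "1e10 a.u.*us", 1e10),
  y_quantity = quantity("productivity (OJIP)", "1e2 mg C m-3 d-1"))
ojip <- c(0.8, 1.4, 2.2, 2.9, 3.6)
modified <- cross_calibrate(ojip, 12.199 * ojip + 8.1251, base)
equation_string(modified)
#> [1] "y = 5.58226x - 3.87262"
predict(modified, 6.38)
#> [1] 31.74222
```

The first number says the water sample whose transient integrates to
12.40 × 10¹⁰ a.u.·µs carries about 6.46 mg/L chlorophyll *a*; the second is
its daily volumetric carbon fixation (×10² mg C m⁻³ d⁻¹) after benchmarking
the fluorescence method against light/dark-bottle incubations.

A fully synthetic end-to-end run:

```r
cfg <- synthetic_config(seed = 42)
d   <- generate_calibration_dataset(seq(1, 10, length.out = 12), cfg, seed = 7)
fit <- fit_linear(d$chl_a, d$integral_area_1e10)
equation_string(fit)
#> [1] "y = 1.56397x - 0.00785586"
detection_limit(cfg, seed = 11)
#> [1] 5e-04
```

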