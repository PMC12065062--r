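---
title: "Methods: chamber fluxes, water-balance ET and ecosystem-service summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber fluxes, water-balance ET and ecosystem-service summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agrobalance` implements the computational chain used in field-scale
comparisons of annual and perennial bioenergy cropping systems: soil
CO~2~ and N~2~O fluxes from static chambers, actual evapotranspiration
(ET) from profile soil-moisture sensors by a screened water-balance
method, FAO-56 reference evapotranspiration (ET~0~) for gap-filling,
water-use efficiency (WUE), root-profile and soil-carbon arithmetic, and
pore-water nitrate summaries. Every stage can be exercised end-to-end on
synthetic data with known ground truth, which is how the package tests
itself.

# Static-chamber fluxes

A closed chamber of headspace volume $V$ (m^3^) over basal area $A$
(m^2^) accumulates gas released by the soil. With mole fractions sampled
every 20 s for 5 min (16 points), the accumulation rate $b$ (ppm s^-1^)
is the ordinary least-squares slope of mole fraction on elapsed time,
over all points and with no deadband removal. The ideal gas law converts
the headspace molar inventory $n = PV/RT$ into a molar flux

$$F = b \times 10^{-6} \; \frac{PV}{RT} \; \frac{1}{A}
\quad [\mathrm{mol\,m^{-2}\,s^{-1}}],$$

expressed per element — carbon for CO~2~ (12.011 g mol^-1^) and nitrogen
for N~2~O (28.014 g mol^-1^, two N per molecule) — and scaled to
g m^-2^ day^-1^. The defaults encode 20.3 cm anchors and a 0.005 m^3^
dome headspace; the dome's shape means the volume is a supplied constant,
not derived from cylinder geometry.

Quality control retains and flags rather than discards: a deployment
with r^2^ < 0.7 *and* |slope| above a small-magnitude threshold
(0.002 ppm s^-1^ by default) is marked `low_r2`, because a near-zero
flux legitimately regresses poorly while a substantial slope with poor
linearity deserves scrutiny. Negative fluxes (uptake) are retained.

Same-day replicate chambers are averaged per plot, daily values are
linearly interpolated between consecutive sampling dates (never
extrapolated beyond the first or last), and the cumulative seasonal
emission is the sum of the daily series converted to kg element ha^-1^
(1 g m^-2^ = 10 kg ha^-1^). When the requested window extends beyond
the observed span the cumulation is clipped and the clipping reported,
so the edge-handling is always explicit.

# Reference evapotranspiration

`compute_et0()` implements the full FAO-56 Penman–Monteith daily chain
under the minimum-data route (sunshine hours rather than measured
radiation):

$$ET_0 = \frac{0.408\,\Delta\,(R_n - G) +
\gamma\,\frac{900}{T+273}\,u_2\,(e_s - e_a)}
{\Delta + \gamma\,(1 + 0.34\,u_2)}$$

with mean saturation vapour pressure from the temperature extremes,
actual vapour pressure from the humidity extremes, extraterrestrial
radiation from latitude and day of year, solar radiation via the
Angstrom formula ($a_s = 0.25$, $b_s = 0.50$ where uncalibrated), albedo
0.23, net longwave with the cloudiness and humidity corrections, soil
heat flux $G = 0$ at the daily scale, and wind adjusted logarithmically
to 2 m. Pressure is used as measured when supplied, otherwise from the
FAO-56 elevation approximation; the temperature in the aerodynamic term
is the mean of the daily extremes. The implementation is verified
against an independent step-by-step hand evaluation of every
sub-equation for a fully specified mid-July day, frozen into the test
suite.

# Water-balance evapotranspiration

Profile sensors at 30, 60 and 90 cm are integrated to total soil
moisture (TSM, mm) with the trapezoidal rule for nonuniform increments;
the surface-to-first-sensor layer takes the shallowest sensor's reading,
since nothing shallower exists. A uniform profile of 0.38 cm^3^ cm^-3^
thus maps to $0.38 \times 900 = 342$ mm; any convention that yields a
slightly different surface contribution would shift this constant, which
is why the surface rule is stated explicitly rather than assumed.

Field capacity (FC) is the mean TSM over the 30 days preceding crop
emergence — the profile recharges fully over winter, so pre-season
storage sits at FC. It is estimated site-level by default and per plot
on request.

Nightly drainage uses the 0000–0400 h window, when no ET is expected:
the hourly rate $(TSM_{0000} - TSM_{0400})/4$, clamped at zero, scaled
by 24 gives the daily loss $Q$. Days enter the ET calculation only if
they pass three screens, applied in order: no midnight-to-midnight net
gain; no precipitation on the day or the three preceding days; storage
at or below FC. For an included day $j$,

$$ET_j = (TSM_j - TSM_{j+1}) - Q_j.$$

The subtraction of $Q$ is a deliberate design choice: water that left
the profile by gravity did not evapotranspire, so the physical balance
removes it from the storage depletion. The additive form
($+Q$) is available behind the `eq1_literal` switch for comparison; on
retained days storage sits at or below FC, so $Q \approx 0$ and the two
conventions nearly coincide — which is presumably how the ambiguity
survives in practice. A negative balance marks the day excluded rather
than reporting negative ET.

Excluded days are gap-filled by scaling that day's ET~0~ with the most
recent prior measured ET:PET ratio (configurable to an average of the
last $k$ ratios via `ratio_window`; leading days back-fill with the
first available value). Every season day is therefore exactly one of
*measured* or *gap-filled*, and the cumulative ET is the sum of both
classes. WUE is aboveground dry biomass divided by cumulative seasonal
ET. Because per-plot WUE averaged across plots differs from the ratio of
mean biomass to mean ET whenever plots differ, the pipeline emits both
conventions (`wue_mean` and `wue_ratio_of_means`).

## Known limitations of the estimator

Two properties of this estimator deserve emphasis; both are visible in
the package's own truth-recovery experiments.

* **Noise amplification in $Q$.** The nightly-drainage rate multiplies
  the overnight TSM difference by six. Reading-to-reading sensor noise
  of even 0.2 mm TSM-equivalent creates a clamped, strictly positive
  phantom drainage of several tenths of a millimetre per day. The
  method works with capacitance sensors because their short-term
  repeatability is far below their 0.001 cm^3^ cm^-3^ reporting
  resolution — consecutive readings repeat under stable conditions. On
  instruments (or derived series) without that stability the estimator
  degrades quickly.
* **Ratio lag under canopy development.** The carried ET:PET ratio
  looks backward. While the crop coefficient rises steeply (canopy
  closure over 5–6 weeks), gap-filled days systematically inherit
  too-small ratios; in wet springs, where most days are excluded, this
  produces a low bias of several percent in cumulative ET even with
  perfect ratios — an inherent property of backward carry, partially
  offset in senescence when the lag works the other way. This is
  consistent with water-balance ET estimates in the literature sitting
  below satellite-based estimates at the same sites.

# Biomass, roots and soil carbon

Dry yields remove harvest moisture (wet basis) and scale the sampled
area to a hectare. Corn aboveground biomass expands dry grain through
the standard harvest index of 0.545 ($AGB = grain/HI$), applied after
moisture removal. Switchgrass AGB is the mean of quadrat dry yields.
Root-profile totals are always recomputed from the depth increments —
printed totals elsewhere occasionally disagree with their own increments
by rounding, so the increments are authoritative. Soil carbon stock per
layer is $c \; [\mathrm{g\,kg^{-1}}] \times \rho_b \;
[\mathrm{g\,cm^{-3}}] \times d \; [\mathrm{cm}] \times 0.1$ Mg C ha^-1^.

# Leachate

Pore-water NO~3~-N samples are summarised by crop, year and depth as
mean ± SE, with replicate samplers averaged within plot-date first so
the plot-date is the statistical unit. Relative reduction between crops
is $(\bar{x}_{ref} - \bar{x}_{alt})/\bar{x}_{ref} \times 100$.
Concentrations below detection are retained at face value unless a
substitution rule is configured. Group statistics throughout the package
are descriptive; mixed-model inference is deliberately out of scope.

# The synthetic study

`synth_scenario()` generates every pipeline input with known truth. The
default mirrors a central-Illinois field trial: 6 plots (corn and
switchgrass × 3 blocks), three seasons, sensors at 30/60/90 cm, three
chambers per plot sampled weekly, two sampler depths for leachate.

* **Weather** — sinusoidal seasonal temperature (annual mean 11 °C,
  amplitude 14 °C, peak at day 196) with Gaussian day noise; first-order
  Markov wet/dry occurrence (unconditional wet-day frequency 0.33,
  wet-day persistence 0.55 — the clustered storms and multi-day dry
  spells of Midwest summers) with gamma depths (mean 10 mm), giving
  ≈ 600 mm April–September; a `drought` preset thins events to ~72% of
  normal, the magnitude of a dry year at such sites. Humidity, sunshine
  (bounded by astronomical daylength) and wind stay within physical
  ranges.
* **Soil moisture** — an hourly bucket: precipitation recharges storage,
  drainage removes 8% h^-1^ of any excess above FC (340 mm), and the
  daily true ET is withdrawn on a diurnal curve that is exactly zero
  between 0000 and 0400 h, so the generator honours the assumption the
  estimator relies on. True ET is a crop-coefficient curve times the
  day's ET~0~ times a lognormal day factor (sd 0.10); the kc curves
  (bare 0.15, full 0.60–0.65) are calibrated so seasonal true ET lands
  near 300 mm, the magnitude reported by water-balance studies in this
  region. ET throttles linearly as storage approaches a 200 mm wilting
  floor. TSM is disaggregated to sensor depths with fixed weights
  (larger swings nearer the surface) chosen so trapezoidal
  re-integration reproduces TSM exactly; each sensor then receives a
  constant calibration offset (sd 0.01 cm^3^ cm^-3^ — the dominant
  error of capacitance sensors, which differencing cancels), per-reading
  jitter (sd 5 × 10^-5^), and quantisation to the 0.001 cm^3^ cm^-3^
  logger resolution. The jitter sits well below the quantum
  deliberately: that is how these instruments behave, and it is the
  property that lets the 0000–0400 h window isolate drainage.
* **Chambers** — the true flux schedule follows a Q~10~ temperature
  response for CO~2~ (higher base rate under switchgrass, reflecting
  root-associated respiration) and a fertiliser-pulse-plus-rain
  response for N~2~O (larger under the higher-N annual). The ideal-gas
  relation is inverted to produce the concentration slope, and 16-point
  ramps receive Gaussian analyser noise (1 ppm CO~2~, 0.005 ppm N~2~O).
* **Leachate** — lognormal samples (sd~log~ 0.3) around stationary corn
  means (12 and 8 mg L^-1^ at 30 and 90 cm) and switchgrass means
  reduced by a configured year-indexed percentage (20, 60, 80% —
  establishment-year parity giving way to a mature-stand decline).
* **Biomass** — harvest records at machine moisture (corn grain, 18%)
  or oven moisture (switchgrass quadrats, 10%) around per-crop-year
  truth values.

What the generator does **not** emulate: spatially correlated rainfall,
runoff and lateral flow, water-table dynamics, mechanistic N~2~O process
chemistry, sensor drift and failure modes beyond a constant offset, and
measurement-day logistics (missed samplings, chamber disturbance).
Passing truth-recovery tests therefore demonstrates the correctness and
statistical behaviour of the computations, not the field accuracy of
the underlying assumptions on any particular soil.

# Numerical and design choices

* Season windows are April 1 – September 30; growing-season climate
  aggregation follows this convention, which reproduces the printed
  seasonal rows of the packaged Urbana monthly table exactly.
  Crop-specific cumulation windows remain configurable.
* Midnight and 0400 h readings are the nearest sensor record within
  ±15 min of the nominal time; otherwise the day is `q-unavailable` and
  gap-filled.
* Screening reasons are recorded with a fixed priority (net-gain, then
  precip-window, then above-fc), so each day carries exactly one reason.
* TSM is mm internally; VWC tables are cm^3^ cm^-3^; conversions are
  explicit.
* The cumulative-ET recovery check is evaluated at the scenario level
  (all plot-seasons pooled, the unit at which such studies report ET).
  Individual plot-seasons scatter roughly ±10–15% around truth, with
  occasional larger misses when a rain run spans the entire canopy ramp
  and no measured ratio exists inside it.
* Problem sizes in the packaged tests: three seasons × six plots of
  hourly three-depth sensor logs (~280k readings), ~2500 chamber
  deployments, 200-chamber noise ensembles, 500-season climate
  calibration; these sizes keep the whole suite around a minute while
  leaving Monte-Carlo error well below the tested tolerances.

# Reproducibility

All generators are pure functions of a `truth_params` object and its
seed; two pipeline runs with the same configuration produce identical
artifacts (the run log's timestamp aside), and the run log records the
seed and a hash of the configuration.
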