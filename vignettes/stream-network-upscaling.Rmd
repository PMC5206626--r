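---
title: "Upscaling stream CH4 and CO2 emissions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upscaling stream CH4 and CO2 emissions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamghg)
```

## The problem and the model

Stream networks emit CH4 and CO2 through the water surface wherever the
dissolved concentration exceeds the atmospheric equilibrium. The flux from
a reach on a day is

$$F = k_g\,(C_{aq} - C_{eq}), \qquad C_{eq} = K_H(T)\,p_{gas},$$

where $k_g$ (m d$^{-1}$) is the gas transfer velocity of the specific gas
at the in-situ temperature, $C_{aq}$ is the dissolved concentration and
$C_{eq}$ its Henry's-law equilibrium with the atmosphere. Concentrations
are carried in μM throughout, which is numerically identical to
mmol m$^{-3}$, so $F$ comes out in mmol m$^{-2}$ d$^{-1}$ with no hidden
unit factors; conversions happen only at I/O boundaries.

Transfer velocities are compared across gases and temperatures through the
Schmidt number $Sc(T) = \nu/D$: $k_{600} = k\,(600/Sc)^{-1/2}$, with 600
the Schmidt number of CO2 at 20 °C in freshwater. `k600_from_k()` and
`k_gas_from_k600()` are exact inverses, which the suite asserts.

Neither $k_{600}$ nor the concentrations can be measured everywhere, so
the upscaling rests on three sub-models:

1. **Tracer injections → measured $k_{600}$.** A volatile, inert tracer
   (propane) is injected at the top of a reach; its first-order loss over
   the travel time $\tau$, with the downstream concentration rescaled by
   the discharge ratio to undo groundwater dilution, gives
   $\mathrm{rate} = \tau^{-1}\ln[(C_U Q_U)/(C_D Q_D)]$, and
   $k = \mathrm{rate}\times 1440 \times \bar h$. When $Q_U = Q_D$ this is
   exactly the uncorrected log-ratio rate, and the result is invariant to
   the arbitrary scale of the relative tracer concentrations.
2. **Regressions → modelled $k_{600}$ everywhere.** Velocity is predicted
   from discharge and slope, and $k_{600}$ from velocity and slope, both
   on log10 scales (defaults in `velocity_model()` / `k600_model()`). The
   daily discharge of every reach comes from the proportionality
   $D = bA$ fitted each day across the gauging stations (through the
   origin, as the relation has no intercept). Predictions are
   back-transformed with the smearing correction and multiplied by a
   measured-vs-modelled calibration factor (default 0.89).
3. **Surveys + anchors → concentrations everywhere.** Spatial surveys are
   interpolated along the network and expressed as ratios to temporally
   resolved anchor stations; each reach's daily series is its ratio times
   its anchor's gap-filled series. The method's core assumption is that
   the field is *separable* — a static spatial pattern times a temporal
   signal — and the reconstruction is exact precisely when that holds,
   which the suite verifies on a zero-noise synthetic world.

Fluxes are integrated per reach-day (ice periods excluded), summed to
annual totals (CH4 in kg yr$^{-1}$, CO2 in Mg yr$^{-1}$, molar masses
16.04 / 44.01 g mol$^{-1}$), converted to CO2-equivalents (GWP 28 over a
100-year horizon, overridable), and summarised as ratio tables by slope
category (S1–S5) and discharge-ratio bin.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dz` | 0.5 | m | elevation drop per reach; makes steep reaches short, resolving hot spots |
| `v_cap` | 0.7 | m s$^{-1}$ | upper end of the velocity range covered by injections; the $k_{600}$ model is never extrapolated above it |
| `calibration` | 0.89 | – | slope of measured vs modelled $k_{600}$ (through the origin); removes overestimation in the high range |
| `slope_floor` | 0.05 | % | lower bound before log10(slope); the flattest category starts at 0 where the log is undefined |
| `despike_threshold` | 0.2 | – | sensor values deviating >20 % from both 12-h window means are condensation artefacts |
| `ice_min_run` | 3 | d | days inside runs of more than 3 consecutive sub-zero days are treated as ice-covered |
| `gwp` | 28 | – | CH4 global warming potential, 100-yr horizon |
| `atm_ch4_ppm`, `atm_co2_ppm` | 2.0, 405 | ppm | atmospheric mixing ratios used for $C_{eq}$ |

All of these sit in `pipeline_config()`; every override is a visible
argument, never a hidden global. The equilibrium temperature is always the
record's water temperature, passed explicitly.

## Physical-chemistry choices

* **Schmidt polynomials.** CH4 and CO2 use fourth-order freshwater
  polynomials in temperature. The fourth-order fits are preferred over the
  older third-order ones because they reproduce the definitional anchor of
  the normalisation — Sc(CO2, 20 °C) rounds to exactly 600 — which the
  third-order fit misses (599.4).
* **Propane.** No polynomial is in common use, so $Sc = \nu(T)/D(T)$ with
  $\nu$ from a standard pure-water viscosity/density correlation and
  $D(T)$ an Arrhenius fit anchored to the classical propane diffusivity
  measurements ($D(10\,°C)=0.80\times10^{-5}$,
  $D(25\,°C)=1.15\times10^{-5}$ cm$^2$ s$^{-1}$, giving
  $E_a \approx 17$ kJ mol$^{-1}$). The fit parameters are exposed on
  `gas_spec("C3H8")` so alternative diffusivity data can be swapped in —
  the choice of diffusivity source measurably shifts propane Schmidt
  numbers and hence all downstream $k_{600}$.
* **Henry constants.** CO2 uses the freshwater molar solubility fit
  $\ln K_H = a_1 + a_2(100/T) + a_3\ln(T/100)$; CH4 the corresponding
  freshwater Bunsen fit divided by 22.414 L mol$^{-1}$; propane a van't
  Hoff extrapolation. All are positive and strictly decreasing over
  0–30 °C (asserted). At 2.0 ppm and 10 °C the CH4 equilibrium is
  0.004 μM to one significant figure; at 405 ppm and ~7–8 °C the CO2
  equilibrium is ~23.5 μM.

## Numerical choices and conventions

* **Smearing (Newman) correction.** Back-transforming a log10-scale
  prediction is biased low; the package multiplies $10^{\hat y}$ by
  $\exp(\mathrm{MSE}\,\ln(10)^2/2)$, with MSE the residual mean square of
  the fitted model (factor exactly 1 at MSE 0). The correction is applied
  *before* the 0.89 calibration, and the velocities fed into the
  $k_{600}$ model are the corrected ones; the alternative orders are not
  distinguishable from the published material, so this order is fixed and
  documented here.
* **Flux-based tracer cross-check.** `flux_based_k()` derives $k$ from the
  general flux relation, treating the tracer loss over the travel time as
  a flux out of a water column of the mean depth with $C_{eq} = 0$. The
  driving concentration is the *log-mean* of the corrected endpoint
  concentrations — the exact average seen by a parcel under first-order
  loss — so the route agrees with the rate-based one identically. With an
  arithmetic mean instead, the two routes would diverge by far more than
  the observed "almost identical" agreement at the high tracer losses
  (>60 %) that steep cascade reaches produce, so the log-mean is the only
  discretisation consistent with the method's own physics. The test suite
  still runs both code paths against each other over simulated campaigns.
* **Velocity cap.** Above `v_cap` the model returns the reach's maximum
  below-cap $k_{600}$ *up to that date* (a running maximum); if a reach
  exceeds the cap before any below-cap day, the model evaluated at the cap
  is used, with a warning. "Reach-specific maximum" admits several
  readings; the running maximum never uses information from the future.
* **Boundary conventions.** Slope categories are half-open and
  lower-inclusive (a 1.0 % reach is S2). Discharge-ratio bins are
  lower-inclusive except the first, which is $\le 1$ — most days sit at or
  below the mean, and the first bin must contain them.
* **Discretisation.** Local elevation rises (DEM noise) are flattened to
  zero drop with a warning before segmentation; reach boundaries are
  found by inverting the cumulative-drop curve, placed at the first point
  reaching the target drop when the curve is flat; the final partial
  reach is kept. Total length and relief are conserved exactly (asserted).
* **Confluences and anchors.** At a confluence the downstream branch
  starts from the drainage-area-weighted mean of the merging endpoint
  values — under $D = bA$ this is discharge weighting, the mass-consistent
  choice. Each reach maps to the nearest anchor by along-network distance.
  Both choices are undetermined by the published description; both are
  isolated in single functions.
* **Negative tracer rates** (apparent downstream tracer gain) are
  physically impossible; they are returned, flagged with a warning, and
  excluded from model fitting as NA $k_{600}$.
* **Calibration factor** is a regression through the origin (a pure
  rescaling); an intercept variant exists behind a flag but is not the
  default, since an additive offset has no physical reading here.

## The synthetic world

`catchment_scenario()` states the world once; the generators derive
everything from its seed (two seeds differing by one produce entirely
different worlds, the same seed byte-identical ones).

* **Network**: 5 branches, 6.4 km, outlet at 51 m elevation, ~7 km²
  drainage. Slope-category length budgets equal the areal targets
  (90.5/5.2/2.6/0.7/0.9 % for S1–S5), so the hot-spot structure is present
  by construction; segment order and within-category slopes are random.
  With 0.5 m reaches this yields ~95–100 reaches.
* **Discharge**: $b(t)$ = base runoff 8 L s$^{-1}$ km$^{-2}$ × seasonal
  cycle × lognormal AR(1) × storm events (Poisson, ~12 yr$^{-1}$,
  multipliers 3–10 decaying over ~1.5 d). This keeps $b$ inside the
  plausible 0.2–315 envelope while guaranteeing days above four times the
  mean discharge, so every hot-moment bin is populated. Station noise is
  5 % lognormal.
* **Temperatures**: sinusoidal air temperature (mean 7 °C, amplitude
  10 °C) crossing zero in winter, which drives multi-day ice runs; water
  temperature is a damped cycle floored at 0.2 °C.
* **Concentrations**: separable by construction,
  $C = R(\mathrm{reach})\,G(t)$. $R$ is lognormal at the survey nodes with
  sdlog 1.0 for CH4 and 0.3 for CO2 — CH4 spatial variability in such
  catchments is far larger than CO2's, and these values keep the minimum
  CH4 concentration near 0.01 μM (a few-fold supersaturated) while CO2
  never falls below its cold-water equilibrium. $G$ is lognormal AR(1):
  piecewise-linear between biweekly knots for CH4 (the manual sampling
  cadence), daily for CO2 (sensor daily means); levels 1.5 μM and 150 μM.
  Observation noise is multiplicative lognormal, sdlog 0.1 — a realistic
  combined analytical and sampling error.
* **Hydraulics and injections**: velocity and $k_{600}$ sit on the model
  surfaces with log10 noise SDs $\sqrt{0.006}$ and $\sqrt{0.050}$ — the
  residual scales of the shipped models. 53 injections are simulated in
  three near-flat and three steep end-member reaches by the forward
  dilution model $C_D = C_U e^{-\mathrm{rate}\,\tau}(Q_U/Q_D)$, with
  groundwater inflow fractions 0.06–0.5 %.

**What a green end-to-end test establishes — and what it does not.** On a
noiseless scenario the pipeline reproduces the generator's annual totals
to floating-point accuracy. This validates the plumbing (discretisation,
scaling, fitting, reconstruction, unit chain) under the method's own
assumptions: a separable concentration field that is piecewise-linear
between survey nodes, $k_{600}$ exactly on the regression surface, and
exact $D = bA$ proportionality. Real catchments violate all three; the
noisy scenario probes robustness to observation error, but neither
scenario can expose structural errors such as a non-separable field,
ebullition, or rating-curve nonlinearity. Green tests bound the numerical
correctness of the implementation, not the field accuracy of the method.

## Interpretation decisions recorded here

* Coefficient-recovery testing treats the 95 % CI coverage *per
  coefficient* (each should cover the truth in ≥90 % of replicates); the
  joint event that all three CIs cover simultaneously is expected below
  90 % even for a perfectly specified model.
* One $k_{600}$ is computed per observation row of an injection table
  (replicate downstream samples are rows), not one per injection.
* Reach depth for the rate-to-k conversion is the per-campaign mean reach
  depth.
* Where surface areas are needed for unmeasured reaches, the profile must
  carry widths (the generator uses a width–drainage power law,
  $w = 0.8A^{0.4}$); the package does not invent widths.
* Days whose concentration is still missing after gap-filling are
  excluded from totals, and the exclusion fraction is reported in the
  summary.

## Known limitations

* Only diffusive, water-side-limited exchange is modelled: no ebullition,
  no microbubble pathway, no chemically enhanced CO2 exchange, no
  carbonate-system speciation (CO2 is treated as the dominant DIC form).
* Freshwater solubility and Schmidt functions only; not valid for saline
  systems.
* The concentration reconstruction cannot represent spatial patterns that
  change between surveys beyond what the ratio CV captures; the resulting
  uncertainty is propagated as the conservative maximum ratio CV.
* The discharge scaling assumes strict area proportionality each day;
  rating curves, routing and hysteresis are out of scope, as is any GIS
  processing — the package consumes an already-extracted longitudinal
  profile.
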