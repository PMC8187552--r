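---
title: "Methods: closing upper-ocean C-N-P budgets from nanomolar nutrient fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closing upper-ocean C-N-P budgets from nanomolar nutrient fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpbudget)
```

## The scientific problem

Subtropical gyres are chronically nutrient-depleted: surface nitrate+nitrite
(N+N) and phosphate (PO₄) sit at tens of nanomoles per litre, below the
detection limits of conventional autoanalyzers. Net community production
(NCP) is nonetheless positive, which poses a supply problem: where do the
nitrogen and phosphorus that sustain the annual carbon uptake come from?
This package implements a budget-closure answer. Nanomolar-sensitive
nutrient profiles are combined with microstructure turbulence measurements
to quantify the upward diffusive supply of DIC, N+N and PO₄ into the
euphotic zone; atmospheric-side terms (air–sea CO₂ flux, N₂ fixation, N and
P deposition) complete the influx; and under an annual steady state the
total influx of each element equals its NCP requirement. Comparing the NCP
requirements with the elemental demand implied by microbial C:N:P
stoichiometry yields a recycling factor — the number of times an element
must be re-used within the euphotic zone.

## Model and assumptions

For each element Y ∈ {C, N, P},

$$\mathrm{NCP\text{-}Y} = F^{up}_Y + F^{at}_Y,$$

assumed at steady state over the annual cycle. The assumptions doing real
work are:

* **Steady state** — net uptake and export balance annually, so influx
  equals requirement.
* **Negligible lateral fluxes** — no significant horizontal surface
  gradients in the gyre interior; lateral and migrating-diatom transports
  are hard-coded to zero (an override exists in the forcing container for
  sensitivity work).
* **Osborn diffusivity** — $K_z = \Gamma\,\varepsilon/N^2$ with a fixed
  mixing efficiency $\Gamma = 0.2$ (argument `mixing_efficiency`; the
  canonical choice, uncertain to a factor of ~2 in the literature).
* **Mixed-layer fluxes excluded** — diffusive fluxes computed above the
  MLD are not influxes from outside the mixed layer; they are exposed for
  inspection but never enter budget terms.
* **Season ↔ SST-regime equivalence** — the four regimes (<24, 24–26,
  26–28, >28 °C) stand in for season; annualization multiplies the
  regime-mean daily flux by the days each regime occupies in the monthly
  SST climatology.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| mixing efficiency Γ | 0.2 | – | Osborn relation's canonical value |
| MLD criterion | 0.2 | °C below θ(10 m) | standard threshold criterion for subtropical profiles |
| EZD criterion | 1 % | of surface PAR | conventional euphotic-zone floor |
| reference salinity | 34.91 | – | regional mean; removes evaporation/precipitation dilution |
| detection substitution | N+N → 5, PO₄ → 3 | nM | nominal values for below-detection samples (limits 3 nM) |
| SST regime edges | 24, 26, 28 | °C | quartile-like seasonal partition of the 20.2–30.5 °C range |
| C:N, C:P | 6–11, 107–243 | mol/mol | measured stoichiometry of subtropical picoplankton |
| N₂ fixation | 2.2×10⁻⁴ ± 6.4×10⁻⁵ | mol N m⁻² d⁻¹ | regional climatological mean (¹⁵N₂ dissolution method) |
| N deposition | 2.7×10⁻⁵ ± 5.7×10⁻⁶ | mol N m⁻² d⁻¹ | regional aerosol-transect mean |
| P deposition | 8.4×10⁻⁸ ± 5.4×10⁻⁸ | mol P m⁻² d⁻¹ | regional aerosol-transect mean |

## Numerical choices

* **Grids and stencils.** Fluxes live on the instrument's 5-m grid.
  Bottle concentrations are linearly interpolated onto it (no
  extrapolation beyond the sampled range); gradients use centered
  differences at interior points and one-sided differences at the ends.
  Centered differencing is symmetric and equals the average slope of the
  piecewise-linear interpolant, which is the natural reading of pairing
  5-m $K_z$ with 5-m $\partial X/\partial z$.
* **Masking, not infinities.** Bins with $N^2 \le 0$ produce no
  diffusivity; they are masked and the masked fraction is logged. Layer
  means average the remaining valid points, unweighted, with depths
  strictly inside (top, bottom] — unweighted because the grid is uniform
  except where masking bites, and no thickness information distinguishes
  masked bins.
* **Negative fluxes are retained.** Downward (negative) layer means are
  physically meaningful and are never clipped.
* **Interpolation conventions.** MLD interpolates linearly in θ–z (the
  profile between bottles is treated as linear; a boundary hit at a
  sampled depth returns that depth exactly). EZD interpolates
  log-linearly in PAR–z because light decays exponentially; this makes
  the inversion exact for an exponential profile. Profiles that never
  meet a criterion return the deepest sampled depth with an explicit
  flag rather than NA.
* **Inventories.** Trapezoidal rule on the piecewise-linear interpolant;
  endpoints inside the sampled range are interpolated, outside it the
  nearest sample is extended as a constant (relevant only for degraded
  casts, since standard casts start at 0 m).
* **Potential temperature and density.** Input temperature is treated as
  potential temperature — at ≤ 200 dbar the adiabatic correction is
  ≈ 0.02 °C, an order of magnitude below the 0.2 °C MLD criterion.
  Potential density uses the EOS-80 one-atmosphere polynomial
  (surface-referenced); the N² tests pin the finite-difference
  construction with a prescribed two-level density profile rather than
  any particular equation of state's digits.
* **Calendar.** Days per month are a uniform 365/12, so regime days
  always sum to 365 regardless of which months fall where.
* **Regime bins.** Half-open with the lower edge inclusive ([24, 26)
  etc.), fixing the behaviour at exact boundary temperatures.
* **Error propagation.** 95 % CIs combine in quadrature for sums and
  differences. For quotients the default divides both half-widths by the
  denominator mean, $(M_1/M_2)\sqrt{(E_1/M_2)^2+(E_2/M_2)^2}$; the
  standard relative-error form with $E_1/M_1$ is selectable
  (`quotient_form = "standard"`), and the package logs a message whenever
  the two differ by more than 1 % so the convention choice is visible in
  the run log. Sample means use Student-t intervals because regime
  samples are small (n ≈ 3–10); a normal-quantile variant exists.
* **Annualization order.** Each regime's flux CI is scaled by its days
  first, then regimes are summed in quadrature (scale-then-sum).
* **Rank tests.** Kruskal–Wallis (base R, tie-corrected) for the omnibus
  comparison; Dunn's z-tests on mean ranks with pooled tie correction for
  the follow-up, judged against the Bonferroni threshold 0.05/6 ≈ 0.0083
  for four regimes. Degenerate all-identical input returns H = 0, p = 1.

## The synthetic cruise generator

`generate_cruise_dataset()` emulates the statistical structure the
analysis assumes, not ocean physics:

* **Sampling design** — 13 cruises × 5 stations near 24°N, bottles at 0,
  10, 25, 50, 75, 100, 125, 150, 200 m; cruise months chosen so every SST
  regime is sampled.
* **Seasonality** — a single annual SST sinusoid (20.21 °C in January to
  30.51 °C in July). Each seasonal variable is phase-locked to it, and
  its anomaly is rescaled by the cool/warm contrast of the seasonal basis
  over the cruise months, so a configured amplitude (20 nM N+N, 15 nM
  PO₄ at the surface, 1.9 mol m⁻² of 0–100 m DIC inventory) *is* the
  expected cool-minus-warm regime difference. Parameter recovery by the
  downstream inventory-difference operation is therefore a designed
  property, verified by Monte-Carlo averaging in the tests.
* **Vertical structure** — an isothermal mixed layer (shallower than
  50 m when SST > 28 °C, deepening to ~100 m in winter) over a linear
  thermocline to 16 °C at 200 m; nanomolar nutrient surface values above
  100 m rising linearly to micromolar values at 200 m (3.5 µM N+N,
  0.25 µM PO₄); DIC increasing at 3.5×10⁻⁴ mol m⁻⁴ at depth, with the
  seasonal surface anomaly confined above 100 m so the subsurface
  gradient that feeds the upward flux is season-independent.
* **Turbulence** — ε log-normal i.i.d. per 5-m bin (median 2×10⁻⁹
  W kg⁻¹, log-sd 1.0 — typical thermocline values yielding
  $K_z \sim 10^{-6}\text{–}10^{-5}$ m² s⁻¹); N² is computed from the
  cast's own T/S, so the mixed layer is unstratified and its bins are
  masked, exercising the masking path on every run.
* **Noise** — measurement-precision scale only: DIC sd 2×10⁻³ mol m⁻³
  (per sample and as a cast-level batch offset), nutrients 2 nM, SST
  0.2 °C, salinity 0.02 around 34.91.
* **Forcing** — the climatological rates in the table above; per-regime
  monthly CO₂ fluxes (0.10, 0.07, 0.04, −0.01 mol C m⁻² mo⁻¹) chosen so
  the annual air–sea term is ~0.7 mol C m⁻² y⁻¹ and the warm regime
  outgasses, matching the regional pattern of a CO₂ sink with summer
  reversal.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mesoscale eddies, typhoons and other episodic
mixing events; spatial covariance between stations; within-regime
environmental variance beyond measurement noise (the within-regime
variance of real fluxes is unknown and is left as a free parameter rather
than asserted); DIC/nutrient covariation through biology; and any
circulation. Real-data regime means will be noisier and their CIs wider
than the synthetic ones.

One structural bias is worth knowing: casts from months climatologically
just below an SST regime edge can cross it through realized-SST noise,
carrying part of a seasonal anomaly into the neighbouring regime. This
attenuates recovered regime contrasts by a few percent — a faithful
consequence of classifying on observed SST, not a bug.

## Problem sizes

The default scenario (65 casts, 41-level turbulence profiles) runs the
full pipeline in about a second; the test suite uses this size throughout,
plus 6-cruise variants where a full seasonal cycle is not needed. The
acceptance script runs one full default-scenario pipeline per invocation;
the demand/recycling/share chain is closed-form arithmetic on the stated
budget inputs.

## Known limitations

* The Osborn Γ = 0.2 is treated as exact; its factor-~2 uncertainty is
  not propagated.
* CO₂ flux enters with zero CI (a modelled monthly product is the input);
  the C budget's CI therefore reflects only the upward term.
* The quotient-CI convention produces very wide ratio intervals when the
  denominator (NCP-P) is orders of magnitude smaller than the numerator;
  the standard form is available where that is unacceptable.
* Annualization assumes the regime partition of the monthly climatology
  transfers to the cruise sampling; months with no cruise in a regime
  would contribute zero flux (with a logged warning) rather than an
  imputed value.
* The Friedman station-pooling test and instrument-level ε processing are
  out of scope; ε is an input.
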