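---
title: "From land-surface phenology to sowing dates to simulated maize yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From land-surface phenology to sowing dates to simulated maize yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosow)
```

## The problem

Regional crop-yield assessment in data-scarce rainfed systems needs two
things a crop growth model cannot supply for itself: management inputs
(above all the sowing date, which varies by weeks across a landscape and
between years) and independent observations to evaluate against. Both can
come from satellite land-surface phenology (LSP). This package implements
that synthesis for maize at "grid" (a cluster of satellite pixels) and
"region" (sub-county, the scale at which official yields are reported)
levels:

1. decode WaPOR-convention seasonal phenology rasters (start, maximum and
   end of season — SOS/MS/EOS — encoded as *dekads*);
2. model per-pixel NDVI time series with a harmonic regression and
   retrieve the sowing date as the zero-gradient minimum of the fitted
   curve closest before SOS;
3. drive a reduced CERES-style daily maize simulator (thermal-time
   phenology, radiation-use-efficiency growth, Priestley–Taylor
   evapotranspiration, tipping-bucket soil water balance) with the
   retrieved dates;
4. evaluate: peak-season timing against MS (squared Pearson correlation),
   regional mean yield against reported yields, per-grid seasonal ET
   deviation against a reference ET product, and a ±30-day sowing-shift
   sensitivity experiment.

A seeded synthetic-scenario generator stands in for the satellite, weather
and ministry data, with known ground truth, so every stage is testable at
desk scale.

## Dekad encoding

A dekad is a calendar ten-day interval: days 1–10, 11–20, and 21 to month
end, three per month, 36 per year. A phenology layer for a target year
spans three calendar years — 108 dekads — with the target year at indices
37–72 (index 37 = first ten days of January). `dekad_decode()` and
`dekad_encode()` are exact inverses over the whole window, month-tail
dekads end on the true month end (including leap February), and
`dekad_midpoint_doy()` gives the interval midpoint as a day-of-year for
comparison with daily model output. Grid-level phenology is the
per-attribute median of the member pixels; on even counts we take the
*lower* median so the aggregate is always a dekad some pixel actually
reported. Records whose median triple violates sos < ms < eos are flagged
rather than dropped silently.

## Harmonic NDVI model

NDVI series from optical sensors are noisy and gappy (clouds, atmospheric
artefacts). We fit, by ordinary least squares,

$$\mathrm{ndvi}(t) = c_0 + c_1 t + \sum_{k=1}^{K}
  \left[a_k \cos\frac{2\pi k t}{P} + b_k \sin\frac{2\pi k t}{P}\right],$$

with $t$ in days from the first retained observation and base period
$P = 365.25$ d. The additive part is an intercept plus a linear trend;
each harmonic pair has the polar form amplitude
$\sqrt{a_k^2+b_k^2}$ / phase $\mathrm{atan2}(b_k, a_k)$. Observations
flagged bad are excluded before fitting; an optional one-pass 3·MAD
residual screen handles unflagged artefacts. The fit requires at least
$2K+3$ clear observations and errors out on rank-deficient designs.

`fit_harmonic()` defaults to $K=3$, a sensible general-purpose smoother
for bimodal tropical seasonality at Landsat revisit density. The sowing
estimator, however, defaults to $K=5$ on a one-year window centred on the
grid's SOS (`fit_halfwidth = 120` d). Two reasons, both visible in
synthetic experiments:

* the pre-sowing trough is a *sharp* feature (bare, prepared land right
  before green-up). Resolving its location needs basis periods comparable
  to its width (~$P/K \approx 73$ d at $K=5$); at $K=3$ the smoothed
  trough migrates ~3 weeks early, a systematic bias far larger than the
  observation noise contribution;
* rainfall onset shifts from year to year, so a multi-year fit with
  year-periodic basis functions averages neighbouring onsets into the
  target season. A season-centred window keeps the minimum local.

Both settings are arguments, not constants.

## Sowing-date retrieval

Sowing must precede SOS, because SOS registers the post-emergence rise of
the canopy. The rule: among the dates where the fitted curve's analytic
derivative crosses zero from negative to positive (located by sign-change
bracketing on a 1-day grid, then bisection to |slope| < 1e−8 NDVI/day)
inside the half-open window [SOS − 90 d, SOS), take the minimum *closest
before SOS*. Shallow bumps before the season — weed regrowth after land
preparation produces a "false minor peak" — are first merged away: if the
peak separating two adjacent minima rises above its higher flanking
minimum by less than 10% of the seasonal amplitude (the
scipy-style prominence convention), the earlier minimum is discarded.
The `latest` selection is deliberately robust to such bumps even when
they survive filtering; a `lowest` (deepest-minimum) mode is available.
When no minimum exists in the window the estimator falls back to
SOS − 30 d and flags the estimate, so downstream simulation stays total.
Pixel estimates are aggregated per grid by the lower-median date, flagged
when more than half the pixels used the fallback.

Thresholds (90-d window, 0.10 prominence, 30-d fallback) are operational
choices the retrieval rule needs but that no observational product
defines; they are exposed in `estimator_config()`.

## The reduced crop simulator

The simulator is a deliberately small, fully-tested daily model in the
CERES-Maize tradition — not a port. Per day, in order: potential ET
(Priestley–Taylor), canopy partition, soil water balance, water stress,
thermal time, stage transitions, LAI update, biomass growth.

* **Thermal time**: $\max(0, \min(\bar T, T_{ceil}) - T_{base})$ with
  $T_{base} = 8$ °C, $T_{ceil} = 34$ °C. Stages: emergence
  (`tt_emergence` = 60 °Cd after sowing), anthesis (`p1` +
  `tt_anth_extra` = 220 + 550 °Cd after emergence), maturity (`p5` =
  700 °Cd after anthesis). Transitions fire on the first day the
  threshold is met, with phase origins anchored at the exact thresholds
  so degree-day arithmetic is reproducible.
* **Priestley–Taylor ET₀**: $\alpha \cdot$ equilibrium evaporation,
  EEQ $= S_{rad}(4.88\times10^{-3} - 4.37\times10^{-3}\,\text{albedo})
  (T_d + 29)$, $T_d = 0.6\,T_{max} + 0.4\,T_{min}$, $\alpha = 1.1$, with
  the long-published hot (> 35 °C) and cold (< 5 °C) multipliers. These
  coefficients are configuration constants of the standard formulation.
  Surface albedo evolves linearly from the soil value (0.13) to 0.23 as
  LAI reaches 3.
* **Partition**: potential soil evaporation $= E_0 e^{-k\,LAI}$
  (k = 0.7), the complement is potential transpiration; they sum to
  $E_0$ by construction.
* **Soil water**: an n-layer tipping bucket. Curve-number runoff
  (CN = 75) on daily rain; infiltration fills layers top-down; water
  above saturation passes on immediately and water between the drained
  upper limit (DUL) and saturation drains at 0.4 d⁻¹; soil evaporation
  draws the top layer down to 0.5·LL (air-dry); transpiration draws
  plant-available water (content − LL) from layers inside the rooting
  front (advancing 2.5 cm/day), proportionally to availability. The daily
  mass balance closes to < 1e−6 mm and is asserted on every step.
* **Growth**: $\Delta B = RUE \cdot 0.5\,S_{rad}(1 - e^{-k\,LAI}) \cdot
  f_w$ with RUE = 3.3 g MJ⁻¹ (PAR) and water stress $f_w$ = actual /
  potential transpiration. LAI expands at `lai_max` / (p1 +
  `tt_anth_extra`) per stressed degree-day to a 4.5 peak at anthesis,
  then senesces linearly in thermal time to 15% of the attained peak at
  maturity. Grain yield is biomass × harvest index, the index growing
  linearly from 0 at anthesis to 0.5 at maturity and scaled by mean
  grain-fill stress. The unstressed peak LAI lands exactly at `lai_max`
  on the anthesis day, which makes the MS comparison (day of maximum
  LAI, earliest on ties) deterministic.

Out of scope, deliberately: nitrogen dynamics (the parameterisation
premise is non-limiting N), photoperiod sensitivity, kernel-level yield
components, pests (fall armyworm damage is a known unmodelled loss),
FAO-56 Penman–Monteith. The shipped default cultivar is **synthetic**: a
plausible medium-duration highland hybrid, not a calibrated coefficient
set, because no calibrated values are bundled with the package. Seasons
are capped 250 days after sowing; a crop that never emerges or matures is
flagged with zero yield rather than erroring, so regional aggregation
stays total.

## Evaluation conventions

"R²" follows the scatter-plot convention: the squared Pearson correlation
of the paired values, not $1 - SSE/SST$ about a fitted line (identical
for a simple linear fit). ET agreement is the percent deviation
$100\,(sim - ref)/ref$ per grid-season, which is scale-invariant. The
sensitivity experiment shifts every grid's estimated sowing date by
−30…+30 days in ten-day steps — six shifted scenarios around the
baseline — re-simulates, aggregates to region-year means and correlates
across years with the reported yields (and reference ET) per region.
Five year-points per region make these correlations fragile; a pooled
across-regions mode is provided and reported alongside.

## The synthetic scenario

The generator emulates, under one mandatory seed (every stream is derived
deterministically from it, so scenarios are bit-reproducible):

* **Weather** — sinusoidal temperature/radiation climatology with daily
  noise; rainfall from a two-state Markov chain (persistence 0.3) whose
  stationary wet-day probability is bimodal: 0.50 in the long rains
  (roughly March–July), 0.35 in the short rains (October–December), 0.07
  otherwise, scaled by a regional wetness gradient (0.85–1.15) and
  shifted by a year-level onset anomaly (SD 12 d); wet-day amounts are
  gamma (shape 0.85, scale 10 mm) scaled by a year-level lognormal
  amount anomaly (SD 0.35). Expected annual totals sit near 1100 mm,
  inside the region's 900–1800 mm band. Interannual variability thus
  enters mostly through rainfall *timing and amount*, shared across the
  domain — the regime in which sowing at the right date matters.
* **Truth** — true sowing per grid-year ~ Normal(region base + year
  onset shift, 7 d), i.e. farmers track onset; the simulator then
  produces true yields, seasonal ET and peak-LAI dates.
* **NDVI** — per pixel, a latent daily curve: 0.15 baseline, a
  double-logistic seasonal pulse keyed to the truth season's emergence
  and maturity with peak scaled by relative peak LAI, a land-preparation
  decline reaching its minimum at sowing, and (probability 0.3) a false
  minor bump 20–40 d before sowing (amplitude 0.05). The latent curve is
  sampled every 10 d with N(0, 0.02) noise, 20% dropouts, and 4%
  low-value artefacts flagged bad. The latent pulse is deliberately *not*
  harmonic — the estimator must survive model mismatch. Pixels carry a
  systematic timing jitter (SD 3 d) around their grid's truth.
* **Phenology dekads** — a threshold emulation on the latent curve: MS
  is the day of the seasonal maximum; SOS/EOS are the crossings of
  (window minimum + 25% of amplitude) directly flanking the maximum,
  dekad-encoded. Anchoring the crossings to the maximum keeps shallow
  pre-season humps from being called SOS in weak seasons. The real
  product's algorithm is proprietary; the emulation only needs the
  sowing-before-SOS ordering, which holds for every generated pixel.
* **Reported yields** — regional truth means × lognormal noise with 8%
  CV.

What the generator does *not* emulate: sensor radiometry, cloud
geometry, spatial autocorrelation (grids are exchangeable), bimodal
double-cropping (one declared season per year), multi-season pixels.
Passing tests therefore show the pipeline's logic is correct under
realistic noise, dropout and false-feature structure — not that the
retrieval would meet the same accuracy on real Landsat/WaPOR data.

## Study conditions and problem sizes

The standard desk scenario used by the test suite and the acceptance
script is 10 regions × 5 grids × 20 pixels × 5 years (2017–2021): 250
grid-seasons, 1000 pixel series, ~5000 harmonic fits, ~2000 season
simulations including the seven-offset sensitivity experiment. Under
these conditions the retrieval recovers sowing dates with a median
absolute error of ~1–3 days (100% within ±10 d), peak-season R² ≈ 0.93,
pooled regional yield r ≈ 0.95 and median |ET deviation| < 1%.

## Numerical choices and degenerate inputs

Minima are bracketed on a 1-day grid then bisected; ties on maximum LAI
take the earliest day; lower medians keep aggregates at observed values;
the half-open SOS window excludes a trough exactly at SOS; empty search
windows, rank-deficient fits, zero-variance correlations, non-positive
ET references, weather gaps and non-monotone GDD inputs all raise typed
errors rather than propagating nonsense. Every random stream passes
through `withr::with_seed` with a sub-seed derived from the scenario
seed and a stream label, so no generator depends on call order.

## Known limitations

* The per-region sensitivity correlations rest on 5 year-points against
  observations with 8% noise, while a ±10-day sowing shift changes
  yields by only a few percent; the −10/0/+10 columns are therefore
  statistically near-tied and the per-region argmax is unstable, even
  though the *mean* correlation across regions peaks at the baseline
  and falls away toward ±30 d. The pooled correlation is the stable
  summary at this scale.
* Sowing retrieval assumes one season per calendar year; short-rains
  crops and double-cropped pixels are out of scope.
* The simulator's water-only stress pathway means it cannot reproduce
  nutrient- or pest-driven yield gaps; its absolute yields are
  water-limited potentials, not farm yields.
* Harmonic fits need ~13 clear observations in the season window; at
  revisit intervals much coarser than 16 d the estimator degrades to the
  flagged fallback path by design.
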