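# phenosow

Grid-scale maize sowing dates from satellite land-surface phenology,
fed into a reduced CERES-style crop simulator, evaluated at regional
scale — with a fully seeded synthetic data generator so the whole
pipeline runs at desk scale with known ground truth.

## Who this is for

Agro-ecosystem modellers and remote-sensing analysts who want to couple
land-surface phenology (LSP) products with a process-based crop model in
data-scarce rainfed systems: the sowing date is the management input that
matters most, it is unobserved at scale, and it can be retrieved from
NDVI time series constrained by a start-of-season (SOS) product.

## The method

**Phenology decoding.** WaPOR-convention seasonal phenology encodes
SOS/MS/EOS (start / maximum / end of season) as *dekads* — ten-day
calendar intervals, 36 per year, 108 over a three-calendar-year window
with the target year at indices 37–72. Grid records are per-attribute
lower medians of the member pixels.

**Sowing retrieval.** Each pixel's NDVI series is modelled as additive
plus harmonic terms,

    ndvi(t) = c0 + c1 t + sum_k [ a_k cos(2 pi k t / P) + b_k sin(2 pi k t / P) ],

fitted by least squares (P = 365.25 d). The sowing date is the
zero-gradient minimum of the fitted curve closest before SOS, after
discarding "false minor peaks" (pre-season bumps with prominence below
10% of the seasonal amplitude); the grid estimate is the median over
pixels and must precede SOS.

**Crop simulation.** A daily water-limited maize model in the CERES
tradition: thermal-time phenology (base 8 °C, ceiling 34 °C),
Priestley–Taylor potential ET (alpha = 1.1 on the equilibrium-evaporation
form), Beer's-law canopy partition, a curve-number + tipping-bucket
layered soil water balance with mass closure asserted at 1e-6 mm,
radiation-use-efficiency biomass growth, stress-scaled LAI dynamics and
harvest-index yield formation.

**Evaluation.** Simulated day of maximum LAI vs the MS dekad midpoint
(R² = squared Pearson r); regional mean simulated yield vs reported
yields; per-grid seasonal ET percent deviation vs a reference; and a
sensitivity experiment shifting every sowing date by −30…+30 days in
ten-day steps (six shifted scenarios around the baseline).

## Worked example

The numbered drivers under `analysis/` run the whole study on the
standard synthetic scenario (10 regions × 5 grids × 20 pixels,
2017–2021, seed 42) and write their tables under `results/`:

```sh
Rscript analysis/01_scenario.R     # synthetic inputs + ground truth
Rscript analysis/02_sowing.R      # grid phenology + sowing retrieval
Rscript analysis/03_simulate.R    # daily crop simulation per grid-season
Rscript analysis/04_evaluate.R    # phenology / yield / ET agreement
Rscript analysis/05_sensitivity.R # +/-30-day sowing-shift experiment
```

Output of a run of stages 2–5:

```
Sowing recovery on 250 grid-seasons:
  median |error| 2.0 days; 100.0% within +/-10 days; 0.0% fallback
Simulated 250 grid-seasons (250 completed to maturity)
  grain yield mean 11507 kg/ha; seasonal ET mean 476 mm; peak LAI mean 4.13
Peak-season phenology: R^2 = 0.946 on 250 pairs
Regional yield agreement (pooled): r = 0.954 on 50 region-years
Seasonal ET deviation: median |dev| 0.56%; 0.0% of grids beyond +/-20%
Mean per-region yield correlation by sowing offset (days):
 offset_days   r_yield
         -30 0.8696408
         -20 0.8997196
         -10 0.9062197
           0 0.9503514
          10 0.9410551
          20 0.8820628
          30 0.8364540
```

Reading it: the retrieval finds sowing within days of truth despite 2%
NDVI noise, 20% dropouts and false pre-season peaks; the simulated peak
season tracks the MS phenology (R² 0.95); regional yields agree with the
noisy "reported" yields; ET deviations are small because the reference
here is the truth simulation; and yield agreement is best at the
retrieved dates, degrading as sowing is displaced from each year's
rainfall onset. Yields are water-limited potentials (nitrogen assumed
non-limiting), hence higher than typical farm yields.

## Layout

- `R/` — dekad codec, harmonic fitting, sowing estimator, crop/soil
  simulator, evaluation statistics, synthetic generator, staged pipeline
- `analysis/` — the numbered narrative drivers shown above
- `tests/testthat/` — unit, property and end-to-end suites
- `vignettes/phenology-to-sowing-to-yield.Rmd` — the methods vignette:
  model assumptions, parameter meanings and defaults, generator realism
  and limitations
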