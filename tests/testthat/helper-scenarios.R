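# Scenarios are generated once per test run and memoised here; the
# "standard" scenario is the full desk-scale study (10 regions x 5 grids
# x 20 pixels x 5 years) used by the recovery and sensitivity checks.

.scenario_cache <- new.env(parent = emptyenv())

standard_scenario <- function() {
  if (is.null(.scenario_cache$standard)) {
    .scenario_cache$standard <- generate_scenario(scenario_config(seed = 42))
  }
  .scenario_cache$standard
}

small_scenario <- function() {
  if (is.null(.scenario_cache$small)) {
    .scenario_cache$small <- generate_scenario(scenario_config(
      n_regions = 3, grids_per_region = 3, pixels_per_grid = 8,
      years = 2018:2020, seed = 7))
  }
  .scenario_cache$small
}

constant_weather <- function(start = "2018-01-01", days = 400, srad = 20,
                             tmax = 28, tmin = 14, rain = 8) {
  data.frame(date = seq(as.Date(start), by = "day", length.out = days),
             srad = srad, tmax = tmax, tmin = tmin, rain = rain)
}

# a harmonic model assembled directly from coefficients
make_model <- function(intercept = 0, trend = 0, a = 0, b = 0,
                       base_period = 365.25,
                       reference_date = as.Date("2018-01-01")) {
  k <- max(length(a), length(b))
  structure(list(intercept = intercept, trend = trend,
                 a = rep_len(a, k), b = rep_len(b, k), n_harmonics = k,
                 base_period = base_period, reference_date = reference_date,
                 rss = 0, n_obs = 0L), class = "harmonic_model")
}

sowing_errors <- function(scenario, est) {
  m <- merge(est, scenario$truth, by.x = c("grid_id", "season_year"),
             by.y = c("grid_id", "year"))
  true_date <- as.Date(sprintf("%d-01-01", m$season_year)) +
    m$true_sowing_doy - 1
  m$err_days <- as.numeric(as.Date(m$sowing_date) - true_date)
  m
}
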