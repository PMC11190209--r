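# Seeded synthetic scenario generator: weather, ground-truth seasons,
# NDVI observations (noise, dropouts, false pre-season peaks, bad-quality
# dips), WaPOR-convention phenology dekads and noisy regional "reported"
# yields, so the whole pipeline runs at desk scale with known truth.

#' Scenario configuration
#'
#' Defines a complete synthetic study: layout (regions, grids, pixels,
#' years), true sowing behaviour, NDVI observation process and weather
#' climatology. Interannual variability enters through a year-level shift
#' of the long-rains onset and a year-level rainfall amount anomaly,
#' shared across the domain (true sowing tracks the onset shift, as
#' rainfed farmers sow at rain onset); a fixed wetness gradient across
#' regions creates regional contrast.
#'
#' @param n_regions,grids_per_region,pixels_per_grid layout counts.
#' @param years study years (calendar years, one long-rains season each).
#' @param sowing_mean_doy per-region mean true sowing day-of-year in a
#'   zero-onset-shift year (default: gradient 78..98 across regions).
#' @param sowing_sd_days within-region, across-grid sowing spread (days).
#' @param revisit_days NDVI revisit interval (default 10).
#' @param ndvi_noise_sd observation noise SD in NDVI units (default 0.02).
#' @param dropout_prob probability an acquisition is lost (default 0.2).
#' @param false_peak_prob per pixel-season probability of a false minor
#'   pre-sowing NDVI bump, e.g. weed regrowth (default 0.3).
#' @param false_peak_amplitude bump amplitude, NDVI units (default 0.05).
#' @param bad_obs_prob probability a retained observation is an
#'   atmospheric artefact (low value, flagged `"bad"`; default 0.04).
#' @param pixel_jitter_sd within-grid pixel timing spread, days.
#' @param yield_obs_noise_cv CV of the lognormal noise on reported
#'   regional yields (default 0.08).
#' @param weather list of climatology parameters; see Details in the
#'   package vignette. Defaults emulate a bimodal equatorial-highland
#'   regime (long rains roughly March-July, short rains October-December,
#'   annual totals near the middle of a 900-1800 mm band).
#' @param seed integer seed (mandatory); every generator derives its
#'   random stream from it.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_regions = 10, grids_per_region = 5,
                            pixels_per_grid = 20, years = 2017:2021,
                            sowing_mean_doy = NULL, sowing_sd_days = 7,
                            revisit_days = 10, ndvi_noise_sd = 0.02,
                            dropout_prob = 0.2, false_peak_prob = 0.3,
                            false_peak_amplitude = 0.05,
                            bad_obs_prob = 0.04, pixel_jitter_sd = 3,
                            yield_obs_noise_cv = 0.08,
                            weather = list(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_regions >= 1, grids_per_region >= 1, pixels_per_grid >= 1,
            revisit_days >= 1, ndvi_noise_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            false_peak_prob >= 0, false_peak_prob <= 1,
            bad_obs_prob >= 0, bad_obs_prob <= 1,
            sowing_sd_days >= 0, yield_obs_noise_cv >= 0)
  if (is.null(sowing_mean_doy)) {
    sowing_mean_doy <- round(seq(78, 98, length.out = n_regions))
  }
  stopifnot(length(sowing_mean_doy) == n_regions)
  wdef <- list(
    tmin_mean = 13, tmin_amp = 1.5,
    diurnal_range = 13, diurnal_amp = 2,
    temp_noise_sd = 1.2,
    srad_mean = 20, srad_amp = 3, srad_noise_sd = 2,
    wet_srad_factor = 0.75,
    wet_prob_long = 0.50, wet_prob_short = 0.35, wet_prob_dry = 0.07,
    long_window = c(65, 210), short_window = c(280, 355),
    rain_shape = 0.85, rain_scale = 10,
    persistence = 0.3,
    onset_sd_days = 12, amount_anomaly_sd = 0.35,
    region_wetness_range = c(0.85, 1.15)
  )
  wdef[names(weather)] <- weather
  structure(list(
    n_regions = n_regions, grids_per_region = grids_per_region,
    pixels_per_grid = pixels_per_grid, years = as.integer(years),
    sowing_mean_doy = sowing_mean_doy, sowing_sd_days = sowing_sd_days,
    revisit_days = revisit_days, ndvi_noise_sd = ndvi_noise_sd,
    dropout_prob = dropout_prob, false_peak_prob = false_peak_prob,
    false_peak_amplitude = false_peak_amplitude,
    bad_obs_prob = bad_obs_prob, pixel_jitter_sd = pixel_jitter_sd,
    yield_obs_noise_cv = yield_obs_noise_cv,
    weather = wdef, seed = as.integer(seed)
  ), class = "scenario_config")
}

# deterministic sub-seed (< 2^31) from the scenario seed and a label
derive_seed <- function(seed, ...) {
  lbl <- paste(c(...), collapse = "|")
  h <- sum(utf8ToInt(lbl) * seq_len(nchar(lbl)))
  as.integer((as.numeric(seed) * 48271 + h * 96731) %% 2147483587)
}

#' Grid and pixel layout of a scenario
#'
#' @param config a [scenario_config()].
#' @return list `pixels` (data.frame `pixel_id, grid_id, region_id`),
#'   `grids` (data.frame `grid_id, region_id, wetness, sowing_mean_doy`).
#' @export
scenario_grid_map <- function(config) {
  wr <- config$weather$region_wetness_range
  wetness <- if (config$n_regions == 1) mean(wr) else
    seq(wr[1], wr[2], length.out = config$n_regions)
  grids <- do.call(rbind, lapply(seq_len(config$n_regions), function(r) {
    data.frame(
      grid_id = sprintf("r%02dg%02d", r, seq_len(config$grids_per_region)),
      region_id = sprintf("r%02d", r),
      wetness = wetness[r],
      sowing_mean_doy = config$sowing_mean_doy[r]
    )
  }))
  pixels <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i) {
    data.frame(
      pixel_id = sprintf("%s_p%03d", grids$grid_id[i],
                         seq_len(config$pixels_per_grid)),
      grid_id = grids$grid_id[i],
      region_id = grids$region_id[i]
    )
  }))
  list(pixels = pixels, grids = grids)
}

# year-level anomalies shared across the domain: onset shift of the long
# rains (days) and multiplicative rainfall amount anomaly (mean one)
year_effects <- function(config, year) {
  withr::with_seed(derive_seed(config$seed, "year", year), {
    onset <- round(stats::rnorm(1, 0, config$weather$onset_sd_days))
    sd <- config$weather$amount_anomaly_sd
    amount <- exp(stats::rnorm(1, 0, sd) - sd^2 / 2)
  })
  list(onset_shift = onset, amount_anomaly = amount)
}

# daily wet-day stationary probability by day-of-year
wet_probability <- function(doy, cfg, onset_shift = 0, wetness = 1) {
  w <- cfg$weather
  p <- rep(w$wet_prob_dry, length(doy))
  lw <- w$long_window + onset_shift
  p[doy >= lw[1] & doy <= lw[2]] <- w$wet_prob_long
  p[doy >= w$short_window[1] & doy <= w$short_window[2]] <- w$wet_prob_short
  pmin(0.95, p * wetness)
}

#' Generate one calendar year of daily weather for a grid
#'
#' Sinusoidal temperature and radiation climatology with Gaussian daily
#' noise; rainfall from a two-state Markov chain whose stationary wet-day
#' probability is seasonal (bimodal: long rains roughly March-July, short
#' rains October-December, shifted by the year's onset anomaly and scaled
#' by the region's wetness), with gamma-distributed wet-day amounts
#' scaled by the year's amount anomaly. Radiation is reduced on wet days;
#' `tmax >= tmin` is enforced by construction. Fully deterministic for a
#' given (config seed, grid, year).
#'
#' @param config a [scenario_config()].
#' @param grid_id grid identifier (part of the random stream label).
#' @param year calendar year.
#' @param wetness regional wet-probability multiplier (default 1).
#' @return data.frame `date, srad, tmax, tmin, rain` (one row per day).
#' @export
generate_weather <- function(config, grid_id, year, wetness = 1) {
  w <- config$weather
  ye <- year_effects(config, year)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- seq_along(dates)
  n <- length(doy)
  withr::with_seed(derive_seed(config$seed, "wth", grid_id, year), {
    tmin <- w$tmin_mean + w$tmin_amp * cos(2 * pi * (doy - 45) / 365) +
      stats::rnorm(n, 0, w$temp_noise_sd)
    drange <- pmax(1, w$diurnal_range +
                     w$diurnal_amp * cos(2 * pi * (doy - 45) / 365) +
                     stats::rnorm(n, 0, w$temp_noise_sd))
    tmax <- tmin + drange
    p <- wet_probability(doy, config, ye$onset_shift, wetness)
    rho <- w$persistence
    wet <- logical(n)
    wet[1L] <- stats::runif(1) < p[1L]
    u <- stats::runif(n)
    for (i in 2:n) {
      pw <- if (wet[i - 1L]) p[i] + rho * (1 - p[i]) else p[i] * (1 - rho)
      wet[i] <- u[i] < pw
    }
    rain <- numeric(n)
    nw <- sum(wet)
    if (nw > 0) {
      rain[wet] <- stats::rgamma(nw, shape = w$rain_shape,
                                 scale = w$rain_scale * ye$amount_anomaly)
    }
    srad <- w$srad_mean + w$srad_amp * cos(2 * pi * (doy - 45) / 365) +
      stats::rnorm(n, 0, w$srad_noise_sd)
    srad[wet] <- srad[wet] * w$wet_srad_factor
    srad <- pmax(2, srad)
  })
  data.frame(date = dates, srad = srad, tmax = tmax, tmin = tmin,
             rain = rain)
}

# continuous multi-year weather for one grid
grid_weather_span <- function(config, grid_id, years, wetness = 1) {
  do.call(rbind, lapply(years, function(y)
    generate_weather(config, grid_id, y, wetness)))
}

#' Generate the ground-truth table of a scenario
#'
#' Draws true sowing days per grid-year (regional mean shifted by the
#' year's rainfall-onset anomaly, grid-level spread `sowing_sd_days`),
#' generates each grid's weather span, and runs the crop simulator to
#' obtain true yields, seasonal ET, peak-LAI dates and phenology.
#'
#' @param config a [scenario_config()].
#' @param soil,cultivar simulator parameters (defaults:
#'   [default_soil()], [default_cultivar()]).
#' @return list of class `scenario_truth`: `truth` (data.frame
#'   `grid_id, region_id, year, true_sowing_doy, true_yield,
#'   true_cumulative_et, true_max_lai_doy`), `seasons` (per grid-year
#'   phenology dates and relative peak LAI for the NDVI generator),
#'   `weather` (list of data.frames by grid), `map`
#'   ([scenario_grid_map()]), `soil`, `cultivar`, `config`.
#' @export
generate_truth <- function(config, soil = default_soil(),
                           cultivar = default_cultivar()) {
  map <- scenario_grid_map(config)
  span_years <- (min(config$years) - 1L):(max(config$years) + 1L)
  weather <- list()
  truth <- list()
  seasons <- list()
  for (i in seq_len(nrow(map$grids))) {
    g <- map$grids[i, ]
    wx <- grid_weather_span(config, g$grid_id, span_years, g$wetness)
    weather[[g$grid_id]] <- wx
    for (y in config$years) {
      ye <- year_effects(config, y)
      sow_doy <- withr::with_seed(
        derive_seed(config$seed, "sow", g$grid_id, y),
        round(stats::rnorm(1, g$sowing_mean_doy + ye$onset_shift,
                           config$sowing_sd_days)))
      sow_doy <- max(15L, min(180L, as.integer(sow_doy)))
      sow_date <- as.Date(sprintf("%d-01-01", y)) + (sow_doy - 1L)
      res <- simulate_season(wx, soil, cultivar, sow_date)
      truth[[length(truth) + 1L]] <- data.frame(
        grid_id = g$grid_id, region_id = g$region_id, year = y,
        true_sowing_doy = sow_doy,
        true_yield = res$grain_yield,
        true_cumulative_et = res$cumulative_et,
        true_max_lai_doy = res$max_lai_doy)
      seasons[[paste(g$grid_id, y)]] <- list(
        grid_id = g$grid_id, year = y,
        sowing = sow_date,
        emergence = res$emergence_date,
        anthesis = res$anthesis_date,
        maturity = res$maturity_date,
        rel_peak = min(1, max(0.2, res$max_lai / cultivar$lai_max)))
    }
  }
  structure(list(truth = do.call(rbind, truth), seasons = seasons,
                 weather = weather, map = map, soil = soil,
                 cultivar = cultivar, config = config),
            class = "scenario_truth")
}

# latent daily NDVI for one pixel: baseline + per-season double-logistic
# pulse + pre-sowing land-preparation decline + optional false bumps
latent_ndvi <- function(t, seasons, jitter = 0, bumps = NULL,
                        baseline = 0.15) {
  v <- rep(baseline, length(t))
  for (s in seasons) {
    if (is.na(s$emergence) || is.na(s$maturity)) next
    sow <- as.numeric(s$sowing) + jitter
    a <- as.numeric(s$emergence) + jitter + 20   # green-up centre
    b <- as.numeric(s$maturity) + jitter         # senescence centre
    amp <- 0.65 * s$rel_peak
    v <- v + amp * (stats::plogis((t - a) / 7) - stats::plogis((t - b) / 9)) +
      0.12 * stats::plogis(-(t - (sow - 10)) / 4) *
        stats::plogis((t - (sow - 120)) / 15)
  }
  if (!is.null(bumps) && nrow(bumps)) {
    for (j in seq_len(nrow(bumps))) {
      v <- v + bumps$amp[j] * exp(-0.5 * ((t - bumps$centre[j]) / 6)^2)
    }
  }
  pmin(1, pmax(-1, v))
}

#' Generate NDVI observations (and latent curves) for every pixel
#'
#' Builds each pixel's latent daily NDVI from the truth seasons (a
#' double-logistic seasonal pulse keyed to emergence/anthesis/maturity,
#' a declining pre-sowing land-preparation tail reaching its minimum at
#' sowing, and — with probability `false_peak_prob` — a false minor bump
#' 20-40 days before sowing), then samples it every `revisit_days` with
#' Gaussian noise, random dropouts and occasional low-value artefacts
#' flagged `qa = "bad"`. Deterministic under the scenario seed.
#'
#' @param truth a [generate_truth()] result.
#' @return list `observations` (data.frame `series_id, grid_id, date,
#'   ndvi, qa`), `latent` (list `dates`, matrix `values` days x pixels,
#'   `pixel_ids`), `pixel_meta` (data.frame `pixel_id, jitter_days`:
#'   each pixel's systematic timing offset from its grid's truth, i.e.
#'   its effective sowing is the grid truth plus the jitter).
#' @export
generate_ndvi <- function(truth) {
  config <- truth$config
  px <- truth$map$pixels
  span <- seq(as.Date(sprintf("%d-01-01", min(config$years) - 1L)),
              as.Date(sprintf("%d-12-31", max(config$years) + 1L)),
              by = "day")
  tnum <- as.numeric(span)
  latent <- matrix(NA_real_, length(span), nrow(px),
                   dimnames = list(NULL, px$pixel_id))
  obs <- vector("list", nrow(px))
  jitters <- numeric(nrow(px))
  samp_idx <- seq(1L, length(span), by = config$revisit_days)
  for (i in seq_len(nrow(px))) {
    pid <- px$pixel_id[i]
    gid <- px$grid_id[i]
    seasons <- truth$seasons[paste(gid, config$years)]
    withr::with_seed(derive_seed(config$seed, "ndvi", pid), {
      jitter <- stats::rnorm(1, 0, config$pixel_jitter_sd)
      has_bump <- stats::runif(length(seasons)) < config$false_peak_prob
      centres <- vapply(seasons, function(s) as.numeric(s$sowing),
                        numeric(1)) - stats::runif(length(seasons), 20, 40)
      bumps <- data.frame(centre = centres[has_bump],
                          amp = rep(config$false_peak_amplitude,
                                    sum(has_bump)))
      lat <- latent_ndvi(tnum, seasons, jitter, bumps)
      keep <- stats::runif(length(samp_idx)) >= config$dropout_prob
      idx <- samp_idx[keep]
      nd <- lat[idx] + stats::rnorm(length(idx), 0, config$ndvi_noise_sd)
      bad <- stats::runif(length(idx)) < config$bad_obs_prob
      nd[bad] <- nd[bad] * 0.35
    })
    latent[, i] <- lat
    jitters[i] <- jitter
    if (length(idx)) {
      obs[[i]] <- data.frame(series_id = pid, grid_id = gid,
                             date = span[idx],
                             ndvi = pmin(1, pmax(-1, nd)),
                             qa = ifelse(bad, "bad", "good"))
    }
  }
  list(observations = do.call(rbind, obs),
       latent = list(dates = span, values = latent,
                     pixel_ids = px$pixel_id),
       pixel_meta = data.frame(pixel_id = px$pixel_id,
                               jitter_days = jitters))
}

#' WaPOR-convention phenology dekads from latent NDVI
#'
#' Emulates a seasonal-phenology retrieval on the latent (noise-free)
#' NDVI: per pixel and season year, over a window from mid-November of
#' the preceding year to 31 December, SOS is the first day the curve
#' exceeds the window minimum plus 25 percent of the window amplitude
#' with positive slope, MS is the day of the window maximum, and EOS the
#' last day above the threshold; the three days are encoded as dekad
#' indices of the 108-dekad window of the season year. Pixels with no
#' detectable season (amplitude below `min_amplitude`) yield a missing
#' record.
#'
#' @param latent the `latent` element of [generate_ndvi()].
#' @param config the [scenario_config()].
#' @param min_amplitude minimum window amplitude for a season call.
#' @return data.frame `pixel_id, season_year, sos, ms, eos` (dekads;
#'   `NA` rows for undetected seasons).
#' @export
generate_wapor_lsp <- function(latent, config, min_amplitude = 0.1) {
  out <- list()
  dts <- latent$dates
  for (y in config$years) {
    w0 <- as.Date(sprintf("%d-11-15", y - 1L))
    w1 <- as.Date(sprintf("%d-12-31", y))
    sel <- dts >= w0 & dts <= w1
    dsel <- dts[sel]
    for (i in seq_along(latent$pixel_ids)) {
      v <- latent$values[sel, i]
      amp <- max(v) - min(v)
      if (amp < min_amplitude) {
        rec <- data.frame(pixel_id = latent$pixel_ids[i], season_year = y,
                          sos = NA_integer_, ms = NA_integer_,
                          eos = NA_integer_)
      } else {
        # threshold crossings directly flanking the seasonal maximum, so
        # shallow pre-season humps (land preparation) are never called SOS
        thr <- min(v) + 0.25 * amp
        imax <- which.max(v)
        below_pre <- which(v[seq_len(imax)] <= thr)
        sos_i <- if (length(below_pre)) max(below_pre) + 1L else 1L
        post <- seq(imax, length(v))
        below_post <- which(v[post] <= thr)
        eos_i <- if (length(below_post)) {
          post[min(below_post)] - 1L
        } else length(v)
        rec <- data.frame(
          pixel_id = latent$pixel_ids[i], season_year = y,
          sos = dekad_encode(dsel[sos_i], y),
          ms = dekad_encode(dsel[imax], y),
          eos = dekad_encode(dsel[eos_i], y))
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Noisy regional "reported" yields from the truth table
#'
#' Regional (sub-county) mean of the true grid yields per year, times
#' seeded lognormal noise with coefficient of variation
#' `yield_obs_noise_cv` — a stand-in for ministry yield records.
#'
#' @param truth a [generate_truth()] result.
#' @return data.frame `region_id, year, yield` (kg ha-1).
#' @export
generate_observed_yields <- function(truth) {
  config <- truth$config
  reg <- aggregate_mean(
    data.frame(grid_id = truth$truth$grid_id, year = truth$truth$year,
               value = truth$truth$true_yield),
    truth$map$grids[, c("grid_id", "region_id")])
  cv <- config$yield_obs_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- withr::with_seed(
    derive_seed(config$seed, "obsyield"),
    exp(stats::rnorm(nrow(reg), -sdlog^2 / 2, sdlog)))
  if (cv == 0) noise <- rep(1, nrow(reg))
  data.frame(region_id = reg$region_id, year = reg$year,
             yield = reg$mean_value * noise)
}

#' Generate a complete scenario in memory
#'
#' Runs all generators in order (truth simulation, NDVI, WaPOR-like
#' phenology dekads, observed yields) and returns every table the
#' pipeline consumes plus the ground truth.
#'
#' @param config a [scenario_config()].
#' @param soil,cultivar simulator parameters.
#' @return list of class `scenario`: `config`, `map`, `weather` (list by
#'   grid), `truth`, `seasons`, `ndvi` (observations), `latent`,
#'   `pixel_lsp`, `observed_yields`, `soil`, `cultivar`.
#' @export
generate_scenario <- function(config, soil = default_soil(),
                              cultivar = default_cultivar()) {
  tr <- generate_truth(config, soil, cultivar)
  nd <- generate_ndvi(tr)
  lsp <- generate_wapor_lsp(nd$latent, config)
  oy <- generate_observed_yields(tr)
  structure(list(config = config, map = tr$map, weather = tr$weather,
                 truth = tr$truth, seasons = tr$seasons,
                 ndvi = nd$observations, latent = nd$latent,
                 pixel_meta = nd$pixel_meta,
                 pixel_lsp = lsp, observed_yields = oy,
                 soil = soil, cultivar = cultivar),
            class = "scenario")
}

#' Write a scenario to disk as plain-text pipeline inputs
#'
#' Emits the CSV/YAML files the pipeline stages consume (weather, NDVI
#' observations, pixel phenology dekads, grid map, observed yields, soil
#' and cultivar parameters) plus the truth table and a manifest recording
#' the seed, a configuration hash and per-file row counts. Re-running
#' with the same configuration reproduces every file exactly.
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return (invisibly) the manifest list.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wx <- do.call(rbind, lapply(names(scenario$weather), function(g) {
    cbind(grid_id = g, scenario$weather[[g]])
  }))
  files <- list(
    weather = wx,
    ndvi = scenario$ndvi,
    pixel_lsp = scenario$pixel_lsp,
    grid_map = scenario$map$pixels,
    grids = scenario$map$grids,
    observed_yields = scenario$observed_yields,
    truth = scenario$truth
  )
  manifest <- list(seed = scenario$config$seed,
                   config_hash = rlang::hash(scenario$config),
                   files = list())
  for (nm in names(files)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(files[[nm]], path, row.names = FALSE)
    manifest$files[[nm]] <- list(file = basename(path),
                                 rows = nrow(files[[nm]]))
  }
  yaml::write_yaml(list(
    layers = scenario$soil$layers,
    drainage_coefficient = scenario$soil$drainage_coefficient,
    runoff_curve_number = scenario$soil$runoff_curve_number,
    albedo = scenario$soil$albedo), file.path(dir, "soil.yaml"))
  yaml::write_yaml(unclass(scenario$cultivar),
                   file.path(dir, "cultivar.yaml"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
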