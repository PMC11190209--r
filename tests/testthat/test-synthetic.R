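test_that("weather generation is seeded, physical and bimodal", {
  cfg <- scenario_config(n_regions = 1, grids_per_region = 1,
                         pixels_per_grid = 1, years = 2018, seed = 99)
  w1 <- generate_weather(cfg, "g1", 2018)
  w2 <- generate_weather(cfg, "g1", 2018)
  expect_identical(w1, w2)
  expect_false(identical(w1, generate_weather(cfg, "g2", 2018)))
  expect_true(all(w1$tmax >= w1$tmin))
  expect_true(all(w1$srad >= 0))
  expect_true(all(w1$rain >= 0))
  expect_equal(nrow(w1), 365)

  # long rains wetter than the dry season
  doy <- seq_len(365)
  long <- doy >= 80 & doy <= 200
  dry <- doy <= 50
  expect_gt(mean(w1$rain[long] > 0), mean(w1$rain[dry] > 0))

  # zero wet probability: an all-dry year
  cfg0 <- scenario_config(n_regions = 1, grids_per_region = 1,
                          pixels_per_grid = 1, years = 2018, seed = 99,
                          weather = list(wet_prob_long = 0,
                                         wet_prob_short = 0,
                                         wet_prob_dry = 0))
  expect_equal(sum(generate_weather(cfg0, "g1", 2018)$rain), 0)
})

test_that("mean annual rainfall sits in the configured band and matches
           the analytic wet-probability x amount product", {
  cfg <- scenario_config(n_regions = 1, grids_per_region = 1,
                         pixels_per_grid = 1, years = 2018, seed = 1234)
  w <- cfg$weather
  # analytic expectation at wetness 1, averaging over onset shifts ~ 0
  p <- phenosow:::wet_probability(seq_len(365), cfg)
  analytic <- sum(p) * w$rain_shape * w$rain_scale
  expect_gt(analytic, 900)
  expect_lt(analytic, 1800)

  totals <- vapply(1:50, function(i) {
    cfgi <- scenario_config(n_regions = 1, grids_per_region = 1,
                            pixels_per_grid = 1, years = 2018,
                            seed = 1234 + i)
    sum(generate_weather(cfgi, "g1", 2018)$rain)
  }, numeric(1))
  expect_gt(mean(totals), 900)
  expect_lt(mean(totals), 1800)
  expect_lt(abs(mean(totals) - analytic) / analytic, 0.25)
})

test_that("true sowing days follow the configured regional distribution", {
  cfg <- scenario_config(n_regions = 1, grids_per_region = 40,
                         pixels_per_grid = 1, years = 2018,
                         sowing_mean_doy = 90, sowing_sd_days = 7,
                         seed = 5)
  tr <- generate_truth(cfg)
  onset <- phenosow:::year_effects(cfg, 2018)$onset_shift
  se <- cfg$sowing_sd_days / sqrt(40)
  expect_lt(abs(mean(tr$truth$true_sowing_doy) - (90 + onset)), 2 * se + 1)

  # zero spread: all grids in the region share one sowing day
  cfg0 <- scenario_config(n_regions = 1, grids_per_region = 5,
                          pixels_per_grid = 1, years = 2018,
                          sowing_mean_doy = 90, sowing_sd_days = 0,
                          seed = 5)
  tr0 <- generate_truth(cfg0)
  expect_equal(length(unique(tr0$truth$true_sowing_doy)), 1)

  # simulator invariants propagate into the truth table
  expect_true(all(tr$truth$true_yield >= 0))
  expect_true(all(tr$truth$true_cumulative_et >= 0))
})

test_that("the noise-free latent NDVI dips at the true sowing date", {
  cfg <- scenario_config(n_regions = 2, grids_per_region = 2,
                         pixels_per_grid = 2, years = 2018:2019,
                         ndvi_noise_sd = 0, dropout_prob = 0,
                         false_peak_prob = 0, pixel_jitter_sd = 0,
                         bad_obs_prob = 0, seed = 31)
  tr <- generate_truth(cfg)
  nd <- generate_ndvi(tr)
  expect_true(all(nd$observations$ndvi >= -1 & nd$observations$ndvi <= 1))
  for (i in seq_along(nd$latent$pixel_ids)) {
    pid <- nd$latent$pixel_ids[i]
    gid <- tr$map$pixels$grid_id[tr$map$pixels$pixel_id == pid]
    for (y in cfg$years) {
      sow <- tr$seasons[[paste(gid, y)]]$sowing
      sel <- nd$latent$dates >= sow - 60 & nd$latent$dates <= sow + 20
      dip <- nd$latent$dates[sel][which.min(nd$latent$values[sel, i])]
      expect_lte(abs(as.numeric(dip - sow)), 2)
    }
  }
})

test_that("NDVI observation process is seeded and degrades as configured", {
  sc <- small_scenario()
  cfg <- sc$config
  tr <- list(config = cfg, map = sc$map, seasons = sc$seasons)
  nd1 <- generate_ndvi(tr)
  nd2 <- generate_ndvi(tr)
  expect_identical(nd1$observations, nd2$observations)
  expect_true(all(nd1$observations$qa %in% c("good", "bad")))
  # dropout removes about the configured fraction of acquisitions
  n_possible <- length(seq(1, length(nd1$latent$dates),
                           by = cfg$revisit_days)) *
    nrow(sc$map$pixels)
  frac <- nrow(nd1$observations) / n_possible
  expect_lt(abs(frac - (1 - cfg$dropout_prob)), 0.05)

  # total dropout: no usable observations at all
  cfg1 <- scenario_config(n_regions = 1, grids_per_region = 1,
                          pixels_per_grid = 2, years = 2018,
                          dropout_prob = 1, seed = 8)
  tr1 <- generate_truth(cfg1)
  nd <- generate_ndvi(tr1)
  expect_null(nd$observations)
})

test_that("emulated phenology dekads are ordered and follow sowing", {
  sc <- small_scenario()
  lsp <- sc$pixel_lsp[stats::complete.cases(sc$pixel_lsp), ]
  expect_gt(nrow(lsp), 0)
  expect_true(all(lsp$sos < lsp$ms))
  expect_true(all(lsp$ms < lsp$eos))

  # SOS dekad strictly after each pixel's effective sowing dekad
  j <- merge(lsp, sc$map$pixels, by = "pixel_id")
  j <- merge(j, sc$truth[, c("grid_id", "year", "true_sowing_doy")],
             by.x = c("grid_id", "season_year"),
             by.y = c("grid_id", "year"))
  j <- merge(j, sc$pixel_meta, by = "pixel_id")
  eff_sowing <- as.Date(sprintf("%d-01-01", j$season_year)) +
    j$true_sowing_doy - 1 + round(j$jitter_days)
  sow_dekad <- mapply(dekad_encode, eff_sowing, j$season_year)
  expect_true(all(j$sos > sow_dekad))

  # MS dekad contains the latent maximum of the season window
  i <- match(j$pixel_id[1], sc$latent$pixel_ids)
  y <- j$season_year[1]
  sel <- sc$latent$dates >= as.Date(sprintf("%d-11-15", y - 1)) &
    sc$latent$dates <= as.Date(sprintf("%d-12-31", y))
  dmax <- sc$latent$dates[sel][which.max(sc$latent$values[sel, i])]
  expect_equal(j$ms[1], dekad_encode(dmax, y))
})

test_that("reported regional yields are noisy means of the truth", {
  sc <- standard_scenario()
  truth_reg <- aggregate_mean(
    data.frame(grid_id = sc$truth$grid_id, year = sc$truth$year,
               value = sc$truth$true_yield),
    sc$map$grids[, c("grid_id", "region_id")])
  j <- merge(truth_reg, sc$observed_yields,
             by = c("region_id", "year"))
  expect_equal(nrow(j), sc$config$n_regions * length(sc$config$years))
  expect_gt(pearson_r(j$mean_value, j$yield), 0.9)

  # zero observation noise reproduces the truth means exactly
  cfg0 <- scenario_config(n_regions = 2, grids_per_region = 2,
                          pixels_per_grid = 1, years = 2018,
                          yield_obs_noise_cv = 0, seed = 3)
  tr0 <- generate_truth(cfg0)
  oy0 <- generate_observed_yields(tr0)
  reg0 <- aggregate_mean(
    data.frame(grid_id = tr0$truth$grid_id, year = tr0$truth$year,
               value = tr0$truth$true_yield),
    tr0$map$grids[, c("grid_id", "region_id")])
  expect_equal(oy0$yield, reg0$mean_value)
})

test_that("scenarios are reproducible end to end and write a manifest", {
  cfg <- scenario_config(n_regions = 1, grids_per_region = 2,
                         pixels_per_grid = 3, years = 2018, seed = 77)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_equal(rlang::hash(s1$truth), rlang::hash(s2$truth))
  expect_equal(rlang::hash(s1$ndvi), rlang::hash(s2$ndvi))
  expect_equal(rlang::hash(s1$observed_yields),
               rlang::hash(s2$observed_yields))
  # one truth record per grid-year
  expect_equal(nrow(s1$truth),
               cfg$n_regions * cfg$grids_per_region * length(cfg$years))

  d1 <- file.path(tempdir(), "scn1"); d2 <- file.path(tempdir(), "scn2")
  m1 <- write_scenario(s1, d1)
  m2 <- write_scenario(s2, d2)
  expect_equal(m1$config_hash, m2$config_hash)
  expect_equal(m1$files$truth$rows, nrow(s1$truth))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
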