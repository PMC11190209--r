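test_that("thermal time applies base and ceiling temperatures", {
  expect_equal(thermal_time(30, 20, 8, 34), 17)
  expect_equal(thermal_time(8, 2, 8, 34), 0)
  expect_equal(thermal_time(40, 36, 8, 34), 26)   # capped at tceil
  expect_error(thermal_time(10, 20), "tmax < tmin")
})

test_that("Priestley-Taylor ET0 follows the equilibrium-evaporation form", {
  expect_equal(priestley_taylor_et0(0, 28, 14), 0)
  # hand evaluation: 1.1 * 20 * (4.88e-3 - 4.37e-3*0.23) * (22.4 + 29)
  expect_equal(priestley_taylor_et0(20, 28, 14, 0.23, 1.1),
               1.1 * 20 * (4.88e-3 - 4.37e-3 * 0.23) * 51.4,
               tolerance = 1e-12)
  # linear in srad below the temperature-adjustment thresholds
  expect_equal(priestley_taylor_et0(40, 28, 14), 2 * priestley_taylor_et0(20, 28, 14))
  # hot and cold multipliers engage
  expect_gt(priestley_taylor_et0(20, 38, 22) / priestley_taylor_et0(20, 34.9, 22), 1)
  # below 5 C the multiplier falls under the ordinary alpha coefficient
  eeq_cold <- 20 * (4.88e-3 - 4.37e-3 * 0.23) * (0.6 * 4 + 0.4 * -2 + 29)
  expect_lt(priestley_taylor_et0(20, 4, -2), 1.1 * eeq_cold)
  expect_error(priestley_taylor_et0(-1, 20, 10), "negative")
})

test_that("ET partition conserves the total and follows canopy cover", {
  p0 <- partition_et(5, 0)
  expect_equal(p0$pot_soil_evap, 5)
  expect_equal(p0$pot_transp, 0)
  pbig <- partition_et(5, 10, 0.7)
  expect_lt(pbig$pot_soil_evap, 0.001 * 5)
  set.seed(3)
  for (i in 1:20) {
    et0 <- runif(1, 0, 8); lai <- runif(1, 0, 6)
    p <- partition_et(et0, lai)
    expect_gte(p$pot_soil_evap, 0)
    expect_gte(p$pot_transp, 0)
    expect_equal(p$pot_soil_evap + p$pot_transp, et0)
  }
})

test_that("soil water step closes its mass balance on random states", {
  set.seed(17)
  soil <- default_soil()
  ly <- soil$layers
  for (i in 1:200) {
    sw <- runif(nrow(ly), ly$ll, ly$sat)
    st <- soil_water_step(sw, soil, rexp(1, 1 / 8),
                          runif(1, 0, 6), runif(1, 0, 7),
                          runif(1, 5, sum(ly$thickness_cm)))
    expect_lt(abs(st$residual), 1e-6)
    expect_gte(st$runoff, 0)
    expect_gte(st$drainage, 0)
    expect_gte(st$evap, 0)
    expect_gte(st$transp, 0)
    expect_true(all(st$sw >= 0 & st$sw <= ly$sat + 1e-12))
  }
})

test_that("soil water step honours its limiting cases", {
  soil <- default_soil()
  ly <- soil$layers
  # no rain, no demand: only drainage of water above DUL moves
  st <- soil_water_step(ly$dul, soil, 0, 0, 0, 90)
  expect_equal(st$sw, ly$dul, tolerance = 1e-12)
  expect_equal(st$runoff + st$drainage + st$evap + st$transp, 0)

  # all layers at wilting point: no transpirable water
  st2 <- soil_water_step(ly$ll, soil, 0, 0, 5, 90)
  expect_equal(st2$transp, 0)

  # 60 mm storm on a profile at DUL: all non-stored water accounted for
  st3 <- soil_water_step(ly$dul, soil, 60, 0, 0, 90)
  stored <- sum((st3$sw - ly$dul) * ly$thickness_cm * 10)
  expect_equal(stored + st3$runoff + st3$drainage, 60, tolerance = 1e-6)
  expect_gt(st3$runoff, 0)
})

test_that("stress factor and growth increment behave as specified", {
  expect_equal(water_stress_factor(5, 5), 1)
  expect_equal(water_stress_factor(0, 5), 0)
  expect_equal(water_stress_factor(2.5, 5), 0.5)
  expect_equal(water_stress_factor(0, 0), 1)

  expect_equal(daily_growth(20, 0, 3.5, 0.7, 1), 0)
  expect_equal(daily_growth(20, 3, 3.5, 0.7, 0), 0)
  expect_equal(daily_growth(20, 3, 3.5, 0.7, 1),
               3.5 * 10 * (1 - exp(-2.1)), tolerance = 1e-12)
})

test_that("phenology stages fire on exact thermal-time thresholds", {
  cv <- cultivar_params(tt_emergence = 51, p5 = 680)
  gdd <- cumsum(rep(17, 120))
  ph <- advance_phenology(gdd, cv)
  expect_equal(unname(ph$day_of["emergence"]), 3L)     # 3 x 17 = 51
  anth <- unname(ph$day_of["anthesis"])
  expect_equal(unname(ph$day_of["maturity"]) - anth, 40L)  # 680/17
  expect_equal(ph$stage[1], "sown")
  expect_equal(ph$stage[length(gdd)], "mature")
  expect_error(advance_phenology(c(10, 5), cv), "non-decreasing")

  # zero thermal time forever: never emerges
  ph0 <- advance_phenology(rep(0, 250), cv)
  expect_true(is.na(ph0$day_of["emergence"]))
  expect_true(all(ph0$stage == "sown"))
})

test_that("a well-watered constant-weather season satisfies all invariants", {
  wx <- constant_weather()
  cv <- default_cultivar()
  r <- simulate_season(wx, default_soil(), cv, as.Date("2018-03-15"))
  expect_true(r$completed)
  expect_true(r$sowing_date < r$emergence_date)
  expect_true(r$emergence_date < r$anthesis_date)
  expect_true(r$anthesis_date < r$maturity_date)
  expect_gt(r$grain_yield, 0)
  expect_lte(r$grain_yield, cv$hi_max * r$total_biomass + 1e-9)
  expect_true(all(r$daily$lai >= 0))
  expect_lt(r$water_residual, 1e-6)
  expect_lte(r$cumulative_et, sum(r$daily$et0) + 1e-9)
  # unstressed canopy peaks at lai_max exactly on the anthesis day
  expect_equal(r$max_lai, cv$lai_max, tolerance = 1e-9)
  expect_equal(r$max_lai_doy, as.POSIXlt(r$anthesis_date)$yday + 1L)
  expect_equal(max_lai_date(r), r$max_lai_doy)
  # cumulative ET non-decreasing
  expect_true(all(diff(cumsum(r$daily$evap + r$daily$transp)) >= 0))
  # determinism: identical runs are identical
  r2 <- simulate_season(wx, default_soil(), cv, as.Date("2018-03-15"))
  expect_identical(r$daily, r2$daily)
  expect_identical(r$grain_yield, r2$grain_yield)
})

test_that("max LAI day takes the earliest day on ties", {
  r <- list(daily = data.frame(
    date = seq(as.Date("2018-07-05"), by = "day", length.out = 7),
    lai = c(1, 2, 3, 3, 3, 2, 1)))
  expect_equal(max_lai_date(r), as.POSIXlt(as.Date("2018-07-07"))$yday + 1L)
  expect_error(max_lai_date(list(daily = data.frame())), "empty")
})

test_that("yield never increases as seasonal rainfall is scaled down", {
  base <- constant_weather(rain = 6)
  prev <- Inf
  for (f in c(1, 0.75, 0.5, 0.25, 0)) {
    wf <- base
    wf$rain <- base$rain * f
    y <- simulate_season(wf, default_soil(), default_cultivar(),
                         as.Date("2018-03-15"))$grain_yield
    expect_lte(y, prev + 1e-9)
    prev <- y
  }
  # total water limitation: no transpiration, no yield
  dry <- base; dry$rain <- 0
  s <- default_soil(); s$layers$sw_init <- s$layers$ll
  rd <- simulate_season(dry, s, default_cultivar(), as.Date("2018-03-15"))
  expect_equal(rd$grain_yield, 0)
  expect_lt(sum(rd$daily$transp), 1e-9)
})

test_that("phenology shifts day-for-day with sowing under constant weather", {
  wx <- constant_weather(days = 450)
  r1 <- simulate_season(wx, default_soil(), default_cultivar(),
                        as.Date("2018-03-10"))
  r2 <- simulate_season(wx, default_soil(), default_cultivar(),
                        as.Date("2018-03-17"))
  expect_equal(as.numeric(r2$emergence_date - r1$emergence_date), 7)
  expect_equal(as.numeric(r2$anthesis_date - r1$anthesis_date), 7)
  expect_equal(as.numeric(r2$maturity_date - r1$maturity_date), 7)
})

test_that("weather contract is enforced", {
  wx <- constant_weather()
  expect_error(simulate_season(wx[-20, ], default_soil(), default_cultivar(),
                               as.Date("2018-01-01")), "gap")
  expect_error(simulate_season(wx, default_soil(), default_cultivar(),
                               as.Date("2017-12-31")), "sowing")
  expect_error(simulate_season(wx, default_soil(), default_cultivar(),
                               as.Date("2016-01-01")), "cover")
  # cold weather: crop never emerges, flagged with zero yield
  cold <- constant_weather(tmax = 8, tmin = 2)
  rc <- simulate_season(cold, default_soil(), default_cultivar(),
                        as.Date("2018-03-15"), max_days = 200)
  expect_false(rc$completed)
  expect_true(is.na(rc$emergence_date))
  expect_equal(rc$grain_yield, 0)
})
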