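#' Daily thermal time (growing degree days)
#'
#' `GDD = max(0, min((tmax + tmin)/2, tceil) - tbase)`. Drives all
#' phenological development in the simulator.
#'
#' @param tmax,tmin daily maximum/minimum air temperature, degrees C.
#' @param tbase base temperature (default 8 C for tropical maize).
#' @param tceil ceiling temperature (default 34 C).
#' @return degree days (C day), vectorised.
#' @export
thermal_time <- function(tmax, tmin, tbase = 8, tceil = 34) {
  if (any(tmax < tmin)) stop("tmax < tmin")
  pmax(0, pmin((tmax + tmin) / 2, tceil) - tbase)
}

#' Priestley-Taylor potential evapotranspiration
#'
#' Radiation/temperature-only potential ET as a coefficient times
#' equilibrium evaporation:
#' `EEQ = srad * (4.88e-3 - 4.37e-3 * albedo) * (Td + 29)` with
#' `Td = 0.6 tmax + 0.4 tmin`; `ET0 = alpha * EEQ` in the ordinary range,
#' with the long-published high/low temperature adjustments above 35 C
#' (`EEQ * ((tmax - 35) * 0.05 + alpha)`) and below 5 C
#' (`EEQ * 0.01 * exp(0.18 * (tmax + 20))`). Recommended for humid
#' environments where radiation dominates the evaporative demand.
#'
#' @param srad solar radiation, MJ m-2 d-1.
#' @param tmax,tmin daily max/min temperature, C.
#' @param albedo surface albedo (fraction).
#' @param pt_alpha Priestley-Taylor coefficient (default 1.1).
#' @return potential ET, mm d-1 (>= 0), vectorised.
#' @export
priestley_taylor_et0 <- function(srad, tmax, tmin, albedo = 0.23,
                                 pt_alpha = 1.1) {
  if (any(srad < 0)) stop("negative solar radiation")
  if (any(tmax < tmin)) stop("tmax < tmin")
  td <- 0.6 * tmax + 0.4 * tmin
  eeq <- srad * (4.88e-3 - 4.37e-3 * albedo) * (td + 29)
  mult <- ifelse(tmax > 35, (tmax - 35) * 0.05 + pt_alpha,
                 ifelse(tmax < 5, 0.01 * exp(0.18 * (tmax + 20)), pt_alpha))
  pmax(0, eeq * mult)
}

#' Partition potential ET into soil evaporation and transpiration
#'
#' Beer's-law canopy shading: potential soil evaporation is
#' `ET0 * exp(-k * LAI)`, the remainder is potential transpiration; the
#' two always sum to ET0.
#'
#' @param et0 potential ET, mm d-1.
#' @param lai leaf area index (>= 0).
#' @param k_light canopy extinction coefficient (default 0.7).
#' @return list `pot_soil_evap`, `pot_transp` (mm d-1).
#' @export
partition_et <- function(et0, lai, k_light = 0.7) {
  stopifnot(all(et0 >= 0), all(lai >= 0))
  es <- et0 * exp(-k_light * lai)
  list(pot_soil_evap = es, pot_transp = et0 - es)
}

#' Construct and validate a layered soil profile
#'
#' @param thickness_cm,ll,dul,sat,sw_init per-layer vectors: thickness
#'   (cm) and volumetric lower limit, drained upper limit, saturation and
#'   initial water content (cm3 cm-3), with `ll < dul < sat` and
#'   `ll <= sw_init <= sat`.
#' @param drainage_coefficient fraction of water above DUL draining to the
#'   next layer per day, in `[0, 1]`.
#' @param runoff_curve_number SCS curve number for daily runoff.
#' @param albedo dry-soil albedo (fraction).
#' @return list of class `soil_profile`.
#' @export
soil_profile <- function(thickness_cm, ll, dul, sat, sw_init = dul,
                         drainage_coefficient = 0.4,
                         runoff_curve_number = 75, albedo = 0.13) {
  n <- length(thickness_cm)
  ll <- rep_len(ll, n); dul <- rep_len(dul, n); sat <- rep_len(sat, n)
  sw_init <- rep_len(sw_init, n)
  stopifnot(all(thickness_cm > 0), all(ll < dul), all(dul < sat),
            all(sw_init >= ll), all(sw_init <= sat),
            drainage_coefficient >= 0, drainage_coefficient <= 1,
            runoff_curve_number > 0, runoff_curve_number <= 100,
            albedo >= 0, albedo < 1)
  structure(list(
    layers = data.frame(thickness_cm = thickness_cm, ll = ll, dul = dul,
                        sat = sat, sw_init = sw_init),
    drainage_coefficient = drainage_coefficient,
    runoff_curve_number = runoff_curve_number,
    albedo = albedo
  ), class = "soil_profile")
}

#' Default soil profile
#'
#' A synthetic deep clay-loam profile broadly representative of the
#' well-drained Nitisol/Ferralsol soils of highland western Kenya maize
#' zones; shipped as a stand-in because no site profile is bundled.
#' @return a [soil_profile()].
#' @export
default_soil <- function() {
  soil_profile(
    thickness_cm = c(15, 15, 30, 30),
    ll = 0.18, dul = 0.29, sat = 0.39,
    sw_init = 0.23,
    drainage_coefficient = 0.4,
    runoff_curve_number = 75,
    albedo = 0.13
  )
}

#' Construct and validate cultivar parameters
#'
#' Thermal-time and growth coefficients of the reduced CERES-style maize
#' model. All thermal times are degree days above `tbase`.
#'
#' @param tbase base temperature, C.
#' @param tceil ceiling temperature for thermal time, C.
#' @param tt_emergence sowing to emergence.
#' @param p1 emergence to end of the juvenile phase.
#' @param tt_anth_extra end-juvenile to anthesis.
#' @param p5 anthesis to physiological maturity.
#' @param phint phyllochron interval (degree days per leaf tip).
#' @param lai_max peak leaf area index attained unstressed at anthesis.
#' @param rue radiation use efficiency, g biomass per MJ intercepted PAR.
#' @param k_light canopy extinction coefficient.
#' @param hi_max maximum harvest index.
#' @param pt_alpha Priestley-Taylor coefficient.
#' @return list of class `cultivar_params`.
#' @export
cultivar_params <- function(tbase = 8, tceil = 34, tt_emergence = 60,
                            p1 = 220, tt_anth_extra = 550, p5 = 700,
                            phint = 45, lai_max = 4.5, rue = 3.3,
                            k_light = 0.7, hi_max = 0.5, pt_alpha = 1.1) {
  stopifnot(tt_emergence > 0, p1 > 0, tt_anth_extra > 0, p5 > 0, phint > 0,
            lai_max > 0, rue > 0, k_light > 0, k_light <= 1.2,
            hi_max > 0, hi_max < 1, pt_alpha > 0, tceil > tbase)
  structure(as.list(environment()), class = "cultivar_params")
}

#' Default (synthetic) maize cultivar
#'
#' A synthetic medium-duration highland cultivar: the coefficient values
#' are plausible for the region's hybrids but are not a calibrated set,
#' and are documented as such.
#' @return a [cultivar_params()].
#' @export
default_cultivar <- function() cultivar_params()

#' One daily step of the tipping-bucket soil water balance
#'
#' Order of operations: curve-number runoff on daily rain; infiltration
#' fills layers top-down (water above saturation passes on immediately,
#' water between DUL and SAT drains downward at `drainage_coefficient`
#' per day; the bottom layer drains out of the profile); soil evaporation
#' from the top layer down to `0.5 * LL`; transpiration from rooted
#' layers limited by plant-available water (`sw - LL`), extracted
#' proportionally to each layer's available water. The daily mass balance
#' `rain = d(storage) + runoff + drainage + evap + transp` closes to
#' numerical precision.
#'
#' @param sw per-layer volumetric water content (cm3 cm-3).
#' @param soil a [soil_profile()].
#' @param rain daily rainfall, mm.
#' @param pot_soil_evap,pot_transp potential fluxes, mm d-1.
#' @param root_depth rooting front depth, cm.
#' @return list `sw` (updated contents), `runoff`, `drainage`, `evap`,
#'   `transp`, `residual` (mass-balance residual, mm).
#' @export
soil_water_step <- function(sw, soil, rain, pot_soil_evap, pot_transp,
                            root_depth) {
  stopifnot(rain >= 0, pot_soil_evap >= 0, pot_transp >= 0)
  ly <- soil$layers
  n <- nrow(ly)
  mmcap <- ly$thickness_cm * 10            # mm of water per unit theta
  w <- sw * mmcap                          # mm per layer
  ll_mm <- ly$ll * mmcap
  dul_mm <- ly$dul * mmcap
  sat_mm <- ly$sat * mmcap
  w0 <- sum(w)

  # surface runoff (SCS curve number, daily)
  runoff <- 0
  if (rain > 0) {
    s <- 254 * (100 / soil$runoff_curve_number - 1)
    ia <- 0.2 * s
    if (rain > ia) runoff <- (rain - ia)^2 / (rain - ia + s)
  }
  inflow <- rain - runoff

  # infiltration + drainage cascade, top down
  for (i in seq_len(n)) {
    w[i] <- w[i] + inflow
    over_sat <- max(0, w[i] - sat_mm[i])
    w[i] <- w[i] - over_sat
    drain <- soil$drainage_coefficient * max(0, w[i] - dul_mm[i])
    w[i] <- w[i] - drain
    inflow <- over_sat + drain
  }
  drainage <- inflow

  # soil evaporation from the top layer, down to 0.5 * LL
  avail_e <- max(0, w[1L] - 0.5 * ll_mm[1L])
  evap <- min(pot_soil_evap, avail_e)
  w[1L] <- w[1L] - evap

  # transpiration from rooted layers, proportional extraction
  top <- cumsum(ly$thickness_cm) - ly$thickness_cm
  rooted <- pmin(pmax(root_depth - top, 0), ly$thickness_cm) / ly$thickness_cm
  avail_t <- pmax(0, w - ll_mm) * rooted
  total_avail <- sum(avail_t)
  transp <- min(pot_transp, total_avail)
  if (transp > 0) w <- w - transp * avail_t / total_avail

  if (any(w < -1e-9) || any(w > sat_mm + 1e-9)) {
    stop("soil water state outside [0, SAT] after update")
  }
  residual <- rain - (sum(w) - w0) - runoff - drainage - evap - transp
  list(sw = w / mmcap, runoff = runoff, drainage = drainage,
       evap = evap, transp = transp, residual = residual)
}

#' Soil-water stress factor
#'
#' Ratio of actual to potential transpiration, clamped to `[0, 1]`;
#' defined as 1 when there is no transpirative demand. Scales both leaf
#' expansion and daily biomass growth.
#'
#' @param actual_transp,pot_transp mm d-1.
#' @return factor in `[0, 1]`.
#' @export
water_stress_factor <- function(actual_transp, pot_transp) {
  stopifnot(all(pot_transp >= 0))
  ifelse(pot_transp == 0, 1, pmin(1, pmax(0, actual_transp / pot_transp)))
}

#' Daily biomass increment from intercepted radiation
#'
#' Radiation-driven growth: `dB = RUE * 0.5 * srad * (1 - exp(-k * LAI))
#' * stress`, with 0.5 the photosynthetically active fraction of global
#' radiation.
#'
#' @param srad solar radiation, MJ m-2 d-1.
#' @param lai leaf area index.
#' @param rue radiation use efficiency, g MJ-1 (PAR).
#' @param k_light canopy extinction coefficient.
#' @param stress water stress factor in `[0, 1]`.
#' @return biomass increment, g m-2 d-1.
#' @export
daily_growth <- function(srad, lai, rue, k_light, stress) {
  stopifnot(all(srad >= 0), all(lai >= 0), all(stress >= 0),
            all(stress <= 1))
  rue * 0.5 * srad * (1 - exp(-k_light * lai)) * stress
}

#' Phenological stage from cumulative thermal time
#'
#' Maps a (monotone, non-decreasing) daily series of cumulative degree
#' days since sowing to developmental stages. Transitions fire on the
#' first day their threshold is met and occur at most once: emergence at
#' `tt_emergence` after sowing; end of the juvenile phase `p1` after
#' emergence; anthesis `p1 + tt_anth_extra` after emergence; maturity
#' `p5` after anthesis.
#'
#' @param cum_gdd cumulative degree days since sowing, one value per day
#'   (day 1 = first day after sowing).
#' @param params a [cultivar_params()].
#' @return list `stage` (character vector per day, from `"sown"`,
#'   `"emerged"`, `"vegetative"`, `"anthesis"`, `"grainfill"`,
#'   `"mature"`) and `day_of` (named integer vector of transition days,
#'   `NA` when not reached).
#' @export
advance_phenology <- function(cum_gdd, params) {
  if (any(diff(cum_gdd) < 0)) stop("cumulative GDD must be non-decreasing")
  n <- length(cum_gdd)
  emerg <- match(TRUE, cum_gdd >= params$tt_emergence)
  gdd_e <- if (!is.na(emerg)) cum_gdd - cum_gdd[emerg] else rep(NA_real_, n)
  endjuv <- if (!is.na(emerg)) match(TRUE, gdd_e >= params$p1) else NA_integer_
  anth <- if (!is.na(emerg)) {
    match(TRUE, gdd_e >= params$p1 + params$tt_anth_extra)
  } else NA_integer_
  mat <- if (!is.na(anth)) {
    match(TRUE, cum_gdd - cum_gdd[anth] >= params$p5)
  } else NA_integer_
  stage <- rep("sown", n)
  if (!is.na(emerg)) stage[emerg:n] <- "emerged"
  if (!is.na(endjuv)) stage[endjuv:n] <- "vegetative"
  if (!is.na(anth)) stage[anth:n] <- "anthesis"
  if (!is.na(anth) && anth < n) stage[(anth + 1L):n] <- "grainfill"
  if (!is.na(mat)) stage[mat:n] <- "mature"
  list(stage = stage,
       day_of = c(emergence = emerg, end_juvenile = endjuv,
                  anthesis = anth, maturity = mat))
}

#' Update leaf area index by one day
#'
#' Vegetative expansion at `lai_max / (p1 + tt_anth_extra)` per degree
#' day, scaled by the water-stress factor, up to anthesis; after anthesis
#' linear senescence in thermal time down to 15 percent of the attained
#' peak at maturity. Never negative.
#'
#' @param lai current LAI.
#' @param phase `"vegetative"` (pre-anthesis, post-emergence) or
#'   `"senescence"` (post-anthesis).
#' @param daily_gdd the day's thermal time.
#' @param stress water stress factor.
#' @param params a [cultivar_params()].
#' @param peak_lai LAI attained at anthesis (senescence only).
#' @param gdd_since_anthesis cumulative thermal time since anthesis
#'   (senescence only).
#' @return updated LAI.
#' @export
update_lai <- function(lai, phase, daily_gdd, stress, params,
                       peak_lai = NA, gdd_since_anthesis = NA) {
  if (phase == "vegetative") {
    rate <- params$lai_max / (params$p1 + params$tt_anth_extra)
    max(0, lai + rate * daily_gdd * stress)
  } else {
    frac <- min(1, gdd_since_anthesis / params$p5)
    max(0, peak_lai * (1 - 0.85 * frac))
  }
}

#' Simulate one maize growing season on a daily time step
#'
#' The daily loop composes thermal-time phenology, water-stressed LAI
#' dynamics, Priestley-Taylor potential ET partitioned by canopy cover,
#' the tipping-bucket soil water balance (rooting front advancing 2.5 cm
#' per day to the profile bottom), and radiation-use-efficiency biomass
#' growth. Surface albedo evolves linearly from the soil value to 0.23 as
#' LAI reaches 3. Grain yield is total biomass times a harvest index that
#' grows linearly from 0 at anthesis to `hi_max` at maturity, scaled by
#' the mean grain-fill water stress. The season is capped 250 days after
#' sowing; a crop that never emerges or matures is flagged.
#'
#' @param weather data.frame `date, srad, tmax, tmin, rain` of
#'   consecutive daily records covering sowing to at least maturity (or
#'   the season cap).
#' @param soil a [soil_profile()].
#' @param cultivar a [cultivar_params()].
#' @param sowing_date `Date`.
#' @param max_days season cap, days after sowing (default 250).
#' @return object of class `season_result`: list with phenology dates,
#'   `daily` trajectory data.frame (`date, gdd, lai, et0, evap, transp,
#'   runoff, drainage, rain, sw_total, biomass`), `grain_yield` and
#'   `total_biomass` (kg ha-1), `cumulative_et` (mm, sowing to maturity),
#'   `max_lai`, `max_lai_doy`, `completed`, `water_residual`.
#' @export
simulate_season <- function(weather, soil, cultivar, sowing_date,
                            max_days = 250) {
  sowing_date <- as.Date(sowing_date)
  weather$date <- as.Date(weather$date)
  w <- weather[weather$date >= sowing_date &
                 weather$date <= sowing_date + max_days, , drop = FALSE]
  w <- w[order(w$date), , drop = FALSE]
  if (nrow(w) < 2L) stop("weather does not cover the season")
  if (w$date[1L] != sowing_date) stop("weather missing the sowing date")
  if (any(diff(as.numeric(w$date)) != 1)) stop("weather gap: missing day(s)")
  if (any(w$tmax < w$tmin) || any(w$srad < 0) || any(w$rain < 0)) {
    stop("invalid weather record")
  }
  n <- nrow(w)
  ly <- soil$layers
  depth_total <- sum(ly$thickness_cm)
  sw <- ly$sw_init

  gdd_day <- thermal_time(w$tmax, w$tmin, cultivar$tbase, cultivar$tceil)
  p_anth <- cultivar$p1 + cultivar$tt_anth_extra  # emergence -> anthesis
  lai <- 0
  peak_lai <- 0
  biomass <- 0
  cum_gdd <- 0
  emerged <- FALSE
  anth_day <- NA_integer_
  emergence <- anthesis <- maturity <- as.Date(NA)
  stress_gf <- numeric(0)
  veg_rate <- cultivar$lai_max / p_anth

  rec <- matrix(NA_real_, n, 10,
                dimnames = list(NULL, c("gdd", "lai", "et0", "evap", "transp",
                                        "runoff", "drainage", "rain",
                                        "sw_total", "biomass")))
  residual_max <- 0
  last_day <- n

  for (i in seq_len(n)) {
    albedo <- soil$albedo + (0.23 - soil$albedo) * min(lai, 3) / 3
    et0 <- priestley_taylor_et0(w$srad[i], w$tmax[i], w$tmin[i], albedo,
                                cultivar$pt_alpha)
    part <- partition_et(et0, lai, cultivar$k_light)
    root_depth <- min(depth_total, 2.5 * i)
    st <- soil_water_step(sw, soil, w$rain[i], part$pot_soil_evap,
                          part$pot_transp, root_depth)
    sw <- st$sw
    residual_max <- max(residual_max, abs(st$residual))
    stress <- water_stress_factor(st$transp, part$pot_transp)

    q_prev <- if (emerged) cum_gdd - cultivar$tt_emergence else 0
    cum_gdd <- cum_gdd + gdd_day[i]

    # phase origins anchored at the exact thresholds, so cultivar
    # degree-day arithmetic holds exactly under constant weather
    if (!emerged && cum_gdd >= cultivar$tt_emergence) {
      emerged <- TRUE
      emergence <- w$date[i]
      q_prev <- 0
    }
    if (emerged && is.na(anth_day)) {
      q_new <- cum_gdd - cultivar$tt_emergence
      # vegetative expansion on the thermal time effective before anthesis
      eff <- min(q_new, p_anth) - min(q_prev, p_anth)
      lai <- max(0, lai + veg_rate * eff * stress)
      if (q_new >= p_anth) {
        anth_day <- i
        anthesis <- w$date[i]
        peak_lai <- lai
      }
    } else if (!is.na(anth_day) && i > anth_day) {
      # linear senescence to 15% of the attained peak at maturity
      frac <- min(1, (cum_gdd - cultivar$tt_emergence - p_anth) / cultivar$p5)
      lai <- max(0, peak_lai * (1 - 0.85 * frac))
    }
    if (!is.na(anth_day)) stress_gf <- c(stress_gf, stress)
    if (!is.na(anth_day) && is.na(maturity) &&
        cum_gdd - cultivar$tt_emergence - p_anth >= cultivar$p5) {
      maturity <- w$date[i]
    }

    # growth
    biomass <- biomass + daily_growth(w$srad[i], lai, cultivar$rue,
                                      cultivar$k_light, stress)

    rec[i, ] <- c(gdd_day[i], lai, et0, st$evap, st$transp, st$runoff,
                  st$drainage, w$rain[i], sum(sw * ly$thickness_cm * 10),
                  biomass)
    if (!is.na(maturity)) { last_day <- i; break }
  }

  rec <- rec[seq_len(last_day), , drop = FALSE]
  daily <- data.frame(date = w$date[seq_len(last_day)], rec)
  completed <- !is.na(maturity)

  # harvest index: linear 0 -> hi_max over grain fill, scaled by mean
  # grain-fill stress
  if (!is.na(anth_day)) {
    gf_frac <- min(1, max(0, cum_gdd - cultivar$tt_emergence - p_anth) /
                     cultivar$p5)
    hi <- cultivar$hi_max * gf_frac *
      (if (length(stress_gf)) mean(stress_gf) else 1)
  } else {
    hi <- 0
  }
  grain_yield <- biomass * hi * 10        # g m-2 -> kg ha-1
  total_biomass <- biomass * 10
  if (is.na(emergence)) grain_yield <- 0

  imax <- which.max(daily$lai)             # earliest day on ties
  structure(list(
    sowing_date = sowing_date,
    emergence_date = emergence,
    anthesis_date = anthesis,
    maturity_date = maturity,
    daily = daily,
    grain_yield = grain_yield,
    total_biomass = total_biomass,
    cumulative_et = sum(daily$evap + daily$transp),
    max_lai = daily$lai[imax],
    max_lai_doy = as.POSIXlt(daily$date[imax])$yday + 1L,
    completed = completed,
    water_residual = residual_max
  ), class = "season_result")
}

#' Day-of-year of maximum simulated LAI
#'
#' The simulator's peak-season indicator, compared against the
#' maximum-season (MS) dekad of the remote-sensing phenology. Earliest
#' day on ties, so the comparison is deterministic.
#'
#' @param result a [simulate_season()] result.
#' @return integer day-of-year.
#' @export
max_lai_date <- function(result) {
  if (!nrow(result$daily)) stop("empty LAI series")
  imax <- which.max(result$daily$lai)
  as.integer(as.POSIXlt(result$daily$date[imax])$yday + 1L)
}

#' @export
print.season_result <- function(x, ...) {
  cat("Season: sown", format(x$sowing_date),
      if (x$completed) paste("matured", format(x$maturity_date)) else
        "(did not mature)", "\n")
  cat(sprintf("  yield %.0f kg/ha  biomass %.0f kg/ha  ET %.0f mm  max LAI %.2f (doy %d)\n",
              x$grain_yield, x$total_biomass, x$cumulative_et,
              x$max_lai, x$max_lai_doy))
  invisible(x)
}
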