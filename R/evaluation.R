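#' Regional (sub-county) mean of grid values
#'
#' Arithmetic mean per region and year of a grid-level variable; missing
#' grid values are excluded and `n_grids` reports the count actually
#' used. Regions with no valid grid in a year are omitted with a warning.
#'
#' @param grid_values data.frame `grid_id, year, value`.
#' @param grid_regions data.frame `grid_id, region_id` (one region per
#'   grid).
#' @return data.frame `region_id, year, mean_value, n_grids`.
#' @export
aggregate_mean <- function(grid_values, grid_regions) {
  m <- merge(grid_values, unique(grid_regions[, c("grid_id", "region_id")]),
             by = "grid_id")
  dropped <- !is.finite(m$value)
  if (any(dropped)) m <- m[!dropped, , drop = FALSE]
  if (nrow(m) == 0L) {
    warning("no valid grid values in any region")
    return(data.frame(region_id = character(0), year = integer(0),
                      mean_value = numeric(0), n_grids = integer(0)))
  }
  agg <- stats::aggregate(value ~ region_id + year, data = m,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ region_id + year, data = m,
                          FUN = length)
  out <- data.frame(region_id = agg$region_id, year = agg$year,
                    mean_value = agg$value, n_grids = cnt$value)
  out[order(out$region_id, out$year), , drop = FALSE]
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors; at least 3 complete pairs with nonzero
#'   variance in both.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined statistic: zero variance")
  }
  stats::cor(x, y)
}

#' Coefficient of determination as squared Pearson correlation
#'
#' The scatter-plot convention for comparing two measurement methods
#' (simulated vs remote-sensing-observed): `R2 = pearson_r(x, y)^2`, not
#' one minus a residual ratio about a fitted line (the two agree for a
#' simple linear fit of y on x).
#'
#' @inheritParams pearson_r
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y) pearson_r(x, y)^2

#' Percent deviation of a simulation from a reference
#'
#' `100 * (simulated - reference) / reference`; scale-invariant and used
#' to map per-grid seasonal ET deviation against the satellite-derived
#' reference.
#'
#' @param simulated,reference numeric (reference strictly positive).
#' @return percent deviation, vectorised.
#' @export
percent_deviation <- function(simulated, reference) {
  if (any(reference <= 0)) stop("undefined deviation: reference must be > 0")
  100 * (simulated - reference) / reference
}

#' Compare simulated peak-season dates with remote-sensing MS phenology
#'
#' Pairs each grid-season's simulated maximum-LAI day-of-year with the
#' midpoint day-of-year of its maximum-season (MS) dekad, and reports the
#' pairs and their squared Pearson correlation. Grid-seasons present in
#' only one input are dropped (count reported).
#'
#' @param sim data.frame `grid_id, season_year, max_lai_doy`.
#' @param lsp data.frame `grid_id, season_year, ms` (dekad index).
#' @return list `pairs` (data.frame with `grid_id, season_year,
#'   sim_doy, ms_doy`), `r2`, `n`, `n_dropped`.
#' @export
compare_phenology <- function(sim, lsp) {
  p <- merge(sim[, c("grid_id", "season_year", "max_lai_doy")],
             lsp[, c("grid_id", "season_year", "ms")],
             by = c("grid_id", "season_year"))
  if (nrow(p) == 0L) stop("no overlapping grid-seasons between inputs")
  p$sim_doy <- p$max_lai_doy
  p$ms_doy <- dekad_midpoint_doy(p$ms, p$season_year)
  n_dropped <- (nrow(sim) - nrow(p)) + (nrow(lsp) - nrow(p))
  list(pairs = p[, c("grid_id", "season_year", "sim_doy", "ms_doy")],
       r2 = r_squared(p$sim_doy, p$ms_doy),
       n = nrow(p), n_dropped = n_dropped)
}

#' Sowing-date sensitivity of yield and ET agreement
#'
#' The shift experiment: every grid's estimated sowing date is displaced
#' by each offset in `offsets` (ten-day steps spanning 30 days before and
#' after the estimate: six shifted scenarios plus the baseline 0), the
#' season is re-simulated, simulated yield and cumulative ET are
#' aggregated to region-year means, and each region's Pearson correlation
#' across years against the observed yields and the reference ET is
#' computed. Regions with fewer than `min_years` paired years are skipped
#' with a warning.
#'
#' @param baseline data.frame `grid_id, season_year, sowing_date` of
#'   baseline (remote-sensing-estimated) sowing dates.
#' @param weather data.frame `grid_id, date, srad, tmax, tmin, rain`
#'   covering all shifted seasons.
#' @param soil a [soil_profile()] (shared across grids).
#' @param cultivar a [cultivar_params()].
#' @param grid_regions data.frame `grid_id, region_id`.
#' @param obs_yields data.frame `region_id, year, yield` (observed).
#' @param ref_et data.frame `grid_id, year, et` (reference seasonal ET
#'   per grid, aggregated internally to region-year means).
#' @param offsets integer offsets in days (default
#'   `c(-30, -20, -10, 0, 10, 20, 30)`).
#' @param min_years minimum paired years per region (default 3).
#' @param pooled if `TRUE`, also correlate across all region-years pooled
#'   (more stable than the 5-point per-region correlations), returned as
#'   extra rows with `region_id = "(pooled)"`.
#' @return data.frame `region_id, offset_days, r_yield, r_et, n_years`.
#' @export
sowing_sensitivity <- function(baseline, weather, soil, cultivar,
                               grid_regions, obs_yields, ref_et,
                               offsets = seq(-30L, 30L, by = 10L),
                               min_years = 3L, pooled = FALSE) {
  weather$date <- as.Date(weather$date)
  wx_by_grid <- split(weather, weather$grid_id)
  ref_reg <- aggregate_mean(
    data.frame(grid_id = ref_et$grid_id, year = ref_et$year,
               value = ref_et$et), grid_regions)
  regions <- unique(grid_regions$region_id)
  rows <- list()
  for (off in offsets) {
    sim_rows <- vector("list", nrow(baseline))
    for (j in seq_len(nrow(baseline))) {
      b <- baseline[j, ]
      res <- simulate_season(wx_by_grid[[as.character(b$grid_id)]], soil,
                             cultivar, as.Date(b$sowing_date) + off)
      sim_rows[[j]] <- data.frame(grid_id = b$grid_id,
                                  year = b$season_year,
                                  yield = res$grain_yield,
                                  et = res$cumulative_et)
    }
    sim <- do.call(rbind, sim_rows)
    yld_reg <- aggregate_mean(
      data.frame(grid_id = sim$grid_id, year = sim$year, value = sim$yield),
      grid_regions)
    et_reg <- aggregate_mean(
      data.frame(grid_id = sim$grid_id, year = sim$year, value = sim$et),
      grid_regions)
    for (rg in regions) {
      ys <- merge(yld_reg[yld_reg$region_id == rg, ],
                  obs_yields[obs_yields$region_id == rg, ],
                  by.x = c("region_id", "year"),
                  by.y = c("region_id", "year"))
      es <- merge(et_reg[et_reg$region_id == rg, ],
                  ref_reg[ref_reg$region_id == rg, ],
                  by = c("region_id", "year"))
      if (nrow(ys) < min_years) {
        warning("region ", rg, " skipped: fewer than ", min_years,
                " paired years")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = rg, offset_days = off,
        r_yield = pearson_r(ys$mean_value, ys$yield),
        r_et = pearson_r(es$mean_value.x, es$mean_value.y),
        n_years = nrow(ys))
    }
    if (pooled) {
      ya <- merge(yld_reg, obs_yields, by = c("region_id", "year"))
      ea <- merge(et_reg, ref_reg, by = c("region_id", "year"))
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = "(pooled)", offset_days = off,
        r_yield = pearson_r(ya$mean_value, ya$yield),
        r_et = pearson_r(ea$mean_value.x, ea$mean_value.y),
        n_years = nrow(ya))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(region_id = character(0), offset_days = integer(0),
                      r_yield = numeric(0), r_et = numeric(0),
                      n_years = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
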