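#' Sowing-date estimator configuration
#'
#' Operational thresholds for the sowing-retrieval rule: the sowing date is
#' the zero-gradient minimum of the fitted NDVI curve closest before the
#' start of season (SOS), with shallow pre-season bumps ("false minor
#' peaks", e.g. weed regrowth after land preparation) ignored.
#'
#' @param search_window days before SOS to scan for minima (default 90).
#' @param evaluation_step grid step in days for bracketing sign changes of
#'   the derivative (default 1; minima are then refined by bisection).
#' @param prominence_fraction minimum prominence of an intervening peak,
#'   as a fraction of the seasonal amplitude, for the minima it separates
#'   to be considered distinct (default 0.10).
#' @param fallback_lag days before SOS assumed when no zero-gradient
#'   minimum is found in the window (default 30); such estimates are
#'   flagged.
#' @param selection `"latest"` (default): the surviving minimum closest
#'   before SOS; `"lowest"`: the deepest surviving minimum in the window.
#' @return list of class `estimator_config`.
#' @export
estimator_config <- function(search_window = 90, evaluation_step = 1,
                             prominence_fraction = 0.10, fallback_lag = 30,
                             selection = c("latest", "lowest")) {
  selection <- match.arg(selection)
  stopifnot(search_window > 0, evaluation_step >= 0.1,
            prominence_fraction >= 0, prominence_fraction < 1,
            fallback_lag > 0)
  structure(list(search_window = search_window,
                 evaluation_step = evaluation_step,
                 prominence_fraction = prominence_fraction,
                 fallback_lag = fallback_lag,
                 selection = selection),
            class = "estimator_config")
}

#' Local minima of a fitted NDVI curve in a window
#'
#' Scans `[t_start, t_end]` at `step`-day resolution for sign changes of
#' the analytic derivative from negative to positive, then refines each
#' bracket by bisection until |slope| < 1e-8 NDVI/day.
#'
#' @param model a [fit_harmonic()] model.
#' @param t_start,t_end window bounds (`Date` or days since the model's
#'   reference date).
#' @param step evaluation grid step in days.
#' @return data.frame `t, date, ndvi` of minima sorted by time (possibly
#'   zero rows).
#' @export
find_candidate_minima <- function(model, t_start, t_end, step = 1) {
  t1 <- model_time(model, t_start)
  t2 <- model_time(model, t_end)
  if (!(t1 < t2)) stop("empty search window: t_start must precede t_end")
  grid <- seq(t1, t2, by = step)
  if (grid[length(grid)] < t2) grid <- c(grid, t2)
  d <- harmonic_slope_t(model, grid)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (d[i] < 0 && d[i + 1L] > 0) {
      roots <- c(roots, bisect_slope(model, grid[i], grid[i + 1L]))
    } else if (d[i] == 0 && (i == 1L || d[max(i - 1L, 1L)] < 0) &&
               d[i + 1L] > 0) {
      roots <- c(roots, grid[i])
    }
  }
  out <- data.frame(t = roots)
  out$date <- as.Date(round(roots), origin = as.Date(model$reference_date))
  out$ndvi <- if (length(roots)) harmonic_value_t(model, roots) else numeric(0)
  out[order(out$t), , drop = FALSE]
}

# bisection on the analytic derivative to |slope| < 1e-8
bisect_slope <- function(model, lo, hi, tol = 1e-8) {
  flo <- harmonic_slope_t(model, lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- harmonic_slope_t(model, mid)
    if (abs(fm) < tol || (hi - lo) < 1e-12) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  mid
}

# fitted value at numeric model time
fitted_at <- function(model, t) harmonic_value_t(model, t)

#' Discard minima separated only by shallow false peaks
#'
#' A pre-season bump whose rise above both flanking minima is less than
#' `prominence_fraction` times the seasonal amplitude is treated as noise
#' (e.g. weed regrowth after land preparation): the earlier of the two
#' minima it separates is merged into the later, deeper structure.
#'
#' @param minima data.frame from [find_candidate_minima()].
#' @param model the fitted `harmonic_model`.
#' @param prominence_fraction threshold as a fraction of seasonal
#'   amplitude.
#' @param amplitude_window length-2 numeric (model days) over which the
#'   seasonal amplitude (max - min of the fitted curve) is measured.
#' @return filtered minima data.frame, chronological order preserved.
#' @export
reject_false_peaks <- function(minima, model, prominence_fraction,
                               amplitude_window) {
  if (nrow(minima) <= 1L || prominence_fraction <= 0) return(minima)
  ag <- seq(amplitude_window[1L], amplitude_window[2L], by = 1)
  amp <- diff(range(fitted_at(model, ag)))
  thr <- prominence_fraction * amp
  repeat {
    if (nrow(minima) <= 1L) break
    dropped <- FALSE
    for (i in seq_len(nrow(minima) - 1L)) {
      seg <- seq(minima$t[i], minima$t[i + 1L], length.out = 64L)
      peak <- max(fitted_at(model, seg))
      rise <- min(peak - minima$ndvi[i], peak - minima$ndvi[i + 1L])
      if (rise < thr) {
        # keep the later, deeper structure; drop the earlier minimum
        minima <- minima[-i, , drop = FALSE]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  minima
}

#' Estimate the sowing date for one pixel
#'
#' Applies the retrieval rule to a fitted NDVI curve: sowing is the latest
#' zero-gradient minimum inside the half-open window
#' `[sos_start - search_window, sos_start)` after false-peak rejection
#' (under `selection = "lowest"`, the deepest surviving minimum instead).
#' If no minimum survives, sowing falls back to
#' `sos_start - fallback_lag`, flagged.
#'
#' @param model fitted `harmonic_model` for the pixel.
#' @param sos_date first day (`Date`) of the grid's SOS dekad.
#' @param config an [estimator_config()].
#' @return one-row data.frame `sowing_date, sowing_doy, method, quality`.
#' @export
estimate_pixel_sowing <- function(model, sos_date, config = estimator_config()) {
  if (!inherits(model, "harmonic_model")) stop("model missing or not fitted")
  t_sos <- model_time(model, sos_date)
  t_lo <- t_sos - config$search_window
  minima <- find_candidate_minima(model, t_lo + as.numeric(model$reference_date),
                                  sos_date, step = config$evaluation_step)
  minima <- minima[minima$t < t_sos - 1e-9, , drop = FALSE]  # strictly before SOS
  if (nrow(minima) > 1L) {
    minima <- reject_false_peaks(minima, model, config$prominence_fraction,
                                 amplitude_window = c(t_lo, t_sos + 180))
  }
  if (nrow(minima) == 0L) {
    d <- as.Date(sos_date) - config$fallback_lag
    return(data.frame(sowing_date = d,
                      sowing_doy = as.POSIXlt(d)$yday + 1L,
                      method = "fallback", quality = "flagged"))
  }
  pick <- if (config$selection == "lowest") which.min(minima$ndvi) else nrow(minima)
  d <- as.Date(round(minima$t[pick]), origin = as.Date(model$reference_date))
  data.frame(sowing_date = d,
             sowing_doy = as.POSIXlt(d)$yday + 1L,
             method = "zero_gradient", quality = "ok")
}

#' Aggregate pixel sowing estimates to one grid estimate
#'
#' Lower median of the pixel sowing dates (so the grid value is an actually
#' estimated date); quality is flagged when more than half the pixels used
#' the fallback rule.
#'
#' @param pixel_estimates data.frame with columns `sowing_date`, `method`
#'   (rows = pixels of one grid-season).
#' @return one-row data.frame `sowing_date, sowing_doy, method, quality,
#'   n_pixels_used`.
#' @export
aggregate_grid_sowing <- function(pixel_estimates) {
  if (nrow(pixel_estimates) == 0L) stop("no pixel estimates to aggregate")
  d <- as.Date(lower_median(as.numeric(pixel_estimates$sowing_date)),
               origin = "1970-01-01")
  frac_fb <- mean(pixel_estimates$method == "fallback")
  data.frame(
    sowing_date = d,
    sowing_doy = as.POSIXlt(d)$yday + 1L,
    method = if (frac_fb > 0.5) "fallback" else "zero_gradient",
    quality = if (frac_fb > 0.5) "flagged" else "ok",
    n_pixels_used = nrow(pixel_estimates)
  )
}

#' Grid-level sowing dates from NDVI series and SOS phenology
#'
#' The full retrieval: for each grid-season in `grid_lsp`, fits a harmonic
#' model per member pixel on a one-year window centred on the grid's SOS,
#' applies the zero-gradient rule per pixel, and takes the grid median.
#' Pixels whose series cannot be fitted (too few clear observations) are
#' skipped; a grid with no fittable pixel falls back to
#' `SOS - fallback_lag`, flagged.
#'
#' @param ndvi data.frame `series_id, date, ndvi, qa` (`series_id` =
#'   pixel id).
#' @param grid_lsp data.frame from [extract_grid_lsp()] (needs `grid_id`,
#'   `season_year`, `sos`).
#' @param grid_map data.frame `pixel_id, grid_id`.
#' @param config an [estimator_config()].
#' @param n_harmonics,base_period harmonic model settings (default
#'   K = 5: the pre-season trough is a sharp feature, and resolving it
#'   needs harmonic periods comparable to its width; see the vignette).
#' @param fit_halfwidth half-width in days of the per-season fitting
#'   window around SOS (default 120 before, `fit_halfwidth + 5` after:
#'   concentrates the fit on the target season so neighbouring seasons
#'   with different rainfall onsets do not bias the trough location).
#' @return data.frame `grid_id, season_year, sowing_date, sowing_doy,
#'   method, quality, n_pixels_used`.
#' @export
estimate_sowing <- function(ndvi, grid_lsp, grid_map,
                            config = estimator_config(),
                            n_harmonics = 5, base_period = 365.25,
                            fit_halfwidth = 120) {
  ndvi$date <- as.Date(ndvi$date)
  px_by_grid <- split(grid_map$pixel_id, grid_map$grid_id)
  series <- split(ndvi[, c("date", "ndvi", "qa")], ndvi$series_id)
  out <- vector("list", nrow(grid_lsp))
  for (i in seq_len(nrow(grid_lsp))) {
    g <- grid_lsp[i, ]
    sos_date <- dekad_decode(g$sos, g$season_year)$first_day
    w0 <- sos_date - fit_halfwidth
    w1 <- sos_date + fit_halfwidth + 5
    ests <- list()
    for (p in px_by_grid[[as.character(g$grid_id)]]) {
      s <- series[[as.character(p)]]
      if (is.null(s)) next
      s <- s[s$date >= w0 & s$date <= w1, , drop = FALSE]
      m <- tryCatch(
        fit_harmonic(s$date, s$ndvi, qa = s$qa, n_harmonics = n_harmonics,
                     base_period = base_period),
        error = function(e) NULL)
      if (is.null(m)) next
      ests[[length(ests) + 1L]] <- estimate_pixel_sowing(m, sos_date, config)
    }
    if (length(ests) == 0L) {
      d <- sos_date - config$fallback_lag
      row <- data.frame(sowing_date = d, sowing_doy = as.POSIXlt(d)$yday + 1L,
                        method = "fallback", quality = "flagged",
                        n_pixels_used = 0L)
    } else {
      row <- aggregate_grid_sowing(do.call(rbind, ests))
    }
    row$grid_id <- g$grid_id
    row$season_year <- g$season_year
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  res[, c("grid_id", "season_year", "sowing_date", "sowing_doy",
          "method", "quality", "n_pixels_used")]
}
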