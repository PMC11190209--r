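#' Dekad arithmetic for the three-calendar-year phenology window
#'
#' WaPOR-convention seasonal phenology layers encode dates as *dekads*:
#' ten-day (or month-tail) calendar intervals, three per month, 36 per year.
#' A phenology layer for a target year spans exactly three calendar years,
#' i.e. 108 dekads, with the target year occupying indices 37--72 (dekad 37
#' is the first ten days of January of the target year, dekad 72 the last
#' eleven days of December). Indices 1--36 fall in the preceding year and
#' 73--108 in the following year.
#'
#' `dekad_decode()` maps an index to its calendar interval;
#' `dekad_encode()` is the inverse, mapping a date inside the window to the
#' unique index whose interval contains it.
#'
#' @param index integer vector of dekad indices in `[1, 108]`.
#' @param target_year integer; the calendar year in the middle of the
#'   three-year window.
#' @return `dekad_decode()`: a data.frame with columns `index`, `year`,
#'   `month`, `dekad_of_month` (1--3), `first_day`, `last_day` (`Date`).
#' @examples
#' dekad_decode(37, 2018)            # 2018-01-01 .. 2018-01-10
#' dekad_encode(as.Date("2019-02-28"), 2019)  # 42
#' @export
dekad_decode <- function(index, target_year) {
  if (length(index) == 0L) stop("empty dekad index")
  if (any(!is.finite(index)) || any(index != trunc(index)) ||
      any(index < 1L) || any(index > 108L)) {
    stop("dekad index must be an integer in [1, 108]")
  }
  index <- as.integer(index)
  year <- target_year - 1L + (index - 1L) %/% 36L
  d0 <- (index - 1L) %% 36L            # dekad-of-year, 0-based
  month <- d0 %/% 3L + 1L
  dom <- d0 %% 3L + 1L                 # dekad-of-month
  first <- as.Date(sprintf("%04d-%02d-%02d", year, month, c(1L, 11L, 21L)[dom]))
  # last day: days 10 / 20 / month end
  month_end <- as.Date(sprintf(
    "%04d-%02d-01",
    ifelse(month == 12L, year + 1L, year),
    ifelse(month == 12L, 1L, month + 1L)
  )) - 1L
  last <- as.Date(ifelse(dom == 3L, month_end, first + 9L),
                  origin = "1970-01-01")
  data.frame(index = index, year = year, month = month,
             dekad_of_month = dom, first_day = first, last_day = last)
}

#' @param date a `Date` vector within the three-year window
#'   `[Jan 1 of target_year - 1, Dec 31 of target_year + 1]`.
#' @rdname dekad_decode
#' @export
dekad_encode <- function(date, target_year) {
  date <- as.Date(date)
  if (any(is.na(date))) stop("invalid date")
  lt <- as.POSIXlt(date)
  year <- lt$year + 1900L
  offset <- year - (target_year - 1L)
  if (any(offset < 0L | offset > 2L)) {
    stop("date outside the three-year window of target year ", target_year)
  }
  month <- lt$mon + 1L
  day <- lt$mday
  dom <- 1L + (day >= 11L) + (day >= 21L)
  as.integer(offset * 36L + (month - 1L) * 3L + dom)
}

#' Midpoint day-of-year of a dekad
#'
#' Floor of the mean of the first and last day-of-year of the decoded
#' interval, computed against the interval's own calendar year (so leap
#' years are honoured). Used to compare dekad-scale phenology attributes
#' (e.g. maximum-season dekads) with daily simulated dates.
#'
#' @inheritParams dekad_decode
#' @return integer day-of-year vector.
#' @export
dekad_midpoint_doy <- function(index, target_year) {
  dec <- dekad_decode(index, target_year)
  doy1 <- as.POSIXlt(dec$first_day)$yday + 1L
  doy2 <- as.POSIXlt(dec$last_day)$yday + 1L
  as.integer(floor((doy1 + doy2) / 2))
}

# Lower median: the lower of the two central order statistics on even
# counts, so the result is always an observed value (a valid dekad).
lower_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sort(x)[floor((length(x) + 1) / 2)]
}

#' Grid-level phenology from pixel dekads
#'
#' Aggregates pixel-level SOS/MS/EOS dekad indices to one record per grid
#' and season: the per-attribute median across the grid's valid pixels
#' (lower median on even counts, so the aggregate stays a valid dekad).
#' A pixel contributes only if all three attributes are present. Records
#' whose median triple violates the seasonal ordering sos < ms < eos are
#' kept but flagged invalid.
#'
#' @param pixel_phenology data.frame with columns `pixel_id`, `season_year`,
#'   `sos`, `ms`, `eos` (dekad indices; `NA` = missing retrieval).
#' @param grid_map data.frame with columns `pixel_id`, `grid_id`,
#'   `region_id` mapping every pixel to exactly one grid and region.
#' @return data.frame `grid_id, region_id, season_year, sos, ms, eos,
#'   n_pixels, valid`, one row per grid-season with at least one valid
#'   pixel.
#' @export
extract_grid_lsp <- function(pixel_phenology, grid_map) {
  need <- c("pixel_id", "season_year", "sos", "ms", "eos")
  if (!all(need %in% names(pixel_phenology))) {
    stop("pixel_phenology must have columns ", paste(need, collapse = ", "))
  }
  px <- merge(pixel_phenology, grid_map[, c("pixel_id", "grid_id", "region_id")],
              by = "pixel_id")
  px <- px[stats::complete.cases(px[, c("sos", "ms", "eos")]), , drop = FALSE]
  if (nrow(px) == 0L) stop("no valid pixels in any grid")
  key <- interaction(px$grid_id, px$season_year, drop = TRUE)
  rows <- lapply(split(px, key), function(g) {
    data.frame(
      grid_id = g$grid_id[1L],
      region_id = g$region_id[1L],
      season_year = g$season_year[1L],
      sos = lower_median(g$sos),
      ms = lower_median(g$ms),
      eos = lower_median(g$eos),
      n_pixels = nrow(g)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$valid <- out$sos < out$ms & out$ms < out$eos
  out[order(out$grid_id, out$season_year), , drop = FALSE]
}
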