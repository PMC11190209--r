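#' Fit a harmonic model to an NDVI time series
#'
#' Models an NDVI series as the sum of additive terms (intercept and linear
#' trend) and `K` harmonic terms on a base period `P`:
#' \deqn{ndvi(t) = c_0 + c_1 t + \sum_{k=1}^{K} a_k \cos(2\pi k t / P)
#'   + b_k \sin(2\pi k t / P)}
#' with `t` in fractional days from `reference_date`. Fitting is ordinary
#' least squares; harmonic smoothing bridges the noise and gaps typical of
#' optical satellite index series. Observations flagged `"bad"` (e.g.
#' atmospheric artefacts) are dropped before fitting.
#'
#' @param dates `Date` (or numeric day) vector of observation times.
#' @param ndvi numeric vector of NDVI values in `[-1, 1]`.
#' @param qa optional character vector, `"good"`/`"bad"`; bad observations
#'   are excluded from the fit.
#' @param n_harmonics number of harmonic pairs `K` (default 3: captures a
#'   bimodal seasonal cycle without overfitting at a ten-day-to-biweekly
#'   revisit density).
#' @param base_period base period `P` in days (default 365.25).
#' @param reference_date origin of the time axis; defaults to the first
#'   retained observation date.
#' @param robust if `TRUE`, one pass of residual screening: observations
#'   with |residual| > 3 MAD are dropped and the model refitted once.
#' @return an object of class `harmonic_model`: list with `intercept`,
#'   `trend`, `a`, `b` (length-`K` cosine/sine coefficients),
#'   `base_period`, `reference_date`, `rss`, `n_obs`.
#' @export
fit_harmonic <- function(dates, ndvi, qa = NULL, n_harmonics = 3,
                         base_period = 365.25, reference_date = NULL,
                         robust = FALSE) {
  stopifnot(n_harmonics >= 1, base_period > 0, length(dates) == length(ndvi))
  keep <- is.finite(ndvi)
  if (!is.null(qa)) keep <- keep & (qa != "bad")
  dates <- dates[keep]
  ndvi <- ndvi[keep]
  if (length(ndvi) < 2 * n_harmonics + 3) {
    stop("insufficient data: need at least ", 2 * n_harmonics + 3,
         " valid observations, got ", length(ndvi))
  }
  if (is.null(reference_date)) reference_date <- dates[1L]
  t <- as.numeric(dates) - as.numeric(reference_date)
  X <- harmonic_design(t, n_harmonics, base_period)
  fit <- stats::lm.fit(X, ndvi)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient design: observation dates do not identify the model")
  }
  if (robust) {
    r <- fit$residuals
    s <- stats::mad(r)
    if (s > 0) {
      keep2 <- abs(r) <= 3 * s
      if (sum(keep2) >= 2 * n_harmonics + 3 && any(!keep2)) {
        fit <- stats::lm.fit(X[keep2, , drop = FALSE], ndvi[keep2])
        if (fit$rank < ncol(X)) stop("rank-deficient design after screening")
        t <- t[keep2]
        ndvi <- ndvi[keep2]
      }
    }
  }
  cf <- fit$coefficients
  k <- seq_len(n_harmonics)
  structure(list(
    intercept = unname(cf[1L]),
    trend = unname(cf[2L]),
    a = unname(cf[2L + 2L * (k - 1L) + 1L]),
    b = unname(cf[2L + 2L * (k - 1L) + 2L]),
    n_harmonics = n_harmonics,
    base_period = base_period,
    reference_date = reference_date,
    rss = sum(fit$residuals^2),
    n_obs = length(ndvi)
  ), class = "harmonic_model")
}

# Design matrix: [1, t, cos(w t), sin(w t), cos(2 w t), sin(2 w t), ...]
harmonic_design <- function(t, n_harmonics, base_period) {
  cols <- list(rep(1, length(t)), t)
  for (k in seq_len(n_harmonics)) {
    w <- 2 * pi * k / base_period
    cols[[length(cols) + 1L]] <- cos(w * t)
    cols[[length(cols) + 1L]] <- sin(w * t)
  }
  do.call(cbind, cols)
}

# days since model reference for Date / numeric input
model_time <- function(model, dates) {
  as.numeric(dates) - as.numeric(model$reference_date)
}

# evaluation on the model-time axis (days since reference_date)
harmonic_value_t <- function(model, t) {
  out <- model$intercept + model$trend * t
  for (k in seq_len(model$n_harmonics)) {
    w <- 2 * pi * k / model$base_period
    out <- out + model$a[k] * cos(w * t) + model$b[k] * sin(w * t)
  }
  out
}

harmonic_slope_t <- function(model, t) {
  out <- rep(model$trend, length(t))
  for (k in seq_len(model$n_harmonics)) {
    w <- 2 * pi * k / model$base_period
    out <- out + w * (-model$a[k] * sin(w * t) + model$b[k] * cos(w * t))
  }
  out
}

#' Evaluate a fitted harmonic model
#'
#' @param object a `harmonic_model`.
#' @param dates `Date` (or numeric date, days since 1970-01-01) vector at
#'   which to evaluate.
#' @param ... unused.
#' @return numeric vector of fitted NDVI values.
#' @export
predict.harmonic_model <- function(object, dates, ...) {
  harmonic_value_t(object, model_time(object, dates))
}

#' Analytic time derivative of a harmonic model
#'
#' Slope of the fitted curve in NDVI units per day:
#' \eqn{c_1 + \sum_k (2\pi k/P)(-a_k \sin + b_k \cos)}. Drives the
#' zero-gradient search for pre-season NDVI minima.
#'
#' @inheritParams predict.harmonic_model
#' @param model a `harmonic_model`.
#' @return numeric vector of slopes (NDVI per day).
#' @export
harmonic_derivative <- function(model, dates) {
  harmonic_slope_t(model, model_time(model, dates))
}

#' Amplitude and phase of one harmonic
#'
#' The k-th cosine/sine pair expressed in polar form:
#' `amplitude = sqrt(a_k^2 + b_k^2)`, `phase = atan2(b_k, a_k)` in
#' `(-pi, pi]`, so that `a cos(wt) + b sin(wt) = A cos(wt - phase)`.
#'
#' @param model a `harmonic_model`.
#' @param k harmonic order, `1 <= k <= K`.
#' @return named numeric vector `c(amplitude=, phase=)`.
#' @export
amplitude_phase <- function(model, k) {
  if (k < 1 || k > model$n_harmonics) {
    stop("harmonic order k out of range [1, ", model$n_harmonics, "]")
  }
  a <- model$a[k]
  b <- model$b[k]
  ph <- atan2(b, a)
  if (ph <= -pi) ph <- pi   # convention: phase in (-pi, pi]
  c(amplitude = sqrt(a^2 + b^2), phase = ph)
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat("Harmonic NDVI model: K =", x$n_harmonics,
      " P =", x$base_period, "d\n")
  cat("  intercept", format(x$intercept, digits = 4),
      " trend/day", format(x$trend, digits = 4), "\n")
  for (k in seq_len(x$n_harmonics)) {
    ap <- amplitude_phase(x, k)
    cat(sprintf("  k=%d  amplitude %.4f  phase %+.3f rad\n",
                k, ap["amplitude"], ap["phase"]))
  }
  cat("  n =", x$n_obs, " rss =", format(x$rss, digits = 4), "\n")
  invisible(x)
}
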