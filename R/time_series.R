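#' Breakpointed time series
#'
#' A minimal container for piecewise-linear time series used for all
#' time-varying object parameters (areas, masses, water fluxes, ...).
#' Breakpoints are years CE (negative = BC); values are interpolated
#' linearly between breakpoints and held constant beyond the ends.
#'
#' @param t numeric vector of strictly increasing breakpoints (years CE).
#' @param y numeric vector of values, same length as `t`.
#' @return An object of class `ts_series`.
#' @export
ts_series <- function(t, y) {
  if (length(t) == 0L) stop("empty time series", call. = FALSE)
  if (length(t) != length(y)) stop("breakpoints and values differ in length", call. = FALSE)
  if (anyNA(t) || anyNA(y)) stop("time series contains NA", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) stop("breakpoints must be strictly increasing", call. = FALSE)
  structure(list(t = as.numeric(t), y = as.numeric(y)), class = "ts_series")
}

#' Constant time series
#' @param value single numeric value.
#' @return A `ts_series` with one breakpoint.
#' @export
ts_constant <- function(value) ts_series(0, value)

is_ts <- function(x) inherits(x, "ts_series")

as_ts <- function(x) {
  if (is_ts(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(ts_constant(x))
  stop("cannot coerce to ts_series", call. = FALSE)
}

#' Interpolate a time series
#'
#' Linear interpolation between breakpoints, constant extrapolation
#' beyond the first and last breakpoint.
#'
#' @param series a `ts_series` (or single numeric, treated as constant).
#' @param t numeric vector of query times (years CE).
#' @return numeric vector of interpolated values.
#' @export
interp_series <- function(series, t) {
  series <- as_ts(series)
  st <- series$t; sy <- series$y
  n <- length(st)
  if (n == 1L) return(rep.int(sy, length(t)))
  tt <- pmin(pmax(t, st[1L]), st[n])   # constant extrapolation
  i <- findInterval(tt, st, all.inside = TRUE)
  sy[i] + (sy[i + 1L] - sy[i]) * (tt - st[i]) / (st[i + 1L] - st[i])
}

#' Time derivative of a piecewise-linear series
#'
#' Central difference over a small window; used e.g. for the wetland-growth
#' rate which depends on the shrinkage rate of the aquatic area.
#'
#' @param series a `ts_series`.
#' @param t query time.
#' @param h half-width of the difference window (years).
#' @return numeric derivative dy/dt at `t`.
#' @keywords internal
deriv_series <- function(series, t, h = 0.5) {
  (interp_series(series, t + h) - interp_series(series, t - h)) / (2 * h)
}

#' @export
print.ts_series <- function(x, ...) {
  cat(sprintf("<ts_series> %d breakpoint(s), t in [%g, %g], y in [%g, %g]\n",
              length(x$t), min(x$t), max(x$t), min(x$y), max(x$y)))
  invisible(x)
}

# breakpoints of a series (empty for constants)
ts_breaks <- function(series) {
  series <- as_ts(series)
  if (length(series$t) == 1L) numeric(0) else series$t
}
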