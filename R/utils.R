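# Shared internal helpers.

# Devices a census subsample can come from.
CENSUS_DEVICES <- c("net", "cpr", "pump", "trap")

# Meteorological seasons, hemisphere-aware (see assign_season()).
SEASONS <- c("winter", "spring", "summer", "autumn")

# Mean length of one degree of latitude, km.
KM_PER_DEG_LAT <- 111.32

foram_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "foramshift_error"))
}

#' Convert calendar dates to a decimal-year time coordinate
#'
#' Gridded fields carry a numeric time axis in decimal years at month centres,
#' `year + (month - 0.5) / 12`; sampling dates are mapped onto the same scale
#' so that time interpolation is linear between month centres.
#'
#' @param date a `Date` vector (or something coercible via [as.Date()]).
#' @return numeric vector of decimal years.
#' @export
date_to_decimal_year <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  yr + (mo - 0.5) / 12
}

# Decimal-year coordinate of the centre of month `month` of year `year`.
month_centre <- function(year, month) year + (month - 0.5) / 12

# Calendar decade label (half-open [1940, 1950) etc.).
decade_of <- function(year) 10 * floor(year / 10)

# Min-max normalization to [0, 1]; constant input -> all NA (degenerate).
min_max <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    return(rep(NA_real_, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Year extracted from a Date vector.
year_of <- function(date) as.integer(format(as.Date(date), "%Y"))

month_of <- function(date) as.integer(format(as.Date(date), "%m"))
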