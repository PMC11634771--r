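# Gridded 4-D environmental fields (lat, lon, depth, time) with multilinear
# point interpolation, calcite saturation state, and attachment of
# environmental conditions to census records.

#' Construct a gridded 4-D environmental field
#'
#' @param variable one of `"temperature_degC"`, `"co3"`, `"co3satcalc"`,
#'   `"omega_calcite"`.
#' @param lat,lon,depth,time strictly monotone increasing numeric axes
#'   (degrees, degrees, metres, decimal years at month centres — see
#'   [date_to_decimal_year()]).
#' @param values numeric array with dim `c(length(lat), length(lon),
#'   length(depth), length(time))`; `NA` marks masked (e.g. land) cells.
#' @return object of class `gridded_field`.
#' @export
gridded_field <- function(variable, lat, lon, depth, time, values) {
  for (ax in list(lat, lon, depth, time)) {
    if (length(ax) > 1 && any(diff(ax) <= 0)) {
      foram_abort("field axes must be strictly monotone increasing",
                  "foramshift_field_error")
    }
  }
  dims <- c(length(lat), length(lon), length(depth), length(time))
  values <- array(values, dim = dims)
  structure(list(variable = variable, lat = lat, lon = lon, depth = depth,
                 time = time, values = values),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat("Gridded field <", x$variable, ">: ",
      length(x$lat), " lat x ", length(x$lon), " lon x ",
      length(x$depth), " depth x ", length(x$time), " time; ",
      sum(is.na(x$values)), " masked cells\n", sep = "")
  invisible(x)
}

#' Build a gridded field by evaluating a function on the grid
#'
#' @param f `function(lat, lon, depth, time)` accepting equal-length vectors.
#' @param variable,lat,lon,depth,time as in [gridded_field()].
#' @return a `gridded_field`.
#' @export
field_from_function <- function(f, variable, lat, lon, depth, time) {
  g <- expand.grid(lat = lat, lon = lon, depth = depth, time = time,
                   KEEP.OUT.ATTRS = FALSE)
  gridded_field(variable, lat, lon, depth, time,
                f(g$lat, g$lon, g$depth, g$time))
}

#' Read / write a gridded field as long-format CSV
#'
#' Plain-text field exchange format: columns `lat`, `lon`, `depth`, `time`,
#' `value` (missing cells may be omitted or empty).  The grid is the Cartesian
#' product of the unique axis values.
#'
#' @param path CSV path.
#' @param variable variable name stored on the result.
#' @return a `gridded_field`.
#' @export
read_field_csv <- function(path, variable = "temperature_degC") {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  depth <- sort(unique(d$depth)); time <- sort(unique(d$time))
  vals <- array(NA_real_, c(length(lat), length(lon), length(depth), length(time)))
  idx <- cbind(match(d$lat, lat), match(d$lon, lon),
               match(d$depth, depth), match(d$time, time))
  vals[idx] <- d$value
  gridded_field(variable, lat, lon, depth, time, vals)
}

#' @rdname read_field_csv
#' @param field a `gridded_field`.
#' @export
write_field_csv <- function(field, path) {
  g <- expand.grid(lat = field$lat, lon = field$lon, depth = field$depth,
                   time = field$time, KEEP.OUT.ATTRS = FALSE)
  g$value <- as.vector(field$values)
  readr::write_csv(g[!is.na(g$value), ], path)
  invisible(path)
}

#' Calcite saturation state from carbonate-ion concentrations
#'
#' `Omega_calcite = co3 / co3satcalc`: the in-situ carbonate-ion concentration
#' divided by its saturation concentration with respect to calcite.  Below 1,
#' calcite dissolution is thermodynamically favoured.
#'
#' @param co3 in-situ carbonate-ion concentration (any concentration unit).
#' @param co3satcalc saturation carbonate-ion concentration, same unit, > 0.
#' @return dimensionless saturation state.
#' @export
omega_from_carbonate <- function(co3, co3satcalc) {
  bad <- !is.na(co3satcalc) & co3satcalc <= 0
  if (any(bad)) {
    foram_abort("co3satcalc must be > 0", "foramshift_domain_error")
  }
  co3 / co3satcalc
}

# Per-axis interpolation stencil: bracketing indices (i0, i1) and weight of
# the upper neighbour, clamping outside the axis span.  A longitude axis
# covering the full circle wraps across the dateline instead of clamping.
axis_stencil <- function(axis, x, circular = FALSE, period = 360) {
  n <- length(axis)
  if (n == 1) {
    return(list(i0 = rep(1L, length(x)), i1 = rep(1L, length(x)),
                w = rep(0, length(x))))
  }
  gap <- period - (axis[n] - axis[1])
  wraps <- circular && gap <= 1.5 * stats::median(diff(axis))
  if (wraps) {
    outside <- x < axis[1] | x > axis[n]
    x_in <- pmin(pmax(x, axis[1]), axis[n])
    i0 <- pmin(pmax(findInterval(x_in, axis), 1L), n - 1L)
    i1 <- i0 + 1L
    w <- (x_in - axis[i0]) / (axis[i1] - axis[i0])
    # seam segment: between the last and (first + period) node
    i0[outside] <- n
    i1[outside] <- 1L
    w[outside] <- ((x[outside] - axis[n]) %% period) / gap
    return(list(i0 = i0, i1 = i1, w = w))
  }
  x <- pmin(pmax(x, axis[1]), axis[n])
  i0 <- pmin(pmax(findInterval(x, axis), 1L), n - 1L)
  list(i0 = i0, i1 = i0 + 1L, w = (x - axis[i0]) / (axis[i0 + 1L] - axis[i0]))
}

#' Interpolate a gridded field to sample points
#'
#' Multilinear interpolation across the four axes.  Points outside an axis
#' span are clamped to its ends (dates before the first or after the last
#' month centre, sampling depths above the shallowest model level).  Masked
#' (`NA`) corner cells are excluded by renormalizing the interpolation weights
#' over the unmasked corners; a fully masked neighbourhood yields `NA`.
#' Longitudes are wrapped into `[-180, 180)` before lookup.
#'
#' @param field a `gridded_field`.
#' @param latitude,longitude,depth numeric vectors (equal length).
#' @param date `Date` vector, or numeric decimal years.
#' @return numeric vector of interpolated values.
#' @export
sample_field <- function(field, latitude, longitude, depth, date) {
  t <- if (inherits(date, "Date") || is.character(date)) {
    date_to_decimal_year(date)
  } else {
    as.numeric(date)
  }
  lon <- ((longitude + 180) %% 360) - 180
  s_lat <- axis_stencil(field$lat, latitude)
  s_lon <- axis_stencil(field$lon, lon, circular = TRUE)
  s_dep <- axis_stencil(field$depth, depth)
  s_tim <- axis_stencil(field$time, t)

  dims <- dim(field$values)
  npt <- length(latitude)
  num <- numeric(npt)
  den <- numeric(npt)
  pick <- function(s, hi) if (hi) s$i1 else s$i0
  for (a in 0:1) {
    for (b in 0:1) {
      for (cc in 0:1) {
        for (d in 0:1) {
          w <- (if (a == 1) s_lat$w else 1 - s_lat$w) *
               (if (b == 1) s_lon$w else 1 - s_lon$w) *
               (if (cc == 1) s_dep$w else 1 - s_dep$w) *
               (if (d == 1) s_tim$w else 1 - s_tim$w)
          i <- pick(s_lat, a == 1)
          j <- pick(s_lon, b == 1)
          k <- pick(s_dep, cc == 1)
          l <- pick(s_tim, d == 1)
          lin <- ((l - 1) * dims[3] * dims[2] * dims[1]) +
                 ((k - 1) * dims[2] * dims[1]) + ((j - 1) * dims[1]) + i
          v <- field$values[lin]
          ok <- !is.na(v) & w > 0
          num[ok] <- num[ok] + w[ok] * v[ok]
          den[ok] <- den[ok] + w[ok]
        }
      }
    }
  }
  # den = 0 means every corner carrying weight is masked: missing
  ifelse(den > 0, num / den, NA_real_)
}

#' Attach environmental conditions to census records
#'
#' Each record is sampled at its location, date and the midpoint of its depth
#' interval (the averaged sampled depth used for multinet, CPR and pump
#' catches).  Adds `temperature` and, when carbonate fields are supplied,
#' `omega_calcite`; records with no field coverage get `NA` and
#' `env_missing = TRUE`.
#'
#' @param records long census tibble.
#' @param fields named list of `gridded_field`s: `temperature`, and either
#'   `omega_calcite` or both `co3` and `co3satcalc`.
#' @return records with environmental columns added.
#' @export
attach_environment <- function(records, fields) {
  pts <- records |>
    dplyr::distinct(.data$latitude, .data$longitude, .data$depth_upper,
                    .data$depth_lower, .data$date) |>
    dplyr::mutate(.depth_mid = (.data$depth_upper + .data$depth_lower) / 2)

  pts$temperature <- sample_field(fields$temperature, pts$latitude,
                                  pts$longitude, pts$.depth_mid, pts$date)
  if (!is.null(fields$omega_calcite)) {
    pts$omega_calcite <- sample_field(fields$omega_calcite, pts$latitude,
                                      pts$longitude, pts$.depth_mid, pts$date)
  } else if (!is.null(fields$co3) && !is.null(fields$co3satcalc)) {
    co3 <- sample_field(fields$co3, pts$latitude, pts$longitude,
                        pts$.depth_mid, pts$date)
    sat <- sample_field(fields$co3satcalc, pts$latitude, pts$longitude,
                        pts$.depth_mid, pts$date)
    pts$omega_calcite <- omega_from_carbonate(co3, sat)
  }
  pts$env_missing <- is.na(pts$temperature)
  if (any(pts$env_missing)) {
    rlang::inform(paste0(sum(pts$env_missing),
                         " sampling point(s) without field coverage flagged"))
  }
  dplyr::left_join(records, dplyr::select(pts, -".depth_mid"),
                   by = c("latitude", "longitude", "depth_upper",
                          "depth_lower", "date"))
}
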