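# 2-D (temperature, Omega_calcite) niche envelopes and the emergence of
# projected future conditions from the currently occupied envelope.

#' Build a niche envelope from occupancy points
#'
#' The envelope is the convex hull of the (temperature, Omega_calcite) points
#' after independently trimming each axis to the stated marginal quantiles
#' (default 1%/99%), a simple, reproducible stand-in for the occupied
#' "balloon" of conditions.  Kernel-density contouring is deliberately not the
#' default; the hull is conservative and has unambiguous membership.
#'
#' @param points tibble with `temperature` and `omega_calcite` columns (rows
#'   with `NA` in either are dropped).
#' @param trim quantile pair `c(lo, hi)`; `c(0, 1)` disables trimming.
#' @return object of class `niche_envelope`: list with `polygon` (tibble of
#'   hull vertices, closed implicitly), `n_input`, `n_retained`, `trim`.
#' @export
build_niche <- function(points, trim = c(0.01, 0.99)) {
  pts <- points[!is.na(points$temperature) & !is.na(points$omega_calcite), ,
                drop = FALSE]
  if (nrow(pts) < 10) {
    foram_abort("build_niche() needs at least 10 points",
                "foramshift_insufficient_data")
  }
  qt <- quantile(pts$temperature, trim, type = 7)
  qo <- quantile(pts$omega_calcite, trim, type = 7)
  keep <- pts$temperature >= qt[1] & pts$temperature <= qt[2] &
    pts$omega_calcite >= qo[1] & pts$omega_calcite <= qo[2]
  kept <- pts[keep, , drop = FALSE]
  hull <- chull(kept$temperature, kept$omega_calcite)
  structure(
    list(polygon = tibble(temperature = kept$temperature[hull],
                          omega_calcite = kept$omega_calcite[hull]),
         n_input = nrow(pts), n_retained = nrow(kept), trim = trim),
    class = "niche_envelope"
  )
}

#' @export
print.niche_envelope <- function(x, ...) {
  cat("Niche envelope: ", nrow(x$polygon), " hull vertices from ",
      x$n_retained, "/", x$n_input, " points (trim ",
      x$trim[1], "-", x$trim[2], ")\n", sep = "")
  invisible(x)
}

# Even-odd ray-casting point-in-polygon with an explicit on-boundary test;
# points on an edge or vertex count as inside.  Vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  eps <- 1e-12 * max(1, abs(vx), abs(vy))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment: collinear and inside the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) <= eps * max(1, abs(x2 - x1), abs(y2 - y1)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on_seg
    # ray casting: horizontal ray towards +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | boundary
}

#' Membership of points in a niche envelope
#'
#' @param envelope a [build_niche()] result.
#' @param points tibble with `temperature`, `omega_calcite`.
#' @return logical vector; boundary points count as inside.
#' @export
in_envelope <- function(envelope, points) {
  ok <- !is.na(points$temperature) & !is.na(points$omega_calcite)
  out <- rep(FALSE, nrow(points))
  out[ok] <- points_in_polygon(points$temperature[ok],
                               points$omega_calcite[ok],
                               envelope$polygon$temperature,
                               envelope$polygon$omega_calcite)
  out
}

#' Fraction of points emerging from a niche envelope
#'
#' The fraction of (future) condition points strictly outside the envelope
#' polygon; boundary points count as inside.  Points with missing conditions
#' are dropped first.
#'
#' @inheritParams in_envelope
#' @return fraction in `[0, 1]`.
#' @export
emergence_fraction <- function(points, envelope) {
  pts <- points[!is.na(points$temperature) & !is.na(points$omega_calcite), ,
                drop = FALSE]
  if (nrow(pts) == 0) {
    foram_abort("emergence_fraction(): no usable points",
                "foramshift_insufficient_data")
  }
  mean(!in_envelope(envelope, pts))
}

#' Project the conditions at historical sampling locations to a future year
#'
#' Re-evaluates every record's (latitude, longitude, depth midpoint,
#' month-of-year) in the scenario fields at `horizon_year` — the sampling
#' month is preserved so seasonality is retained, only the calendar year is
#' replaced.  Records without scenario coverage are dropped and counted.
#'
#' @param records census tibble (the historical sampling locations).
#' @param fields named list of scenario `gridded_field`s: `temperature` and
#'   `omega_calcite` (or `co3` + `co3satcalc`).
#' @param horizon_year e.g. 2050 or 2100; must be covered by the scenario
#'   fields' time axis (after month-centre clamping no more than half a year
#'   beyond either end).
#' @return tibble `temperature`, `omega_calcite` plus the records' identity
#'   columns; attribute `"n_dropped"`.
#' @export
project_conditions <- function(records, fields, horizon_year) {
  tspan <- range(fields$temperature$time)
  if (horizon_year + 1 < tspan[1] || horizon_year > tspan[2] + 1) {
    foram_abort("horizon_year outside the scenario fields' time span",
                "foramshift_parameter_error")
  }
  pts <- records |>
    dplyr::distinct(.data$latitude, .data$longitude, .data$depth_upper,
                    .data$depth_lower, .data$date)
  pts$.t <- month_centre(horizon_year, month_of(pts$date))
  depth_mid <- (pts$depth_upper + pts$depth_lower) / 2
  pts$temperature <- sample_field(fields$temperature, pts$latitude,
                                  pts$longitude, depth_mid, pts$.t)
  if (!is.null(fields$omega_calcite)) {
    pts$omega_calcite <- sample_field(fields$omega_calcite, pts$latitude,
                                      pts$longitude, depth_mid, pts$.t)
  } else {
    co3 <- sample_field(fields$co3, pts$latitude, pts$longitude, depth_mid,
                        pts$.t)
    sat <- sample_field(fields$co3satcalc, pts$latitude, pts$longitude,
                        depth_mid, pts$.t)
    pts$omega_calcite <- omega_from_carbonate(co3, sat)
  }
  dropped <- sum(is.na(pts$temperature) | is.na(pts$omega_calcite))
  out <- pts[!is.na(pts$temperature) & !is.na(pts$omega_calcite), , drop = FALSE]
  out$horizon <- horizon_year
  out <- dplyr::select(out, -".t")
  attr(out, "n_dropped") <- dropped
  out
}

#' Niche emergence summary per latitudinal band and horizon
#'
#' For each band: the current all-records envelope (from the historical
#' fields), per-marker-species current point clouds, and the emergence
#' fraction of the band's projected conditions at each horizon.  Also reports
#' whether emergence is ordered tropical >= mid >= high at each horizon — a
#' qualitative diagnostic, not an assertion.
#'
#' @param records census tibble (long).
#' @param fields_current,fields_scenario named lists of `gridded_field`s as in
#'   [attach_environment()] / [project_conditions()].
#' @param bands named list of latitude bands, default tropical 0-30, mid
#'   30-50, high 50-90 degrees N.
#' @param horizons future years, default `c(2050, 2100)`.
#' @param marker_species optional character vector; their current point
#'   clouds are returned per band.
#' @param trim passed to [build_niche()].
#' @return list: `summary` (tibble band x horizon with `emergence`, `n`),
#'   `envelopes` (named list), `marker_points` (named list of tibbles),
#'   `ordering_ok` (logical per horizon).
#' @export
band_summary <- function(records, fields_current, fields_scenario,
                         bands = list(tropical = c(0, 30), mid = c(30, 50),
                                      high = c(50, 90)),
                         horizons = c(2050, 2100), marker_species = NULL,
                         trim = c(0.01, 0.99)) {
  cur <- attach_environment(records, fields_current)
  rows <- list()
  envelopes <- list()
  marker_points <- list()
  for (bn in names(bands)) {
    b <- bands[[bn]]
    in_band <- cur$latitude >= b[1] &
      (if (b[2] >= 90) cur$latitude <= 90 else cur$latitude < b[2])
    cb <- cur[in_band, , drop = FALSE]
    env <- build_niche(
      dplyr::distinct(cb, .data$subsample_id, .keep_all = TRUE), trim = trim
    )
    envelopes[[bn]] <- env
    if (!is.null(marker_species)) {
      conc <- if ("concentration" %in% names(cb)) cb$concentration else cb$value
      marker_points[[bn]] <- cb[cb$species %in% marker_species &
                                  !is.na(conc) & conc > 0,
                                c("species", "temperature", "omega_calcite")]
    }
    for (h in horizons) {
      proj <- project_conditions(cb, fields_scenario, h)
      rows[[length(rows) + 1]] <- tibble(
        band = bn, horizon = h,
        emergence = emergence_fraction(proj, env), n = nrow(proj)
      )
    }
  }
  summary <- dplyr::bind_rows(rows)
  ordering_ok <- vapply(horizons, function(h) {
    e <- summary$emergence[summary$horizon == h]
    all(diff(e) <= 1e-12)
  }, logical(1))
  names(ordering_ok) <- horizons
  list(summary = summary, envelopes = envelopes,
       marker_points = marker_points, ordering_ok = ordering_ok)
}
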