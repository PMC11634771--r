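# Species richness, gridded richness maps, the latitudinal diversity gradient
# (per-bin 95th percentile + smoother), and modern-vs-pre-industrial richness
# differences on a shared grid.

#' Global grid specification
#'
#' Cells are half-open `[lo, lo + cell)` in both axes, anchored at
#' (-90, -180), so a point exactly on a boundary belongs to the higher cell.
#'
#' @param cell_lat,cell_lon cell sizes in degrees, > 0.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(cell_lat = 3, cell_lon = 6) {
  if (cell_lat <= 0 || cell_lon <= 0) {
    foram_abort("grid cell sizes must be > 0", "foramshift_grid_error")
  }
  structure(list(cell_lat = cell_lat, cell_lon = cell_lon, origin = c(-90, -180)),
            class = "grid_spec")
}

# Lower bounds of the cell containing each point.
grid_cell <- function(latitude, longitude, grid) {
  tibble(
    cell_lat_lo = grid$origin[1] +
      grid$cell_lat * floor((latitude - grid$origin[1]) / grid$cell_lat),
    cell_lon_lo = grid$origin[2] +
      grid$cell_lon * floor((longitude - grid$origin[2]) / grid$cell_lon)
  )
}

#' Species richness per sampling unit
#'
#' Richness of a unit (a sample, a profile, or a sediment site) is the number
#' of taxa from the analysis set present (value > 0) anywhere in the unit.
#' Species outside the analysis set are ignored; an all-zero unit has
#' richness 0.
#'
#' @param records long tibble with `species` and either `value`
#'   (counts/concentrations) or `present` (0/1), plus `latitude`, `longitude`
#'   and optionally `year`.
#' @param taxa character vector restricting the analysis set (e.g. the shared
#'   modern/pre-industrial species list); `NULL` uses all species present.
#' @param unit_col column identifying the unit (`"sample_id"`,
#'   `"profile_id"`, `"site_id"`, ...).
#' @return tibble `unit_id`, `latitude`, `longitude`, `year`, `richness`.
#' @export
richness_table <- function(records, taxa = NULL, unit_col = "sample_id") {
  if (!(unit_col %in% names(records))) {
    foram_abort(paste0("richness_table(): no column '", unit_col, "'"),
                "foramshift_schema_error")
  }
  val <- if ("present" %in% names(records)) records$present else records$value
  d <- records
  d$.present <- !is.na(val) & val > 0
  if (!is.null(taxa)) d <- d[d$species %in% taxa, , drop = FALSE]
  d$unit_id <- d[[unit_col]]
  has_year <- "year" %in% names(d)
  d |>
    dplyr::summarise(
      latitude = mean(.data$latitude),
      longitude = mean(.data$longitude),
      year = if (has_year) as.integer(round(mean(.data$year))) else NA_integer_,
      richness = dplyr::n_distinct(.data$species[.data$.present]),
      .by = "unit_id"
    )
}

#' Reduce unit richness onto a grid
#'
#' @param richness tibble from [richness_table()].
#' @param grid a [grid_spec()].
#' @param reducer `"max"` (default; invariant to record duplication) or
#'   `"mean"`.
#' @return tibble `cell_lat_lo`, `cell_lon_lo`, `richness`, `n_units`; cells
#'   without data are absent.
#' @export
gridded_richness <- function(richness, grid = grid_spec(3, 6),
                             reducer = c("max", "mean")) {
  reducer <- match.arg(reducer)
  f <- if (reducer == "max") function(x) max(x) else function(x) mean(x)
  dplyr::bind_cols(richness,
                   grid_cell(richness$latitude, richness$longitude, grid)) |>
    dplyr::summarise(richness = f(.data$richness), n_units = dplyr::n(),
                     .by = c("cell_lat_lo", "cell_lon_lo"))
}

#' Latitudinal diversity gradient
#'
#' Per 10-degree latitude bin, a high percentile (default the 95th, linear
#' interpolation between order statistics) of unit richness, plus a smooth
#' curve through the (bin centre, percentile) points.  The default smoother
#' is a generalized-cross-validated cubic smoothing spline; `"gam"` fits a
#' thin-plate GAM via mgcv.  Fewer than 4 populated bins skips the smoother
#' with a warning (percentiles are still returned).
#'
#' @param richness tibble from [richness_table()].
#' @param bin bin width in degrees (half-open bins anchored at -90; the
#'   topmost bin is closed at 90).
#' @param prob percentile level in (0, 1].
#' @param smoother `"spline"`, `"gam"` or `"none"`.
#' @return tibble `bin_lo`, `bin_centre`, `n_units`, `percentile`, `fitted`.
#' @export
latitudinal_gradient <- function(richness, bin = 10, prob = 0.95,
                                 smoother = c("spline", "gam", "none")) {
  smoother <- match.arg(smoother)
  d <- richness
  d$bin_lo <- bin * floor(d$latitude / bin)
  d$bin_lo[d$latitude >= 90] <- 90 - bin
  out <- d |>
    dplyr::summarise(
      n_units = dplyr::n(),
      percentile = unname(quantile(.data$richness, prob, type = 7)),
      .by = "bin_lo"
    ) |>
    dplyr::mutate(bin_centre = .data$bin_lo + bin / 2) |>
    dplyr::arrange(.data$bin_lo) |>
    dplyr::select("bin_lo", "bin_centre", "n_units", "percentile")

  out$fitted <- NA_real_
  if (smoother == "none") return(out)
  if (nrow(out) < 4) {
    rlang::warn("latitudinal_gradient(): fewer than 4 populated bins; smoother skipped")
    return(out)
  }
  if (smoother == "spline") {
    fit <- stats::smooth.spline(out$bin_centre, out$percentile, cv = FALSE)
    out$fitted <- predict(fit, out$bin_centre)$y
  } else {
    k <- min(nrow(out) - 1, 6)
    fit <- mgcv::gam(percentile ~ s(bin_centre, k = k), data = out)
    out$fitted <- as.numeric(predict(fit, out))
  }
  out
}

#' Gridded richness difference between two presence datasets
#'
#' Compares modern (water-column) against pre-industrial (surface-sediment)
#' species richness on a shared grid and taxonomy, on a presence/absence
#' basis.  Cell richness is computed on the pooled presences of all units
#' falling in the cell (the union of species seen anywhere in the cell), since
#' sediment sites and plankton profiles differ in their per-unit support.
#' The difference is `modern - preindustrial` (positive = modern gain); cells
#' occupied in only one dataset are reported separately, never as differences.
#'
#' @param modern,preindustrial long tibbles with `latitude`, `longitude`,
#'   `species` and `value` or `present`.
#' @param taxa shared analysis set (character), or `NULL` for the union.
#' @param grid a [grid_spec()]; the 4.5 x 9 degree grid by default.
#' @return list with tibbles `diff` (`cell_lat_lo`, `cell_lon_lo`,
#'   `richness_modern`, `richness_preindustrial`, `difference`),
#'   `modern_only` and `preindustrial_only`.
#' @export
richness_change <- function(modern, preindustrial, taxa = NULL,
                            grid = grid_spec(4.5, 9)) {
  pooled <- function(d) {
    val <- if ("present" %in% names(d)) d$present else d$value
    d$.present <- !is.na(val) & val > 0
    if (!is.null(taxa)) d <- d[d$species %in% taxa, , drop = FALSE]
    dplyr::bind_cols(d, grid_cell(d$latitude, d$longitude, grid)) |>
      dplyr::summarise(
        richness = dplyr::n_distinct(.data$species[.data$.present]),
        .by = c("cell_lat_lo", "cell_lon_lo")
      )
  }
  m <- pooled(modern)
  p <- pooled(preindustrial)
  both <- dplyr::inner_join(m, p, by = c("cell_lat_lo", "cell_lon_lo"),
                            suffix = c("_modern", "_preindustrial")) |>
    dplyr::mutate(difference = .data$richness_modern -
                    .data$richness_preindustrial) |>
    dplyr::rename(richness_modern = "richness_modern",
                  richness_preindustrial = "richness_preindustrial")
  list(
    diff = both,
    modern_only = dplyr::anti_join(m, p, by = c("cell_lat_lo", "cell_lon_lo")),
    preindustrial_only = dplyr::anti_join(p, m,
                                          by = c("cell_lat_lo", "cell_lon_lo"))
  )
}
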