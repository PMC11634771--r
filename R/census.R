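# Census ingest: FORCIS-like subsample tables, ForCenS-like sediment tables,
# taxonomy tables, season assignment, profile grouping and filtering.
#
# The canonical in-memory representation of a census is a long tibble with one
# row per (subsample, species) count and the subsample metadata repeated on
# each row.  Species with an NA cell in the wide CSV are treated as "not
# assessed" and carry no row; explicit zeroes are kept.

CENSUS_META_COLS <- c(
  "subsample_id", "sample_id", "latitude", "longitude", "date",
  "depth_upper", "depth_lower", "device", "size_lower", "size_upper",
  "volume_filtered", "count_kind"
)

#' Describe how census CSV columns map onto the canonical fields
#'
#' @param subsample_id,sample_id,latitude,longitude,date,depth_upper,depth_lower,device,size_lower,size_upper,volume_filtered,count_kind
#'   column names in the CSV holding each canonical field. `sample_id`,
#'   `volume_filtered` and `count_kind` may name absent columns; sensible
#'   defaults are filled in (`sample_id = subsample_id`, `count_kind =
#'   "raw_count"`, missing volume).
#' @param species_cols character vector of the CSV columns holding per-species
#'   counts/concentrations, or `NULL` to use every unmapped column.
#' @return a named list used by [read_census()].
#' @export
census_schema <- function(subsample_id = "subsample_id",
                          sample_id = "sample_id",
                          latitude = "latitude",
                          longitude = "longitude",
                          date = "date",
                          depth_upper = "depth_upper",
                          depth_lower = "depth_lower",
                          device = "device",
                          size_lower = "size_lower",
                          size_upper = "size_upper",
                          volume_filtered = "volume_filtered",
                          count_kind = "count_kind",
                          species_cols = NULL) {
  list(
    subsample_id = subsample_id, sample_id = sample_id,
    latitude = latitude, longitude = longitude, date = date,
    depth_upper = depth_upper, depth_lower = depth_lower,
    device = device, size_lower = size_lower, size_upper = size_upper,
    volume_filtered = volume_filtered, count_kind = count_kind,
    species_cols = species_cols
  )
}

# Row-wise invariant check on the canonical wide metadata. Returns a character
# vector of ";"-separated violation messages ("" where the row is valid).
census_row_problems <- function(meta) {
  n <- nrow(meta)
  probs <- rep("", n)
  add <- function(bad, msg) {
    bad <- which(bad)
    probs[bad] <<- ifelse(probs[bad] == "", msg, paste(probs[bad], msg, sep = "; "))
  }
  add(is.na(meta$latitude) | meta$latitude < -90 | meta$latitude > 90,
      "latitude outside [-90, 90]")
  add(is.na(meta$longitude) | meta$longitude < -180 | meta$longitude >= 180,
      "longitude outside [-180, 180)")
  add(is.na(meta$date), "unparseable date")
  add(is.na(meta$depth_upper) | meta$depth_upper < 0, "depth_upper missing or < 0")
  add(is.na(meta$depth_lower) | !(meta$depth_lower > meta$depth_upper) &
        !is.na(meta$depth_upper),
      "depth interval invalid (requires depth_upper < depth_lower)")
  add(!(meta$device %in% CENSUS_DEVICES),
      paste0("device not one of {", paste(CENSUS_DEVICES, collapse = ", "), "}"))
  add(is.na(meta$size_lower) | meta$size_lower < 0, "size_lower missing or < 0")
  add(!is.na(meta$size_upper) & !is.na(meta$size_lower) &
        meta$size_upper <= meta$size_lower,
      "size fraction invalid (requires size_lower < size_upper)")
  add(!is.na(meta$volume_filtered) & meta$volume_filtered <= 0,
      "volume_filtered must be > 0 when present")
  add(!(meta$count_kind %in% c("raw_count", "concentration")),
      "count_kind not one of {raw_count, concentration}")
  probs
}

#' Read a FORCIS-style census CSV into the canonical long form
#'
#' Each CSV row is one subsample (a single plankton aliquot from one location,
#' date, depth interval and size fraction).  Rows violating the subsample
#' invariants are rejected, not silently dropped: they are collected, with
#' row-indexed diagnostics, in the `"rejected"` attribute (see
#' [rejected_rows()]) and reported via a warning.  A blank/missing
#' `size_upper` encodes an unbounded ("OPEN") top fraction and becomes `NA` in
#' the output.  Negative species counts reject the row.
#'
#' @param path CSV file path (comma separated, UTF-8, `.` decimal, ISO-8601
#'   dates).
#' @param schema a [census_schema()].
#' @return a long tibble with columns `r paste(CENSUS_META_COLS, collapse=", ")`,
#'   `species`, `value`, plus derived `year`, `month`, `season`; attribute
#'   `"rejected"` holds the rejected rows.
#' @export
read_census <- function(path, schema = census_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  census_from_frame(raw, schema)
}

# Shared by read_census() and the simulator round-trip tests.
census_from_frame <- function(raw, schema = census_schema()) {
  mandatory <- c("subsample_id", "latitude", "longitude", "date",
                 "depth_upper", "depth_lower", "device", "size_lower")
  missing_cols <- vapply(mandatory, function(f) !(schema[[f]] %in% names(raw)),
                         logical(1))
  if (any(missing_cols)) {
    foram_abort(
      paste0("census CSV is missing mandatory column(s): ",
             paste(unlist(schema[mandatory[missing_cols]]), collapse = ", ")),
      "foramshift_schema_error"
    )
  }

  get_col <- function(field, default = NULL) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  meta <- tibble(
    subsample_id = as.character(get_col("subsample_id")),
    sample_id = as.character(get_col("sample_id") %||% get_col("subsample_id")),
    latitude = num(get_col("latitude")),
    longitude = num(get_col("longitude")),
    date = suppressWarnings(as.Date(as.character(get_col("date")),
                                    format = "%Y-%m-%d")),
    depth_upper = num(get_col("depth_upper")),
    depth_lower = num(get_col("depth_lower")),
    device = as.character(get_col("device")),
    size_lower = num(get_col("size_lower")),
    size_upper = num(get_col("size_upper", default = NA_real_)),
    volume_filtered = num(get_col("volume_filtered", default = NA_real_)),
    count_kind = as.character(get_col("count_kind", default = "raw_count"))
  )
  meta$count_kind[is.na(meta$count_kind)] <- "raw_count"

  sp_cols <- schema$species_cols %||%
    setdiff(names(raw), unlist(schema[setdiff(names(schema), "species_cols")]))
  if (length(sp_cols) == 0) {
    foram_abort("no species columns found in census CSV",
                "foramshift_schema_error")
  }
  counts <- raw[sp_cols]
  counts[] <- lapply(counts, num)

  problems <- census_row_problems(meta)
  neg <- vapply(seq_len(nrow(counts)),
                function(i) any(unlist(counts[i, ]) < 0, na.rm = TRUE),
                logical(1))
  problems[neg] <- ifelse(problems[neg] == "", "negative species count",
                          paste(problems[neg], "negative species count", sep = "; "))

  bad <- problems != ""
  rejected <- tibble(row = which(bad),
                     subsample_id = meta$subsample_id[bad],
                     reason = problems[bad])
  if (nrow(rejected) > 0) {
    rlang::warn(paste0(nrow(rejected), " census row(s) rejected; see ",
                       "rejected_rows() for diagnostics"))
  }

  long <- dplyr::bind_cols(meta[!bad, ], counts[!bad, , drop = FALSE]) |>
    tidyr::pivot_longer(dplyr::all_of(sp_cols), names_to = "species",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  long <- long |>
    dplyr::mutate(
      year = year_of(.data$date),
      month = month_of(.data$date),
      season = assign_season(.data$latitude, .data$date)
    )
  attr(long, "rejected") <- rejected
  long
}

#' Rejected-row diagnostics from a census read
#'
#' @param records the result of [read_census()].
#' @return tibble with columns `row`, `subsample_id`, `reason`.
#' @export
rejected_rows <- function(records) {
  attr(records, "rejected") %||% tibble(row = integer(), subsample_id = character(),
                                        reason = character())
}

#' Write canonical census records back to a wide CSV
#'
#' Inverse of [read_census()] up to column order: species absent from a
#' subsample are written as empty cells, the OPEN size fraction as an empty
#' `size_upper`.
#'
#' @param records long census tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(records, path) {
  wide <- records |>
    dplyr::select(dplyr::all_of(CENSUS_META_COLS), "species", "value") |>
    tidyr::pivot_wider(names_from = "species", values_from = "value")
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Read a ForCenS-style surface-sediment presence/absence CSV
#'
#' One row per site with `site_id`, `latitude`, `longitude` and one 0/1 column
#' per species (non-zero abundances are coerced to presence = 1).
#'
#' @param path CSV path.
#' @param species_cols species columns; `NULL` for all unnamed ones.
#' @return long tibble `site_id`, `latitude`, `longitude`, `species`, `present`.
#' @export
read_sediment <- function(path, species_cols = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("site_id", "latitude", "longitude")
  if (!all(needed %in% names(raw))) {
    foram_abort("sediment CSV must have site_id, latitude, longitude columns",
                "foramshift_schema_error")
  }
  sp_cols <- species_cols %||% setdiff(names(raw), needed)
  raw |>
    dplyr::mutate(site_id = as.character(.data$site_id)) |>
    tidyr::pivot_longer(dplyr::all_of(sp_cols), names_to = "species",
                        values_to = "present") |>
    dplyr::filter(!is.na(.data$present)) |>
    dplyr::mutate(present = as.integer(.data$present > 0))
}

#' Read a taxonomy table
#'
#' Columns: `species_name`, `lumped_name`, `province` (tropical, subtropical,
#' temperate, subpolar, polar, global), `trophic` (symbiont_bearing,
#' symbiont_barren, facultative), `spinose` (logical).  The lumping map must be
#' idempotent: every `lumped_name` that itself appears as a `species_name`
#' must map to itself.
#'
#' @param path CSV path.
#' @return taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_taxonomy(tax)
}

validate_taxonomy <- function(tax) {
  needed <- c("species_name", "lumped_name")
  if (!all(needed %in% names(tax))) {
    foram_abort("taxonomy needs species_name and lumped_name columns",
                "foramshift_schema_error")
  }
  map <- setNames(tax$lumped_name, tax$species_name)
  twice <- ifelse(map %in% names(map), unname(map[map]), unname(map))
  if (any(twice != unname(map))) {
    foram_abort("taxonomy lumping map is not idempotent", "foramshift_taxonomy_error")
  }
  as_tibble(tax)
}

#' Lump morphospecies into analysis taxa
#'
#' Counts of morphospecies mapping to the same `lumped_name` are summed within
#' each subsample; the per-subsample total count is conserved exactly.  Species
#' missing from the taxonomy pass through unchanged with one logged warning, so
#' partial taxonomies remain usable (a species the taxonomy deliberately maps
#' to itself — e.g. the pink ruber kept apart from its white counterpart —
#' stays separate).
#'
#' @param records long census tibble.
#' @param taxonomy taxonomy tibble (see [read_taxonomy()]).
#' @return records with `species` replaced by lumped names.
#' @export
lump_taxa <- function(records, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  map <- setNames(taxonomy$lumped_name, taxonomy$species_name)
  unmapped <- setdiff(unique(records$species), names(map))
  if (length(unmapped) > 0) {
    rlang::warn(paste0("species not in taxonomy passed through unchanged: ",
                       paste(unmapped, collapse = ", ")))
  }
  key_cols <- intersect(names(records), c(CENSUS_META_COLS, "year", "month",
                                          "season", "profile_id"))
  records |>
    dplyr::mutate(species = ifelse(.data$species %in% names(map),
                                   unname(map[.data$species]), .data$species)) |>
    dplyr::summarise(value = sum(.data$value),
                     .by = dplyr::all_of(c(key_cols, "species")))
}

#' Hemisphere-aware meteorological season of a sampling date
#'
#' Northern convention (latitude >= 0, the equator counting as Northern):
#' winter = Dec-Feb, spring = Mar-May, summer = Jun-Aug, autumn = Sep-Nov;
#' the Southern Hemisphere is offset by six months.
#'
#' @param latitude degrees north, vectorized.
#' @param date `Date` vector.
#' @return character vector in `c("winter", "spring", "summer", "autumn")`.
#' @export
assign_season <- function(latitude, date) {
  mo <- month_of(date)
  north <- c("winter", "winter", "spring", "spring", "spring", "summer",
             "summer", "summer", "autumn", "autumn", "autumn", "winter")
  season <- north[mo]
  south <- latitude < 0
  flip <- c(winter = "summer", spring = "autumn", summer = "winter",
            autumn = "spring")
  season[south] <- unname(flip[season[south]])
  season
}

#' Group subsamples into vertical profiles
#'
#' Subsamples sharing device, date and location (within `location_tolerance`,
#' implemented by snapping coordinates to a tolerance grid) form one profile.
#' Adds per-row columns `profile_id`, `profile_n` (number of distinct depth
#' intervals), `profile_depth_min`, `profile_depth_max` and `profile_valid`
#' (FALSE when the profile's distinct depth intervals overlap).  Several size
#' fractions of the same aliquot share a depth interval and count as one
#' member.
#'
#' @param records long census tibble.
#' @param location_tolerance degrees; default 0.01.
#' @return records with profile columns added.
#' @export
group_profiles <- function(records, location_tolerance = 0.01) {
  key <- paste(records$device, records$date,
               round(records$latitude / location_tolerance),
               round(records$longitude / location_tolerance), sep = "|")
  records$profile_id <- paste0("P", as.integer(factor(key)))

  intervals <- records |>
    dplyr::distinct(.data$profile_id, .data$depth_upper, .data$depth_lower)
  prof <- intervals |>
    dplyr::arrange(.data$profile_id, .data$depth_upper) |>
    dplyr::summarise(
      profile_n = dplyr::n(),
      profile_depth_min = min(.data$depth_upper),
      profile_depth_max = max(.data$depth_lower),
      # half-open intervals: the next interval may start exactly at the
      # previous lower bound without overlapping
      profile_valid = all(head(.data$depth_lower, -1) <=
                            tail(.data$depth_upper, -1)) || dplyr::n() == 1,
      .by = "profile_id"
    )
  dplyr::left_join(records, prof, by = "profile_id")
}

#' Filter census records by a conjunction of predicates
#'
#' All predicates are optional; `NULL` means "no constraint", so the empty
#' call is the identity.  Depth windows and latitude bands are half-open
#' (`[lo, hi)`), except a latitude band reaching 90 which is closed at the
#' pole.  A subsample is inside a depth window when `depth_upper >= lo`,
#' `depth_upper < hi` and `depth_lower <= hi`.  The number of subsamples
#' removed by each predicate is recorded in the `"filter_report"` attribute;
#' an empty result warns rather than errors.
#'
#' @param records long census tibble (needs `profile_n` from
#'   [group_profiles()] if `min_profile_size` is used).
#' @param depth_range `c(lo, hi)` metres.
#' @param seasons subset of `c("winter", "spring", "summer", "autumn")`.
#' @param lat_band `c(lo, hi)` degrees north.
#' @param lon_window `c(lo, hi)` degrees east.
#' @param devices subset of `c("net", "cpr", "pump", "trap")`.
#' @param years `c(first, last)`, inclusive.
#' @param min_profile_size minimum number of distinct depth intervals.
#' @return filtered records, attribute `"filter_report"`.
#' @export
filter_records <- function(records, depth_range = NULL, seasons = NULL,
                           lat_band = NULL, lon_window = NULL, devices = NULL,
                           years = NULL, min_profile_size = NULL) {
  report <- list()
  drop_count <- function(before, after) {
    dplyr::n_distinct(before$subsample_id) - dplyr::n_distinct(after$subsample_id)
  }
  apply_pred <- function(x, name, keep) {
    out <- x[keep & !is.na(keep), , drop = FALSE]
    report[[name]] <<- drop_count(x, out)
    out
  }

  out <- records
  if (!is.null(depth_range)) {
    out <- apply_pred(out, "depth_range",
                      out$depth_upper >= depth_range[1] &
                        out$depth_upper < depth_range[2] &
                        out$depth_lower <= depth_range[2])
  }
  if (!is.null(seasons)) {
    out <- apply_pred(out, "seasons", out$season %in% seasons)
  }
  if (!is.null(lat_band)) {
    hi_ok <- if (lat_band[2] >= 90) out$latitude <= 90 else out$latitude < lat_band[2]
    out <- apply_pred(out, "lat_band", out$latitude >= lat_band[1] & hi_ok)
  }
  if (!is.null(lon_window)) {
    out <- apply_pred(out, "lon_window",
                      out$longitude >= lon_window[1] & out$longitude < lon_window[2])
  }
  if (!is.null(devices)) {
    out <- apply_pred(out, "devices", out$device %in% devices)
  }
  if (!is.null(years)) {
    out <- apply_pred(out, "years", out$year >= years[1] & out$year <= years[2])
  }
  if (!is.null(min_profile_size)) {
    if (!("profile_n" %in% names(out))) {
      foram_abort("min_profile_size requires group_profiles() first",
                  "foramshift_filter_error")
    }
    out <- apply_pred(out, "min_profile_size", out$profile_n >= min_profile_size)
  }
  if (nrow(out) == 0) rlang::warn("filter_records(): no records left")
  attr(out, "filter_report") <- report
  out
}
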