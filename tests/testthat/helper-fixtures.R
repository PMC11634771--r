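# Fixtures are built in code at test time; no binary data.

# Wide toy census data frame with two species columns.
toy_census_df <- function() {
  data.frame(
    subsample_id = c("s1", "s2", "s3"),
    sample_id = c("a", "a", "b"),
    latitude = c(40, 40, -20),
    longitude = c(-30, -30, 10),
    date = c("1995-07-15", "1995-07-15", "2001-12-01"),
    depth_upper = c(0, 50, 0),
    depth_lower = c(50, 100, 200),
    device = "net",
    size_lower = c(100, 100, 150),
    size_upper = c(NA, NA, NA),
    volume_filtered = c(25, 25, 50),
    count_kind = "raw_count",
    G_ruber = c(3, 0, 7),
    N_pachyderma = c(0, 2, 5),
    stringsAsFactors = FALSE
  )
}

write_toy_census <- function(df = toy_census_df()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  # blank size_upper encodes the OPEN fraction
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Minimal long records for estimator tests (already "harmonized").
make_records <- function(latitude, year, species = "sp", concentration = 1,
                         depth_upper = 0, depth_lower = 50, month = 7,
                         device = "net", longitude = -30) {
  n <- max(length(latitude), length(year), length(concentration),
           length(depth_upper))
  d <- tibble::tibble(
    subsample_id = sprintf("r%04d", seq_len(n)),
    sample_id = sprintf("r%04d", seq_len(n)),
    latitude = rep_len(latitude, n),
    longitude = rep_len(longitude, n),
    year = rep_len(year, n),
    month = rep_len(month, n),
    depth_upper = rep_len(depth_upper, n),
    depth_lower = rep_len(depth_lower, n),
    device = rep_len(device, n),
    species = rep_len(species, n),
    concentration = rep_len(concentration, n)
  )
  d$date <- as.Date(sprintf("%d-%02d-15", d$year, d$month))
  d$season <- assign_season(d$latitude, d$date)
  d
}

# Profile records whose per-profile depth of maximum abundance lands in the
# 10-m interval containing `target_depth` (20 intervals over 0-200 m).
make_dma_profiles <- function(target_depth, year, id_prefix = "p") {
  n <- length(target_depth)
  rows <- lapply(seq_len(n), function(i) {
    ups <- seq(0, 190, by = 10)
    peak <- findInterval(target_depth[i], c(ups, 200))
    d <- tibble::tibble(
      subsample_id = sprintf("%s%03d_%02d", id_prefix, i, seq_along(ups)),
      sample_id = subsample_id,
      latitude = 35, longitude = -30,
      year = year[i], month = 6,
      depth_upper = ups, depth_lower = ups + 10,
      device = "net", species = "sp",
      concentration = ifelse(seq_along(ups) == peak, 10, 0.1),
      profile_id = sprintf("%s%03d", id_prefix, i),
      profile_n = length(ups),
      profile_depth_min = 0, profile_depth_max = 200,
      profile_valid = TRUE
    )
    d$date <- as.Date(sprintf("%d-06-15", d$year))
    d$season <- "summer"
    d
  })
  dplyr::bind_rows(rows)
}

# Independent type-7 quantile oracle (sort-based, linear interpolation).
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force winding-number point-in-polygon oracle (boundary-inclusive up
# to angular tolerance).
winding_oracle <- function(px, py, vx, vy) {
  vapply(seq_along(px), function(i) {
    dx <- vx - px[i]
    dy <- vy - py[i]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# Tiny 4-D field: values from a supplied function, optionally masked cells.
tiny_field <- function(f, lat = c(0, 10), lon = c(-30, -20),
                       depth = c(0, 100), time = c(2000.5, 2001.5),
                       variable = "temperature_degC") {
  field_from_function(f, variable, lat, lon, depth, time)
}
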