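CENSUS_META_COLS_TEST <- c(
  "subsample_id", "sample_id", "latitude", "longitude", "date",
  "depth_upper", "depth_lower", "device", "size_lower", "size_upper",
  "volume_filtered", "count_kind"
)

test_that("census ingest preserves counts and survives a write/read round trip", {
  path <- write_toy_census()
  recs <- read_census(path)
  expect_equal(dplyr::n_distinct(recs$subsample_id), 3)
  expect_equal(nrow(rejected_rows(recs)), 0)
  expect_equal(recs$value[recs$subsample_id == "s1" &
                            recs$species == "G_ruber"], 3)
  # blank size_upper encodes the OPEN top fraction
  expect_true(all(is.na(recs$size_upper)))

  out <- withr::local_tempfile(fileext = ".csv")
  write_census(recs, out)
  back <- read_census(out)
  key <- function(d) dplyr::arrange(d[, c(CENSUS_META_COLS_TEST, "species",
                                          "value")],
                                    subsample_id, species)
  expect_equal(key(back), key(recs))
})

test_that("rows violating subsample invariants are rejected with diagnostics", {
  df <- toy_census_df()
  df$depth_upper[1] <- 50
  df$depth_lower[1] <- 20
  df$device[2] <- "submarine"
  df$G_ruber[3] <- -1
  path <- write_toy_census(df)
  expect_warning(recs <- read_census(path), "rejected")
  rej <- rejected_rows(recs)
  expect_equal(sort(rej$row), 1:3)
  expect_match(rej$reason[rej$row == 1], "depth interval")
  expect_match(rej$reason[rej$row == 2], "device")
  expect_match(rej$reason[rej$row == 3], "negative")
  expect_equal(nrow(recs), 0)
})

test_that("missing mandatory columns raise a schema error", {
  df <- toy_census_df()
  df$latitude <- NULL
  path <- write_toy_census(df)
  expect_error(read_census(path), class = "foramshift_schema_error")
})

test_that("lumping sums morphospecies and conserves per-subsample totals", {
  recs <- tibble::tibble(
    subsample_id = "s1", sample_id = "s1", latitude = 10, longitude = 0,
    date = as.Date("2000-06-15"), depth_upper = 0, depth_lower = 100,
    device = "net", size_lower = 100, size_upper = NA_real_,
    volume_filtered = 10, count_kind = "raw_count",
    species = c("A1", "A2", "ruber_pink", "ruber_white"),
    value = c(3, 5, 2, 4)
  )
  tax <- tibble::tibble(
    species_name = c("A1", "A2", "ruber_pink", "ruber_white"),
    lumped_name = c("A", "A", "ruber_pink", "ruber_white")
  )
  lumped <- lump_taxa(recs, tax)
  expect_equal(lumped$value[lumped$species == "A"], 8)
  # the pink type stays separate from its white counterpart
  expect_true(all(c("ruber_pink", "ruber_white") %in% lumped$species))
  expect_equal(sum(lumped$value), sum(recs$value))

  # identity map leaves values unchanged; unmapped species warn and pass
  expect_warning(thru <- lump_taxa(recs, tax[1:2, ]), "passed through")
  expect_equal(sum(thru$value), sum(recs$value))

  bad_tax <- tibble::tibble(species_name = c("A1", "A"),
                            lumped_name = c("A", "B"))
  expect_error(lump_taxa(recs, bad_tax), class = "foramshift_taxonomy_error")
})

test_that("seasons are hemisphere-aware and partition all dates", {
  expect_equal(assign_season(40, as.Date("1990-07-15")), "summer")
  expect_equal(assign_season(-40, as.Date("1990-07-15")), "winter")
  # the equator counts as Northern Hemisphere
  expect_equal(assign_season(0, as.Date("1990-12-01")), "winter")
  grid <- expand.grid(lat = c(-50, 0, 50), month = 1:12)
  seas <- assign_season(grid$lat,
                        as.Date(sprintf("2000-%02d-15", grid$month)))
  expect_true(all(seas %in% c("winter", "spring", "summer", "autumn")))
  expect_equal(length(seas), nrow(grid))
})

test_that("profile grouping keys on device, date and snapped location", {
  base <- make_records(latitude = 40, year = 2000,
                       depth_upper = c(0, 20, 50, 100),
                       depth_lower = c(20, 50, 100, 200))
  g <- group_profiles(base)
  expect_equal(dplyr::n_distinct(g$profile_id), 1)
  expect_equal(unique(g$profile_n), 4)
  expect_true(all(g$profile_valid))

  two <- make_records(latitude = c(40, 45), year = 2000)
  expect_equal(dplyr::n_distinct(group_profiles(two)$profile_id), 2)

  # overlapping depth intervals flag the profile invalid
  bad <- make_records(latitude = 40, year = 2000,
                      depth_upper = c(0, 30, 50, 100),
                      depth_lower = c(40, 60, 100, 200))
  expect_false(any(group_profiles(bad)$profile_valid))
})

test_that("filters are conjunctive, half-open and idempotent", {
  recs <- make_records(latitude = c(25, 35, 45, 55), year = c(1980, 1995,
                                                              1995, 2010),
                       month = c(7, 7, 1, 7),
                       depth_upper = c(0, 0, 0, 200),
                       depth_lower = c(50, 50, 50, 300))
  expect_identical(nrow(filter_records(recs)), nrow(recs))

  # depth window [0, 200): a record starting exactly at 200 m is excluded
  d <- filter_records(recs, depth_range = c(0, 200))
  expect_false("r0004" %in% d$subsample_id)

  # 30-50 N + summer: hand-enumerated subset
  f <- filter_records(recs, lat_band = c(30, 50), seasons = "summer")
  expect_setequal(f$subsample_id, "r0002")
  expect_equal(attr(f, "filter_report")$seasons, 1)

  expect_equal(filter_records(f, lat_band = c(30, 50), seasons = "summer"),
               f, ignore_attr = TRUE)
  expect_true(all(filter_records(recs, years = c(1990, 2000))$subsample_id
                  %in% recs$subsample_id))
  expect_warning(filter_records(recs, lat_band = c(80, 90)), "no records")
})

test_that("sediment and taxonomy readers validate their tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(site_id = c("x", "y"), latitude = c(10, 60),
                              longitude = 0, A = c(1, 0), B = c(3, 1)),
                   path, row.names = FALSE)
  sed <- read_sediment(path)
  expect_equal(sort(unique(sed$present)), c(0L, 1L))
  expect_equal(sed$present[sed$site_id == "x" & sed$species == "B"], 1L)

  tpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(species_name = "A1", lumped_name = "A",
                              province = "tropical",
                              trophic = "symbiont_bearing", spinose = TRUE),
                   tpath, row.names = FALSE)
  expect_s3_class(read_taxonomy(tpath), "tbl_df")
})
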