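test_that("the range edge is the stated occurrence-latitude quantile", {
  recs <- make_records(latitude = rep(42, 30), year = 2000)
  expect_equal(as.numeric(northern_edge(recs, "sp")), 42)

  lats <- make_records(latitude = 0:89, year = 2000)
  expect_equal(as.numeric(northern_edge(lats, "sp")), 84.55)
  expect_equal(as.numeric(northern_edge(lats, "sp")),
               quantile_oracle(0:89, 0.95))
  expect_equal(as.numeric(northern_edge(lats, "sp", quantile = 1)), 89)
  expect_equal(as.numeric(northern_edge(lats, "sp", method = "max")), 89)

  # monotone in the quantile level
  qs <- sapply(c(0.5, 0.8, 0.95, 1), function(q)
    as.numeric(northern_edge(lats, "sp", quantile = q)))
  expect_true(all(diff(qs) >= 0))

  # proportional duplication leaves the edge unchanged up to the
  # finite-sample wobble of the interpolated quantile (< one latitude step)
  expect_equal(as.numeric(northern_edge(dplyr::bind_rows(lats, lats), "sp")),
               as.numeric(northern_edge(lats, "sp")), tolerance = 0.01)

  few <- make_records(latitude = rep(10, 5), year = 2000)
  e <- northern_edge(few, "sp")
  expect_true(is.na(e))
  expect_equal(attr(e, "n"), 5)
})

test_that("poleward shift converts degrees to km over median-year spans", {
  before <- make_records(latitude = rep(40, 25), year = 1975)
  after <- make_records(latitude = rep(45, 25), year = 2005)
  after$subsample_id <- paste0("x", after$subsample_id)
  est <- poleward_shift(dplyr::bind_rows(before, after), "sp")
  expect_equal(est$delta, 5 * 111.32)
  expect_equal(est$speed_km_per_yr, 556.6 / 30, tolerance = 1e-10)

  # identical occurrence sets in both periods: no shift
  same <- dplyr::bind_rows(
    make_records(latitude = 20 + (1:30) / 3, year = 1980),
    make_records(latitude = 20 + (1:30) / 3, year = 2000) |>
      dplyr::mutate(subsample_id = paste0("y", subsample_id))
  )
  est0 <- poleward_shift(same, "sp")
  expect_equal(est0$delta, 0)
  expect_equal(est0$speed_km_per_yr, 0)

  # swapping the period labels negates delta and speed
  swapped <- dplyr::bind_rows(before, after) |>
    dplyr::mutate(year = ifelse(year == 1975, 2005, 1975),
                  date = as.Date(sprintf("%d-07-15", year)))
  est_sw <- poleward_shift(swapped, "sp")
  expect_equal(est_sw$delta, -est$delta)
  expect_equal(est_sw$speed_km_per_yr, -est$speed_km_per_yr)

  insuf <- poleward_shift(before, "sp")
  expect_equal(insuf$classification, "insufficient_data")
})

test_that("depth of maximum abundance takes the shallowest winning interval", {
  prof <- tibble::tibble(
    subsample_id = paste0("s", 1:4), sample_id = paste0("s", 1:4),
    latitude = 30, longitude = -30, year = 2000,
    depth_upper = c(0, 20, 50, 100), depth_lower = c(20, 50, 100, 200),
    device = "net", species = "sp",
    concentration = c(5, 20, 8, 1),
    profile_id = "p1", profile_n = 4, profile_depth_min = 0,
    profile_depth_max = 200, profile_valid = TRUE
  )
  expect_equal(depth_of_max_abundance(prof, "sp")$depth_of_max, 35)

  tie <- dplyr::mutate(prof, concentration = c(5, 20, 20, 1))
  expect_equal(depth_of_max_abundance(tie, "sp")$depth_of_max, 35)

  zero <- dplyr::mutate(prof, concentration = 0)
  expect_equal(nrow(depth_of_max_abundance(zero, "sp")), 0)

  # profiles failing the >= 4-member / 0-200 m criteria are excluded
  small <- dplyr::mutate(prof, profile_n = 3)
  expect_equal(nrow(depth_of_max_abundance(small, "sp")), 0)
  deep <- dplyr::mutate(prof, profile_depth_max = 400)
  expect_equal(nrow(depth_of_max_abundance(deep, "sp")), 0)
})

test_that("the two-group ANOVA matches its closed form and the t-test", {
  av <- one_way_anova(c(10, 20, 30), c(40, 50, 60))
  expect_equal(av$F, 13.5)
  expect_equal(av$df_between, 1L)
  expect_equal(av$df_within, 4L)
  expect_equal(av$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(av$p_value, 0.0213, tolerance = 5e-3)

  same <- one_way_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  expect_true(is.na(one_way_anova(c(1), c(2, 3))$p_value))
  expect_true(is.na(one_way_anova(c(1, 1), c(1, 1))$p_value))

  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.5)
    av <- one_way_anova(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(av$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("vertical shift recovers a constructed deepening and classifies it", {
  set.seed(3)
  profs <- dplyr::bind_rows(
    make_dma_profiles(rnorm(30, 20, 5), rep(1988, 30), "a"),
    make_dma_profiles(rnorm(30, 75, 5), rep(2008, 30), "b")
  )
  est <- vertical_shift_test(profs, "sp", cutoff_year = 1997)
  expect_equal(est$classification, "significant_deepening")
  expect_equal(est$delta, 55, tolerance = 0.15)
  expect_equal(est$n_before, 30L)

  same <- dplyr::bind_rows(
    make_dma_profiles(seq(20, 80, length.out = 20), rep(1988, 20), "a"),
    make_dma_profiles(seq(20, 80, length.out = 20), rep(2008, 20), "b")
  )
  est0 <- vertical_shift_test(same, "sp", cutoff_year = 1997)
  expect_equal(est0$delta, 0)
  expect_equal(est0$classification, "not_significant")

  lone <- make_dma_profiles(c(30, 40), c(1988, 1989), "a")
  expect_equal(vertical_shift_test(lone, "sp")$classification,
               "insufficient_data")
})
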