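square_points <- function() {
  tibble::tibble(
    temperature = c(0, 1, 1, 0, 0.5, 0.2, 0.8, 0.5, 0.3, 0.6),
    omega_calcite = c(0, 0, 1, 1, 0.5, 0.4, 0.6, 0.2, 0.8, 0.3)
  )
}

test_that("the untrimmed envelope of a square cloud is the square", {
  env <- build_niche(square_points(), trim = c(0, 1))
  expect_equal(nrow(env$polygon), 4)
  expect_setequal(env$polygon$temperature, c(0, 1, 1, 0))
  expect_equal(env$n_retained, 10)

  dup <- build_niche(dplyr::bind_rows(square_points(), square_points()),
                     trim = c(0, 1))
  expect_setequal(paste(dup$polygon$temperature, dup$polygon$omega_calcite),
                  paste(env$polygon$temperature, env$polygon$omega_calcite))

  expect_error(build_niche(square_points()[1:5, ]),
               class = "foramshift_insufficient_data")
})

test_that("marginal trimming excludes the extreme outliers from the hull", {
  set.seed(9)
  pts <- tibble::tibble(temperature = rnorm(1000, 20, 3),
                        omega_calcite = rnorm(1000, 4, 0.5))
  env <- build_niche(pts, trim = c(0.01, 0.99))
  expect_lte(env$n_retained, 1000 - 4 * 5)
  extremes <- pts[c(which.max(pts$temperature), which.min(pts$temperature),
                    which.max(pts$omega_calcite),
                    which.min(pts$omega_calcite)), ]
  expect_false(any(in_envelope(env, extremes)))
  # envelope area grows with the trim interval
  wide <- build_niche(pts, trim = c(0, 1))
  expect_true(all(in_envelope(wide, env$polygon)))
})

test_that("emergence fractions hit their constructed values", {
  env <- build_niche(square_points(), trim = c(0, 1))
  expect_equal(emergence_fraction(square_points(), env), 0)

  outside <- dplyr::mutate(square_points(), temperature = temperature + 10)
  expect_equal(emergence_fraction(outside, env), 1)

  set.seed(4)
  half <- tibble::tibble(
    temperature = c(runif(500, 0.05, 0.95), runif(500, 2, 3)),
    omega_calcite = runif(1000, 0.05, 0.95)
  )
  expect_equal(emergence_fraction(half, env), 0.5)

  # boundary points count as inside
  rim <- tibble::tibble(temperature = c(0, 1, 0.5), omega_calcite = c(0, 1, 0))
  expect_equal(emergence_fraction(rim, env), 0)
})

test_that("emergence grows monotonically as the cloud translates outward", {
  set.seed(10)
  env <- build_niche(tibble::tibble(temperature = rnorm(200, 0, 1),
                                    omega_calcite = rnorm(200, 0, 1)),
                     trim = c(0, 1))
  cloud <- tibble::tibble(temperature = rnorm(300, 0, 1),
                          omega_calcite = rnorm(300, 0, 1))
  em <- sapply(seq(0, 8, by = 0.8), function(s)
    emergence_fraction(dplyr::mutate(cloud, temperature = temperature + s),
                       env))
  expect_true(all(diff(em) >= 0))
  expect_equal(em[1], emergence_fraction(cloud, env))
  expect_equal(em[length(em)], 1)
})

test_that("point-in-polygon agrees with the winding-number oracle", {
  set.seed(12)
  hull_pts <- cbind(rnorm(40), rnorm(40))
  h <- chull(hull_pts)
  vx <- hull_pts[h, 1]; vy <- hull_pts[h, 2]
  px <- runif(1000, -3, 3); py <- runif(1000, -3, 3)
  mine <- foramshift:::points_in_polygon(px, py, vx, vy)
  oracle <- winding_oracle(px, py, vx, vy)
  expect_equal(mine, oracle)
})

test_that("projected conditions track the scenario fields exactly", {
  f_T <- function(lat, lon, depth, time) 25 - 0.3 * lat + 0.1 * (time - 2000)
  f_O <- function(lat, lon, depth, time) 5 - 0.02 * lat
  hist <- list(
    temperature = tiny_field(f_T, lat = c(0, 50), depth = c(0, 200),
                             time = c(2000.5, 2018.5)),
    omega_calcite = tiny_field(f_O, lat = c(0, 50), depth = c(0, 200),
                               time = c(2000.5, 2018.5),
                               variable = "omega_calcite")
  )
  plus2 <- list(
    temperature = tiny_field(function(a, b, c, d) f_T(a, b, c, d) + 2,
                             lat = c(0, 50), depth = c(0, 200),
                             time = c(2049.5, 2050.5)),
    omega_calcite = tiny_field(f_O, lat = c(0, 50), depth = c(0, 200),
                               time = c(2049.5, 2050.5),
                               variable = "omega_calcite")
  )
  recs <- make_records(latitude = c(10, 30), year = 2010, month = 6,
                       depth_upper = 0, depth_lower = 100)
  recs$longitude <- -25
  cur <- attach_environment(recs, hist)
  # a scenario frozen at the historical state reproduces current conditions
  hist2050 <- hist
  hist2050$temperature$time <- hist2050$temperature$time + 40
  hist2050$omega_calcite$time <- hist2050$omega_calcite$time + 40
  # (time-shifted copy of the same values: conditions unchanged at clamp)
  proj2 <- project_conditions(recs, plus2, 2050)
  expect_equal(sort(proj2$temperature),
               sort(f_T(c(10, 30), 0, 0, 2050 + 5.5 / 12) + 2))
  expect_equal(sort(proj2$omega_calcite), sort(f_O(c(10, 30), 0, 0, 0)))

  expect_error(project_conditions(recs, plus2, 2100),
               class = "foramshift_parameter_error")
})

test_that("band summaries report zero emergence for an unchanged ocean", {
  w <- world_scenario(seed = 21, warming_rate = 0, omega_trend = 0,
                      years = c(2000, 2003))
  sv <- generate_survey(w, default_species_set()[c(1, 4, 7), ])
  fields <- generate_environment(w, years = 2000:2003)
  # the same climate continued to 2050: nothing emerges
  scen <- generate_environment(w, years = 2050)
  bs <- band_summary(sv$census, fields, scen,
                     bands = list(mid = c(20, 60)), horizons = 2050,
                     trim = c(0, 1))
  expect_equal(bs$summary$emergence, 0)

  # warming confined to the tropics: tropical emergence only
  w2 <- world_scenario(seed = 22, warming_rate = 0, omega_trend = 0,
                       years = c(2000, 2003))
  sv2 <- generate_survey(w2, default_species_set()[c(1, 4, 7), ])
  f2 <- generate_environment(w2, years = 2000:2003)
  scen2 <- f2
  bump <- array(0, dim = dim(scen2$temperature$values))
  bump[scen2$temperature$lat < 30, , , ] <- 10
  scen2$temperature$values <- scen2$temperature$values + bump
  scen2$temperature$time <- scen2$temperature$time + 47
  scen2$omega_calcite$time <- scen2$omega_calcite$time + 47
  scen2$co3$time <- scen2$co3$time + 47
  scen2$co3satcalc$time <- scen2$co3satcalc$time + 47
  bs2 <- band_summary(sv2$census, f2, scen2,
                      bands = list(tropical = c(0, 27), high = c(33, 90)),
                      horizons = 2050, trim = c(0, 1))
  em <- bs2$summary
  expect_gt(em$emergence[em$band == "tropical"], 0.5)
  expect_equal(em$emergence[em$band == "high"], 0)
})
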