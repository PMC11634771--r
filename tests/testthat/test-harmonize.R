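test_that("the multiplication factor hits its anchor points", {
  m <- size_norm_model(f_max = 3, S_half = 200, S_sup1 = 100)
  expect_equal(size_factor(100, m), 1)
  # half-saturation: midpoint between 1 and f_max
  expect_equal(size_factor(200, m), 2)
  expect_equal(size_factor(300, m), 1 + 2 * 200 / 300)
  expect_equal(size_factor(NA, m), 3)
  expect_equal(size_factor(Inf, m), 3)
  expect_error(size_factor(50, m), class = "foramshift_domain_error")
  expect_error(size_norm_model(f_max = 0.5), class = "foramshift_model_error")
})

test_that("f is strictly increasing and bounded by f_max", {
  m <- size_norm_model(f_max = 4.2, S_half = 310, S_sup1 = 80)
  grid <- seq(80, 5000, by = 5)
  f <- size_factor(grid, m)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 1 & f < m$f_max))
})

test_that("concentration normalization follows the printed formula", {
  # model and sizes chosen so that f(sz_norm) = 1.2, f(sz_inf) = 1.5,
  # f(sz_sup) = 2.5 with f_max = 3
  m <- size_norm_model(f_max = 3, S_half = 200, S_sup1 = 100,
                       sz_norm = 1000 / 9)
  expect_equal(size_factor(m$sz_norm, m), 1.2)
  expect_equal(normalize_concentration(10, 400 / 3, 400, m), 18)

  # a fraction already on the normalization basis is unchanged
  m100 <- size_norm_model()
  expect_equal(normalize_concentration(7.5, 100, NA, m100), 7.5)
  expect_equal(normalize_concentration(0, 150, 250, m100), 0)
  expect_error(normalize_concentration(1, 150, 150, m100),
               class = "foramshift_degenerate_fraction")
})

test_that("count-to-concentration conversion guards its domain", {
  expect_equal(to_concentration(50, 25), 2)
  expect_equal(to_concentration(0, 10), 0)
  expect_error(to_concentration(5, 0), class = "foramshift_unit_error")
  expect_error(to_concentration(5, NA), class = "foramshift_unit_error")
})

harmonize_fixture <- function(conc_by_fraction, sample_id = "a") {
  # conc_by_fraction: named list fraction "inf_sup" -> concentration
  rows <- lapply(names(conc_by_fraction), function(nm) {
    bounds <- suppressWarnings(as.numeric(strsplit(nm, "_")[[1]]))
    tibble::tibble(
      subsample_id = paste0(sample_id, "_", nm), sample_id = sample_id,
      latitude = 30, longitude = -30, date = as.Date("2000-06-15"),
      depth_upper = 0, depth_lower = 100, device = "net",
      size_lower = bounds[1],
      size_upper = if (is.na(bounds[2])) NA_real_ else bounds[2],
      volume_filtered = 1, count_kind = "concentration",
      species = "sp", value = conc_by_fraction[[nm]]
    )
  })
  dplyr::bind_rows(rows)
}

test_that("split sieve fractions harmonize to the whole-catch result", {
  m <- size_norm_model()
  c_tot <- 7.3
  # fractions carved from a population whose cumulative size distribution is
  # proportional to f: the independent construction the model inverts
  frac_conc <- function(a, b) {
    fb <- if (is.na(b)) m$f_max else size_factor(b, m)
    c_tot * (fb - size_factor(a, m)) / (m$f_max - size_factor(m$sz_norm, m))
  }
  split2 <- harmonize_fixture(list("100_150" = frac_conc(100, 150),
                                   "150_NA" = frac_conc(150, NA)))
  whole <- harmonize_fixture(list("100_NA" = frac_conc(100, NA)), "b")
  h2 <- harmonize_table(split2, m)
  hw <- harmonize_table(whole, m)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$concentration, hw$concentration, tolerance = 1e-12)
  expect_equal(hw$concentration, c_tot, tolerance = 1e-12)

  # any partition recovers the true >= sz_norm concentration exactly
  cuts <- list(c(100, 140), c(140, 200), c(200, 330), c(330, NA))
  parts <- lapply(cuts, function(cc) {
    normalize_concentration(frac_conc(cc[1], cc[2]), cc[1], cc[2], m)
  })
  for (p in parts) expect_equal(p, c_tot, tolerance = 1e-9)
})

test_that("harmonize_table converts, flags and excludes as specified", {
  recs <- harmonize_fixture(list("100_NA" = 4))
  recs$count_kind <- "raw_count"
  recs$volume_filtered <- 2
  recs$value <- 8
  h <- harmonize_table(recs)
  expect_equal(h$concentration, 4)
  expect_equal(h$harmonization, "raw")

  below <- harmonize_fixture(list("30_80" = 5))
  hb <- harmonize_table(below)
  expect_equal(hb$harmonization, "not_quantifiable")
  expect_true(is.na(hb$concentration))

  # raw counts without volume are excluded, not silently dropped
  novol <- harmonize_fixture(list("150_NA" = 6))
  novol$count_kind <- "raw_count"
  novol$volume_filtered <- NA_real_
  hn <- harmonize_table(novol)
  expect_equal(nrow(hn), 0)
  expect_equal(nrow(attr(hn, "excluded")), 1)

  # scale equivariance: doubling the measured concentration doubles the
  # normalized one
  one <- harmonize_fixture(list("150_NA" = 3))
  two <- harmonize_fixture(list("150_NA" = 6))
  expect_equal(2 * harmonize_table(one)$concentration,
               harmonize_table(two)$concentration)
})

test_that("per-species models override the global one", {
  recs <- dplyr::bind_rows(
    harmonize_fixture(list("150_NA" = 3)),
    harmonize_fixture(list("150_NA" = 3), "b") |>
      dplyr::mutate(species = "other")
  )
  # note: for open-top fractions the correction is independent of f_max
  # (numerator and denominator both scale with f_max - 1), so a per-species
  # model differs through S_half
  strong <- size_norm_model(S_half = 400)
  h <- harmonize_table(recs, per_species = list(other = strong))
  c_def <- h$concentration[h$species == "sp"]
  c_ovr <- h$concentration[h$species == "other"]
  expect_equal(c_def, normalize_concentration(3, 150, NA))
  expect_equal(c_ovr, normalize_concentration(3, 150, NA, strong))
  expect_false(isTRUE(all.equal(c_def, c_ovr)))
})
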