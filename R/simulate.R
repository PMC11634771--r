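# Synthetic FORCIS-like surveys, ForCenS-like sediment tables and idealized
# 4-D environmental fields with injected, known ground truth, so that every
# pipeline stage can be validated by parameter recovery.
#
# The idealized ocean is an Atlantic-like sector with temperature additive in
# depth: a mixed layer of depth `mld` overlying an exponential thermocline,
#   T(lat, z, t) = T_eq - g*lat - dT_depth*(1 - exp(-max(z - mld, 0)/z_scale))
#                  + warming*(t - t0)/10 + seasonal(z, t),
# so that isotherms at every depth drift poleward at the same rate and an
# injected poleward speed is realized exactly by drifting a species'
# effective thermal optimum against the meridional gradient g.  Omega_calcite
# declines linearly in time and depth; co3 = Omega * co3satcalc by
# construction.

#' Species scenario with injected ground truth
#'
#' Expected concentration of a species at a sampling point is
#' `base * Gaussian(T_local; T_opt_eff(t), T_sd) * Gaussian(z; depth_mode +
#' deepening*(t-t0)/10, depth_sd) * (1 + trend/100)^((t-t0)/10)`, with
#' `T_opt_eff(t) = T_opt + warming*(t-t0)/10 - g * (poleward_speed/111.32) *
#' (t-t0)` so that the realized latitudinal niche centre moves poleward at
#' exactly `poleward_speed` km/yr (a species with speed 0 holds its ground
#' and experiences the local warming; a species whose effective optimum is
#' fixed tracks the isotherms).  Counts are Poisson draws of `expected *
#' volume`, split across reported size fractions by the species' own
#' size-accumulation curve.
#'
#' @param name species name.
#' @param T_opt thermal optimum at the reference year, degrees C.
#' @param T_sd thermal niche breadth (Gaussian SD), degrees C.
#' @param depth_mode,depth_sd depth habitat centre and breadth, m.
#' @param base_concentration individuals per m^3 (>= 100 um basis) at the
#'   niche centre.
#' @param trend_pct_per_decade signed percent abundance change per decade.
#' @param poleward_speed_km_yr injected poleward range speed, km per year.
#' @param deepening_m_per_decade injected habitat deepening, m per decade.
#' @param province,trophic,spinose taxonomy attributes.
#' @param f_max,S_half per-species size-accumulation parameters.
#' @return one-row tibble.
#' @export
species_scenario <- function(name, T_opt, T_sd = 1.5, depth_mode = 40,
                             depth_sd = 25, base_concentration = 2,
                             trend_pct_per_decade = 0,
                             poleward_speed_km_yr = 0,
                             deepening_m_per_decade = 0,
                             province = "subtropical",
                             trophic = "symbiont_bearing", spinose = FALSE,
                             f_max = 3, S_half = 200) {
  stopifnot(T_sd > 0, depth_sd > 0, base_concentration >= 0)
  tibble(name = name, T_opt = T_opt, T_sd = T_sd, depth_mode = depth_mode,
         depth_sd = depth_sd, base_concentration = base_concentration,
         trend_pct_per_decade = trend_pct_per_decade,
         poleward_speed_km_yr = poleward_speed_km_yr,
         deepening_m_per_decade = deepening_m_per_decade,
         province = province, trophic = trophic, spinose = spinose,
         f_max = f_max, S_half = S_half)
}

#' The default nine-species recovery set
#'
#' Three thermally specialized low-latitude species with injected poleward
#' speeds 0, 5 and 10 km/yr; three mid-latitude species with injected
#' deepening 0, 5 and 12.5 m per decade (about 0, 20 and 50 m between the
#' median sampling years of the two periods around a 1997 cutoff, which sit
#' roughly four decades apart); three species with injected declines of 0,
#' -4.03 and -7.04 percent per decade (0, 25 and 40 percent over the seven
#' decade steps from the 1940s to the 2010s).
#'
#' @return tibble of [species_scenario()] rows.
#' @export
default_species_set <- function() {
  dplyr::bind_rows(
    species_scenario("speed_0", T_opt = 16, poleward_speed_km_yr = 0),
    species_scenario("speed_5", T_opt = 15, poleward_speed_km_yr = 5),
    species_scenario("speed_10", T_opt = 14, poleward_speed_km_yr = 10),
    species_scenario("deep_0", T_opt = 12, T_sd = 3, depth_mode = 30,
                     depth_sd = 20, deepening_m_per_decade = 0,
                     trophic = "symbiont_barren"),
    species_scenario("deep_20", T_opt = 12, T_sd = 3, depth_mode = 30,
                     depth_sd = 20, deepening_m_per_decade = 5,
                     trophic = "symbiont_barren"),
    species_scenario("deep_50", T_opt = 12, T_sd = 3, depth_mode = 30,
                     depth_sd = 20, deepening_m_per_decade = 12.5,
                     trophic = "symbiont_barren"),
    species_scenario("decline_0", T_opt = 10, T_sd = 3,
                     trend_pct_per_decade = 0, province = "temperate"),
    species_scenario("decline_25", T_opt = 10, T_sd = 3,
                     trend_pct_per_decade = -4.026, province = "temperate"),
    species_scenario("decline_40", T_opt = 10, T_sd = 3,
                     trend_pct_per_decade = -7.043, province = "temperate")
  )
}

#' World scenario for the synthetic survey
#'
#' Defaults describe an idealized North Atlantic sector small enough for
#' minutes-scale tests: 1-degree fields from 5 to 70 degrees N, monthly
#' resolution, eight depth levels to 300 m, 16 multinet profiles per year
#' from 1940 to 2018 with eight 25-m depth intervals to 200 m, half sampled
#' with a 100 um mesh reported in two sieve fractions and half with a 150 um
#' mesh.  The deep seasonal-mean mixed layer (100 m) keeps the upper-ocean
#' temperature depth-uniform, so the latitudinal range edge is equally sharp
#' in every near-surface interval.
#'
#' @param years sampled period `c(first, last)`.
#' @param lat_range,lon_range station ranges, degrees.
#' @param depth_intervals 2-column matrix of profile depth intervals (m).
#' @param profiles_per_year stations per year up to `effort_change_year`.
#' @param profiles_per_year_late stations per year from `effort_change_year`
#'   on (survey effort grew strongly in the recent decades of the real
#'   censuses); `NULL` keeps `profiles_per_year`.
#' @param effort_change_year year at which the sampling effort changes.
#' @param months sampled months (spring-summer biased by default).
#' @param volume_m3 filtered volume per aliquot.
#' @param T_eq equator surface temperature at the reference year, degrees C.
#' @param T_grad meridional surface gradient, degrees C per degree latitude.
#' @param dT_depth total mixed-layer-to-deep cooling, degrees C.
#' @param mld mixed-layer depth, m (temperature depth-uniform above it).
#' @param z_scale e-folding depth of the thermocline below the mixed layer, m.
#' @param warming_rate surface warming, degrees C per decade (uniform in
#'   depth by construction).
#' @param seasonal_amp,seasonal_z seasonal amplitude (degrees C) and its
#'   e-folding depth (m).
#' @param omega_eq,omega_grad,omega_trend,omega_depth calcite saturation
#'   state: equatorial surface value, decline per degree latitude, per
#'   decade, and per metre depth.
#' @param satcalc0,satcalc_depth saturation carbonate-ion concentration
#'   (umol/kg) at the surface and its increase per metre.
#' @param reference_year epoch `t0` of all linear drifts.
#' @param seed integer seed; a fixed seed makes every generated table
#'   bit-identical.
#' @return object of class `world_scenario` (a list).
#' @export
world_scenario <- function(years = c(1940, 2018), lat_range = c(10, 65),
                           lon_range = c(-40, -10),
                           depth_intervals = cbind(seq(0, 175, by = 25),
                                                   seq(25, 200, by = 25)),
                           profiles_per_year = 16,
                           profiles_per_year_late = 36,
                           effort_change_year = 1990, months = 4:9,
                           volume_m3 = 50,
                           T_eq = 28, T_grad = 0.45, dT_depth = 15,
                           mld = 100, z_scale = 120, warming_rate = 0.15,
                           seasonal_amp = 0.75, seasonal_z = 75,
                           omega_eq = 5.5, omega_grad = 0.035,
                           omega_trend = -0.1, omega_depth = -0.004,
                           satcalc0 = 42, satcalc_depth = 0.01,
                           reference_year = 1940, seed = 1) {
  structure(
    list(years = years, lat_range = lat_range, lon_range = lon_range,
         depth_intervals = depth_intervals,
         profiles_per_year = profiles_per_year,
         profiles_per_year_late = profiles_per_year_late %||% profiles_per_year,
         effort_change_year = effort_change_year, months = months,
         volume_m3 = volume_m3, T_eq = T_eq, T_grad = T_grad,
         dT_depth = dT_depth, mld = mld, z_scale = z_scale,
         warming_rate = warming_rate,
         seasonal_amp = seasonal_amp, seasonal_z = seasonal_z,
         omega_eq = omega_eq, omega_grad = omega_grad,
         omega_trend = omega_trend, omega_depth = omega_depth,
         satcalc0 = satcalc0, satcalc_depth = satcalc_depth,
         reference_year = reference_year, seed = seed),
    class = "world_scenario"
  )
}

#' Analytic environmental functions of a world scenario
#'
#' @param world a [world_scenario()].
#' @return list of functions `temperature`, `omega`, `co3satcalc`, `co3`,
#'   each `function(lat, lon, depth, time)` with `time` in decimal years.
#' @export
env_functions <- function(world) {
  w <- world
  temperature <- function(lat, lon, depth, time) {
    frac <- time - floor(time)
    below <- pmax(depth - w$mld, 0)
    w$T_eq - w$T_grad * abs(lat) -
      w$dT_depth * (1 - exp(-below / w$z_scale)) +
      w$warming_rate * (time - w$reference_year) / 10 +
      w$seasonal_amp * exp(-below / w$seasonal_z) *
        cos(2 * pi * (frac - 0.625)) * sign(lat + 1e-12)
  }
  omega <- function(lat, lon, depth, time) {
    w$omega_eq - w$omega_grad * abs(lat) +
      w$omega_trend * (time - w$reference_year) / 10 +
      w$omega_depth * depth
  }
  co3satcalc <- function(lat, lon, depth, time) {
    w$satcalc0 + w$satcalc_depth * depth + 0 * lat
  }
  co3 <- function(lat, lon, depth, time) {
    omega(lat, lon, depth, time) * co3satcalc(lat, lon, depth, time)
  }
  list(temperature = temperature, omega = omega, co3satcalc = co3satcalc,
       co3 = co3)
}

#' Generate gridded environmental fields from a world scenario
#'
#' Evaluates the analytic fields on a regular grid.  `time_step = "monthly"`
#' gives month-centre time axes (the default); `"annual"` gives one mid-year
#' slice per year.  The same scenario functions extend smoothly beyond the
#' sampled period, so passing future years yields the scenario fields.
#'
#' @param world a [world_scenario()].
#' @param years integer years for the time axis; defaults to the sampled
#'   period.
#' @param time_step `"monthly"` or `"annual"`.
#' @param lat_step,lon_step grid steps in degrees.
#' @param depths depth axis in metres.
#' @return named list of `gridded_field`s: `temperature`, `co3`,
#'   `co3satcalc`, `omega_calcite`.
#' @export
generate_environment <- function(world, years = NULL,
                                 time_step = c("monthly", "annual"),
                                 lat_step = 1, lon_step = 15,
                                 depths = c(0, 25, 50, 75, 100, 150, 200,
                                            300)) {
  time_step <- match.arg(time_step)
  years <- years %||% seq(world$years[1], world$years[2])
  time <- if (time_step == "monthly") {
    as.vector(outer(1:12, years, function(m, y) month_centre(y, m)))
  } else {
    years + 0.5
  }
  time <- sort(time)
  lat <- seq(world$lat_range[1] - 5, world$lat_range[2] + 5, by = lat_step)
  lon <- seq(world$lon_range[1] - 5, world$lon_range[2] + 5, by = lon_step)
  f <- env_functions(world)
  list(
    temperature = field_from_function(f$temperature, "temperature_degC",
                                      lat, lon, depths, time),
    co3 = field_from_function(f$co3, "co3", lat, lon, depths, time),
    co3satcalc = field_from_function(f$co3satcalc, "co3satcalc",
                                     lat, lon, depths, time),
    omega_calcite = field_from_function(f$omega, "omega_calcite",
                                        lat, lon, depths, time)
  )
}

# Expected concentration (>= 100 um basis) of each species at sampling
# points; `pts` needs lat, depth_mid, t (decimal years).  Returns a matrix
# points x species.
expected_concentration <- function(world, species, lat, depth_mid, t) {
  f <- env_functions(world)
  T_local <- f$temperature(lat, NA, depth_mid, t)
  el <- t - world$reference_year
  sapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    T_opt_eff <- s$T_opt + world$warming_rate * el / 10 -
      world$T_grad * (s$poleward_speed_km_yr / KM_PER_DEG_LAT) * el
    mode_eff <- s$depth_mode + s$deepening_m_per_decade * el / 10
    s$base_concentration *
      exp(-((T_local - T_opt_eff)^2) / (2 * s$T_sd^2)) *
      exp(-((depth_mid - mode_eff)^2) / (2 * s$depth_sd^2)) *
      (1 + s$trend_pct_per_decade / 100)^(el / 10)
  })
}

#' Generate a synthetic census survey with known ground truth
#'
#' Stations are drawn uniformly over the sector and sampled as multinet
#' profiles; every depth-interval aliquot is counted for every species with
#' Poisson noise.  Stations alternate between a 100 um mesh whose catch is
#' reported as two sieve fractions (100-150 um and >= 150 um, split
#' multinomially by the species' size-accumulation curve, conserving the
#' total count exactly) and a 150 um mesh reporting the single open fraction
#' >= 150 um (sub-150 um individuals pass through the mesh).
#'
#' @param world a [world_scenario()].
#' @param species tibble of [species_scenario()] rows.
#' @return list: `census` (canonical long tibble as from [read_census()])
#'   and `truth` (the injected parameters per species).
#' @export
generate_survey <- function(world, species = default_species_set()) {
  set.seed(world$seed)
  years <- seq(world$years[1], world$years[2])
  per_year <- ifelse(years < world$effort_change_year,
                     world$profiles_per_year, world$profiles_per_year_late)
  n_prof <- sum(per_year)

  stations <- tibble(
    station = seq_len(n_prof),
    year = rep(years, times = per_year),
    month = sample(world$months, n_prof, replace = TRUE),
    latitude = runif(n_prof, world$lat_range[1], world$lat_range[2]),
    longitude = runif(n_prof, world$lon_range[1], world$lon_range[2]),
    mesh = rep_len(c(100, 150), n_prof)
  )
  stations$date <- as.Date(sprintf("%d-%02d-15", stations$year,
                                   stations$month))

  iv <- world$depth_intervals
  aliquots <- tidyr::crossing(stations, tibble(depth_upper = iv[, 1],
                                               depth_lower = iv[, 2])) |>
    dplyr::mutate(
      depth_mid = (.data$depth_upper + .data$depth_lower) / 2,
      t = month_centre(.data$year, .data$month),
      sample_id = sprintf("S%05d_%03d", .data$station, .data$depth_upper)
    )

  lambda <- expected_concentration(world, species, aliquots$latitude,
                                   aliquots$depth_mid, aliquots$t) *
    world$volume_m3

  rows <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    s <- species[i, ]
    m <- size_norm_model(s$f_max, s$S_half, 100, 100)
    p150 <- (s$f_max - size_factor(150, m)) / (s$f_max - size_factor(100, m))
    N <- rpois(nrow(aliquots), lambda[, i])
    split_mesh <- aliquots$mesh == 100
    n_coarse <- integer(length(N))
    n_coarse[split_mesh] <- rbinom(sum(split_mesh), N[split_mesh], p150)
    # 150 um mesh: sub-150 individuals pass through (physical thinning)
    n_coarse[!split_mesh] <- rbinom(sum(!split_mesh), N[!split_mesh], p150)
    fine <- aliquots[split_mesh, ] |>
      dplyr::mutate(species = s$name,
                    value = N[split_mesh] - n_coarse[split_mesh],
                    size_lower = 100, size_upper = 150)
    coarse <- aliquots |>
      dplyr::mutate(species = s$name, value = n_coarse,
                    size_lower = 150, size_upper = NA_real_)
    rows[[i]] <- dplyr::bind_rows(fine, coarse)
  }

  census <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      subsample_id = sprintf("%s_f%d", .data$sample_id, .data$size_lower),
      device = "net",
      volume_filtered = world$volume_m3,
      count_kind = "raw_count",
      season = assign_season(.data$latitude, .data$date)
    ) |>
    dplyr::select(dplyr::all_of(CENSUS_META_COLS), "species", "value",
                  "year", "month", "season") |>
    dplyr::arrange(.data$subsample_id, .data$species)

  list(census = census, truth = species)
}

#' Generate a pre-industrial sediment presence/absence table
#'
#' Presence of a species at a site is declared when its expected
#' concentration at the reference (pre-industrial) year, averaged over the
#' upper 200 m and the calendar year, exceeds `threshold`.
#'
#' @param world a [world_scenario()].
#' @param species tibble of [species_scenario()] rows.
#' @param year reference year, default 1900.
#' @param threshold detection threshold, individuals per m^3.
#' @param lat_step,lon_step site spacing in degrees.
#' @return long tibble `site_id`, `latitude`, `longitude`, `species`,
#'   `present`.
#' @export
generate_sediment <- function(world, species = default_species_set(),
                              year = 1900, threshold = 0.05, lat_step = 2,
                              lon_step = 10) {
  sites <- tidyr::crossing(
    latitude = seq(world$lat_range[1], world$lat_range[2], by = lat_step),
    longitude = seq(world$lon_range[1], world$lon_range[2], by = lon_step)
  ) |>
    dplyr::mutate(site_id = sprintf("SED%04d", dplyr::row_number()))

  depths <- seq(10, 190, by = 20)
  months <- 1:12
  grid <- tidyr::crossing(sites, depth_mid = depths, month = months) |>
    dplyr::mutate(t = month_centre(year, .data$month))
  lambda <- expected_concentration(world, species, grid$latitude,
                                   grid$depth_mid, grid$t)
  out <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    g <- grid
    g$conc <- lambda[, i]
    out[[i]] <- g |>
      dplyr::summarise(mean_conc = mean(.data$conc),
                       .by = c("site_id", "latitude", "longitude")) |>
      dplyr::mutate(species = species$name[i],
                    present = as.integer(.data$mean_conc > threshold)) |>
      dplyr::select(-"mean_conc")
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$site_id, .data$species)
}
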