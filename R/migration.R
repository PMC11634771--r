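# Lateral range-edge shifts (poleward migration speed) and vertical
# habitat-depth shifts (depth of maximum abundance before/after a cutoff
# year).

shift_estimate <- function(species, metric, value_before = NA_real_,
                           value_after = NA_real_, delta = NA_real_,
                           speed_km_per_yr = NA_real_, n_before = 0L,
                           n_after = 0L, p_value = NA_real_,
                           classification = "insufficient_data") {
  tibble(species = species, metric = metric, value_before = value_before,
         value_after = value_after, delta = delta,
         speed_km_per_yr = speed_km_per_yr, n_before = as.integer(n_before),
         n_after = as.integer(n_after), p_value = p_value,
         classification = classification)
}

# Occurrence records of one species: concentration > 0 after the standard
# depth/season filters.
occurrences <- function(records, species, depth_range, seasons) {
  conc <- if ("concentration" %in% names(records)) records$concentration else records$value
  d <- records[records$species == species & !is.na(conc) & conc > 0, ,
               drop = FALSE]
  filter_records(d, depth_range = depth_range, seasons = seasons)
}

#' Poleward range edge of a species
#'
#' The "maximum latitude of the northernmost 5% of samples" statistic, read
#' as a high quantile (default the 95th percentile, linear-interpolation
#' convention) of the species' occurrence latitudes; occurrences are records
#' with concentration > 0 in the chosen depth window and seasons.
#' `method = "max"` gives the literal maximum latitude of the top tail
#' instead (the overall maximum occurrence latitude), which is
#' noise-dominated and not the default.
#'
#' @param records harmonized census tibble (long; `concentration` or `value`).
#' @param species species name.
#' @param quantile quantile level, default 0.95.
#' @param depth_range depth window, default `c(0, 100)` m.
#' @param seasons default spring + summer.
#' @param n_min minimum occurrences (default 20); fewer returns `NA`.
#' @param method `"quantile"` or `"max"`.
#' @return latitude in degrees north (clipped to 90), or `NA` with attribute
#'   `"n"` giving the occurrence count either way.
#' @export
northern_edge <- function(records, species, quantile = 0.95,
                          depth_range = c(0, 100),
                          seasons = c("spring", "summer"), n_min = 20,
                          method = c("quantile", "max")) {
  method <- match.arg(method)
  occ <- suppressWarnings(occurrences(records, species, depth_range, seasons))
  n <- nrow(occ)
  if (n < n_min) {
    return(structure(NA_real_, n = n))
  }
  edge <- if (method == "max") {
    max(occ$latitude)
  } else {
    unname(quantile(occ$latitude, quantile, type = 7))
  }
  structure(min(edge, 90), n = n)
}

#' Poleward shift of a species' range edge across a cutoff year
#'
#' Compares the range edge (see [northern_edge()]) before and after
#' `cutoff_year`; `delta` is in degrees latitude converted to km at 111.32
#' km/degree, and the speed divides by the difference between the median
#' sampling years of the occurrences in the two periods.  Positive values are
#' poleward (northward) shifts.
#'
#' @inheritParams northern_edge
#' @param cutoff_year records with `year < cutoff_year` form the "before"
#'   period; default 1990.
#' @return one-row tibble (a ShiftEstimate): `value_before`/`value_after` are
#'   edge latitudes, `delta` is km, `speed_km_per_yr` km per year.
#' @export
poleward_shift <- function(records, species, cutoff_year = 1990,
                           quantile = 0.95, depth_range = c(0, 100),
                           seasons = c("spring", "summer"), n_min = 20,
                           method = c("quantile", "max")) {
  method <- match.arg(method)
  before <- records[records$year < cutoff_year, , drop = FALSE]
  after <- records[records$year >= cutoff_year, , drop = FALSE]
  e_b <- northern_edge(before, species, quantile, depth_range, seasons, n_min,
                       method)
  e_a <- northern_edge(after, species, quantile, depth_range, seasons, n_min,
                       method)
  n_b <- attr(e_b, "n")
  n_a <- attr(e_a, "n")
  if (is.na(e_b) || is.na(e_a)) {
    return(shift_estimate(species, "northern_edge_deg", n_before = n_b,
                          n_after = n_a))
  }
  occ_b <- suppressWarnings(occurrences(before, species, depth_range, seasons))
  occ_a <- suppressWarnings(occurrences(after, species, depth_range, seasons))
  dt <- median(occ_a$year) - median(occ_b$year)
  delta_km <- (as.numeric(e_a) - as.numeric(e_b)) * KM_PER_DEG_LAT
  shift_estimate(
    species, "northern_edge_deg",
    value_before = as.numeric(e_b), value_after = as.numeric(e_a),
    delta = delta_km,
    speed_km_per_yr = if (dt > 0) delta_km / dt else NA_real_,
    n_before = n_b, n_after = n_a,
    classification = "not_significant"
  )
}

#' Depth of maximum abundance per profile
#'
#' For each valid profile (>= `min_members` distinct depth intervals, all
#' within the upper `depth_limit` metres, non-overlapping) and species, the
#' midpoint of the depth interval with the highest concentration.  Ties go to
#' the shallowest such interval; a species absent from every interval yields
#' no row.
#'
#' @param records harmonized census tibble carrying `profile_id` (see
#'   [group_profiles()]) and `concentration`.
#' @param species species name(s); `NULL` for all.
#' @param min_members minimum distinct depth intervals per profile (default 4).
#' @param depth_limit maximum `depth_lower` of the profile (default 200 m).
#' @return tibble `profile_id`, `species`, `latitude`, `year`,
#'   `depth_of_max`.
#' @export
depth_of_max_abundance <- function(records, species = NULL, min_members = 4,
                                   depth_limit = 200) {
  if (!("profile_id" %in% names(records))) {
    foram_abort("depth_of_max_abundance() requires group_profiles() first",
                "foramshift_profile_error")
  }
  d <- records
  if (!is.null(species)) d <- d[d$species %in% species, , drop = FALSE]
  d <- d[!is.na(d$concentration) &
           d$profile_n >= min_members &
           d$profile_depth_max <= depth_limit &
           d$profile_valid, , drop = FALSE]
  empty <- tibble(profile_id = character(), species = character(),
                  latitude = numeric(), year = integer(),
                  depth_of_max = numeric())
  if (nrow(d) == 0) return(empty)
  d$depth_mid <- (d$depth_upper + d$depth_lower) / 2
  per_interval <- d |>
    dplyr::summarise(concentration = sum(.data$concentration),
                     .by = c("profile_id", "species", "latitude", "year",
                             "depth_mid")) |>
    dplyr::filter(.data$concentration > 0)
  if (nrow(per_interval) == 0) return(empty)
  per_interval |>
    dplyr::arrange(.data$depth_mid) |>
    dplyr::summarise(
      depth_of_max = .data$depth_mid[which.max(.data$concentration)],
      .by = c("profile_id", "species", "latitude", "year")
    )
}

#' One-way fixed-effects ANOVA between two groups
#'
#' The two-group case is equivalent to a two-sided pooled t-test
#' (`F = t^2`).  Degenerate inputs (fewer than 2 values per group, or zero
#' pooled within-group variance) return `NA`s with classification handled by
#' the callers.
#'
#' @param group_a,group_b numeric vectors.
#' @return one-row tibble `F`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n <- length(group_a) + length(group_b)
  empty <- tibble(F = NA_real_, df_between = NA_integer_,
                  df_within = NA_integer_, p_value = NA_real_)
  if (length(group_a) < 2 || length(group_b) < 2) return(empty)
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                   sum((group_b - mean(group_b))^2)) / (n - 2)
  if (pooled_var <= 0) return(empty)
  fit <- oneway.test(values ~ grp,
                     data = data.frame(values = c(group_a, group_b),
                                       grp = rep(c("a", "b"),
                                                 c(length(group_a),
                                                   length(group_b)))),
                     var.equal = TRUE)
  tibble(F = unname(fit$statistic),
         df_between = as.integer(fit$parameter[["num df"]]),
         df_within = as.integer(fit$parameter[["denom df"]]),
         p_value = unname(fit$p.value))
}

#' Vertical habitat-depth shift of a species across a cutoff year
#'
#' Compares per-profile depths of maximum abundance (see
#' [depth_of_max_abundance()]) before and after `cutoff_year` with a two-sided
#' one-way ANOVA.  `delta = mean_after - mean_before` in metres; positive is
#' deepening.  Classification: `significant_deepening` when `p < alpha` and
#' `delta > 0`, `significant_shallowing` when `p < alpha` and `delta < 0`,
#' else `not_significant`; fewer than 2 valid profiles in either period (or a
#' degenerate ANOVA) gives `insufficient_data`.
#'
#' @param records harmonized, profile-grouped census tibble.
#' @param species species name.
#' @param cutoff_year default 1997 (multinet era).
#' @param alpha significance level, default 0.05.
#' @param seasons,depth_limit,min_members profile selection defaults: spring +
#'   summer, upper 200 m, >= 4 depth intervals.
#' @param devices devices to keep, default `"net"`.
#' @return one-row tibble (a ShiftEstimate) with `metric = "depth_of_max_m"`.
#' @export
vertical_shift_test <- function(records, species, cutoff_year = 1997,
                                alpha = 0.05,
                                seasons = c("spring", "summer"),
                                depth_limit = 200, min_members = 4,
                                devices = "net") {
  d <- suppressWarnings(
    filter_records(records, seasons = seasons, devices = devices)
  )
  dma <- depth_of_max_abundance(d, species, min_members = min_members,
                                depth_limit = depth_limit)
  before <- dma$depth_of_max[dma$year < cutoff_year]
  after <- dma$depth_of_max[dma$year >= cutoff_year]
  av <- one_way_anova(before, after)
  if (is.na(av$p_value)) {
    return(shift_estimate(species, "depth_of_max_m",
                          n_before = length(before), n_after = length(after)))
  }
  delta <- mean(after) - mean(before)
  cls <- if (av$p_value < alpha && delta > 0) {
    "significant_deepening"
  } else if (av$p_value < alpha && delta < 0) {
    "significant_shallowing"
  } else {
    "not_significant"
  }
  shift_estimate(species, "depth_of_max_m",
                 value_before = mean(before), value_after = mean(after),
                 delta = delta, n_before = length(before),
                 n_after = length(after), p_value = av$p_value,
                 classification = cls)
}
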