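# The core parameter-recovery experiment: generate replicate surveys with
# injected ground truth, run the full pipeline (harmonize -> profiles ->
# environment -> estimators) on each, and compare the replicate-averaged
# estimates with the injected values.  Also the null (zero-effect)
# simulations that calibrate the test families.

# One replicate: all estimators on one survey.
recovery_replicate <- function(world, species, with_thermal = TRUE) {
  survey <- generate_survey(world, species)
  harmonized <- harmonize_table(survey$census)
  grouped <- group_profiles(harmonized)
  truth <- survey$truth
  rows <- list()

  for (i in which(grepl("^speed", truth$name))) {
    sp <- truth$name[i]
    est <- poleward_shift(grouped, sp, cutoff_year = 1990)
    rows[[length(rows) + 1]] <- tibble(
      component = "poleward_speed_km_yr", species = sp,
      injected = truth$poleward_speed_km_yr[i],
      expected = truth$poleward_speed_km_yr[i],
      estimate = est$speed_km_per_yr, p_value = NA_real_,
      classification = est$classification, n = est$n_before + est$n_after
    )
  }

  for (i in which(grepl("^deep", truth$name))) {
    sp <- truth$name[i]
    est <- vertical_shift_test(grouped, sp, cutoff_year = 1997)
    dma <- depth_of_max_abundance(
      suppressWarnings(filter_records(grouped, seasons = c("spring", "summer"),
                                      devices = "net")), sp
    )
    dt_dec <- (median(dma$year[dma$year >= 1997]) -
                 median(dma$year[dma$year < 1997])) / 10
    rows[[length(rows) + 1]] <- tibble(
      component = "deepening_m", species = sp,
      injected = truth$deepening_m_per_decade[i],
      expected = truth$deepening_m_per_decade[i] * dt_dec,
      estimate = est$delta, p_value = est$p_value,
      classification = est$classification, n = est$n_before + est$n_after
    )
  }

  for (i in which(grepl("^decline", truth$name))) {
    sp <- truth$name[i]
    # the decline species' province band, as the band-wise analysis would use
    series <- decadal_series(harmonized, sp, band = c(30, 50),
                             depth_range = c(0, 200))
    tt <- trend_test(series)
    n_steps <- (max(series$decade) - min(series$decade)) / 10
    r <- 1 + truth$trend_pct_per_decade[i] / 100
    rows[[length(rows) + 1]] <- tibble(
      component = "decline_pct", species = sp,
      injected = -truth$trend_pct_per_decade[i],
      expected = (1 - r^n_steps) * 100,
      estimate = tt$percent_change, p_value = tt$p_value,
      classification = tt$classification, n = sum(series$n)
    )
  }

  if (with_thermal) {
    fields <- generate_environment(world)
    with_env <- attach_environment(harmonized, fields["temperature"])
    for (i in which(truth$poleward_speed_km_yr == 0)) {
      sp <- truth$name[i]
      resp <- thermal_response(with_env, sp, bin = 1, period = "all")
      peak <- resp$temp_bin[which.max(resp$value)]
      occ <- with_env[with_env$species == sp & with_env$concentration > 0 &
                        with_env$depth_lower <= 100, , drop = FALSE]
      drift <- world$warming_rate * (mean(occ$year) - world$reference_year) / 10
      rows[[length(rows) + 1]] <- tibble(
        component = "T_opt_degC", species = sp,
        injected = truth$T_opt[i], expected = truth$T_opt[i] + drift,
        estimate = peak, p_value = NA_real_, classification = NA_character_,
        n = nrow(occ)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the parameter-recovery experiment
#'
#' Generates `n_rep` replicate synthetic surveys, runs the full pipeline on
#' each (harmonize, group profiles, attach the generated temperature field),
#' and recovers, averaged over replicates: poleward range speeds (vs injected
#' 0/5/10 km/yr), habitat deepening between period median years (vs the
#' injected rate times the elapsed decades), percent decline over the fitted
#' decades (vs the injected per-decade trend compounded), and thermal optima
#' from 1-degree-bin thermal responses (vs the injected optimum advanced by
#' the warming accrued up to the occurrences' mean sampling year; computed on
#' the first replicate only — the binned peak is stable at survey size).
#'
#' @param seed integer seed; replicate r uses `seed * 100 + r`.
#' @param world a [world_scenario()] (its seed is overridden per replicate).
#' @param species tibble of [species_scenario()] rows.
#' @param n_rep number of replicate surveys, default 6.
#' @return tibble with one row per recovered quantity: `component`,
#'   `species`, `injected`, `expected` (injected value mapped to the
#'   estimator's time base, replicate mean), `estimate` (replicate mean),
#'   `p_value` (first replicate), `classification` (modal across
#'   replicates), `n` (mean), `n_rep`; per-replicate rows in attribute
#'   `"replicates"`.
#' @export
run_recovery_experiment <- function(seed = 1, world = world_scenario(),
                                    species = default_species_set(),
                                    n_rep = 6) {
  reps <- lapply(seq_len(n_rep), function(r) {
    world$seed <- seed * 100 + r
    recovery_replicate(world, species, with_thermal = (r == 1)) |>
      dplyr::mutate(rep = r)
  })
  all <- dplyr::bind_rows(reps)
  modal <- function(x) names(which.max(table(x)))[1]
  out <- all |>
    dplyr::summarise(
      injected = dplyr::first(.data$injected),
      expected = mean(.data$expected),
      estimate = mean(.data$estimate),
      p_value = dplyr::first(.data$p_value),
      classification = if (all(is.na(.data$classification))) NA_character_
                       else modal(.data$classification),
      n = mean(.data$n),
      n_rep = dplyr::n(),
      .by = c("component", "species")
    )
  attr(out, "replicates") <- all
  out
}

#' Build a decadal series from decade means
#'
#' Constructor used by null simulations and tests to exercise [trend_test()]
#' on externally supplied decade means.
#'
#' @param decade numeric decade labels (1940, 1950, ...).
#' @param mean_raw mean concentration per decade.
#' @param species label stored on the series.
#' @return a `decadal_series` tibble.
#' @export
as_decadal_series <- function(decade, mean_raw, species = NA_character_) {
  d <- tibble(decade = decade, n = NA_integer_, mean_raw = mean_raw,
              sd_raw = NA_real_) |>
    dplyr::arrange(decade)
  d$value <- min_max(d$mean_raw)
  structure(d, species = species, degenerate = all(is.na(d$value)),
            class = c("decadal_series", class(d)))
}

#' Type-I error rates of the test families under zero effect
#'
#' Simulates zero-effect data for the two significance-test families — the
#' two-period depth-shift ANOVA and the decadal trend regression — and
#' reports the rate of significant classifications at `alpha`, which should
#' sit within sampling error of `alpha`.
#'
#' @param n_rep replicates per family.
#' @param alpha significance level.
#' @param n_profiles per-period profile count for the ANOVA family.
#' @param seed integer seed.
#' @return list: `anova_rate`, `trend_rate`, `anova_p` (the null p-values,
#'   usable for a uniformity check), `n_rep`.
#' @export
type_one_error_rates <- function(n_rep = 1000, alpha = 0.05, n_profiles = 15,
                                 seed = 1) {
  set.seed(seed)
  anova_p <- vapply(seq_len(n_rep), function(i) {
    one_way_anova(rnorm(n_profiles, 50, 15),
                  rnorm(n_profiles, 50, 15))$p_value
  }, numeric(1))
  trend_sig <- vapply(seq_len(n_rep), function(i) {
    s <- as_decadal_series(seq(1940, 2010, by = 10), 1 + rnorm(8, 0, 0.15))
    tt <- trend_test(s, alpha = alpha)
    tt$classification %in% c("significant_decrease", "significant_increase")
  }, logical(1))
  list(anova_rate = mean(anova_p < alpha), trend_rate = mean(trend_sig),
       anova_p = anova_p, n_rep = n_rep)
}
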