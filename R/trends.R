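# Decadal abundance trends per species and latitudinal band, latitudinal
# abundance sections, thermal-response curves on 1-degree temperature bins,
# and PCoA-based clustering of species by their thermal responses.

# Mean concentration of one species across every aliquot in scope, zero-filled
# for aliquots where the species was counted absent of it.
species_means <- function(records, species, by_col) {
  units <- records |>
    dplyr::distinct(.data$subsample_id, .keep_all = TRUE) |>
    dplyr::select("subsample_id", dplyr::all_of(by_col))
  sp <- records[records$species == species,
                c("subsample_id", "concentration"), drop = FALSE]
  units |>
    dplyr::left_join(sp, by = "subsample_id") |>
    dplyr::mutate(concentration = ifelse(is.na(.data$concentration), 0,
                                         .data$concentration))
}

#' Decadal abundance series of a species in a latitudinal band
#'
#' Mean concentration per calendar decade (half-open `[1940, 1950)`, ...)
#' across all records in the band/depth window, then min-max normalized to
#' `[0, 1]` across the populated decades.  Decades with no data are absent
#' (not zero).  A constant (degenerate) series keeps its raw means but gets
#' all-`NA` normalized values and a `degenerate` flag, to avoid fabricating
#' trends; fewer than 2 populated decades raises an insufficient-data error.
#'
#' @param records harmonized census tibble (with `concentration`).
#' @param species species name.
#' @param band latitude band `c(lo, hi)`; defaults follow the North Atlantic
#'   provinces (0-30, 30-50, 50-90 degrees N).
#' @param depth_range depth window, default `c(0, 200)` m.
#' @param start_decade first decade considered, default 1940.
#' @param devices default net + pump.
#' @return tibble of class `decadal_series`: `decade`, `n`, `mean_raw`,
#'   `sd_raw`, `value` (normalized); attributes `species`, `band`,
#'   `degenerate`.
#' @export
decadal_series <- function(records, species, band = c(0, 30),
                           depth_range = c(0, 200), start_decade = 1940,
                           devices = c("net", "pump")) {
  d <- suppressWarnings(
    filter_records(records, depth_range = depth_range, lat_band = band,
                   devices = devices)
  )
  d <- d[d$year >= start_decade, , drop = FALSE]
  per_decade <- species_means(d, species, "year") |>
    dplyr::mutate(decade = decade_of(.data$year)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_raw = mean(.data$concentration),
      sd_raw = sd(.data$concentration),
      .by = "decade"
    ) |>
    dplyr::arrange(.data$decade)
  if (nrow(per_decade) < 2) {
    foram_abort("decadal_series(): fewer than 2 populated decades",
                "foramshift_insufficient_data")
  }
  per_decade$value <- min_max(per_decade$mean_raw)
  degenerate <- all(is.na(per_decade$value))
  if (degenerate) {
    rlang::warn("decadal_series(): constant decade means; normalized values set to NA")
  }
  structure(per_decade, species = species, band = band,
            degenerate = degenerate,
            class = c("decadal_series", class(per_decade)))
}

#' Trend test on a decadal abundance series
#'
#' Ordinary least-squares regression of the decadal means on the decade index
#' (decades since the first populated decade), with the p-value from the
#' regression ANOVA (F test of the slope).  The reported `slope` and
#' `p_value` come from the normalized series (min-max normalization is
#' linear, so p is identical to the raw-mean fit); `percent_change` is the
#' percent decline over the fitted period computed from the raw-mean fit,
#' `(fitted_first - fitted_last) / fitted_first * 100` — positive when
#' abundance declined.  Classification: `significant_decrease` /
#' `significant_increase` when `p < alpha` by slope sign, else
#' `not_significant`; degenerate series give `insufficient_data`.
#'
#' @param series a [decadal_series()].
#' @param alpha significance level, default 0.05.
#' @return one-row tibble `species`, `slope` (normalized units per decade),
#'   `p_value`, `percent_change`, `n_decades`, `classification`.
#' @export
trend_test <- function(series, alpha = 0.05) {
  species <- attr(series, "species") %||% NA_character_
  res <- tibble(species = species, slope = NA_real_, p_value = NA_real_,
                percent_change = NA_real_, n_decades = nrow(series),
                classification = "insufficient_data")
  if (isTRUE(attr(series, "degenerate")) || nrow(series) < 3) return(res)

  idx <- (series$decade - min(series$decade)) / 10
  fit_norm <- lm(series$value ~ idx)
  av <- anova(fit_norm)
  p <- av$`Pr(>F)`[1]
  slope <- unname(coef(fit_norm)[2])

  fit_raw <- lm(series$mean_raw ~ idx)
  f_first <- unname(predict(fit_raw,
                            data.frame(idx = min(idx))))
  f_last <- unname(predict(fit_raw, data.frame(idx = max(idx))))
  pc <- if (f_first > 0) (f_first - f_last) / f_first * 100 else NA_real_

  cls <- if (!is.na(p) && p < alpha && slope < 0) {
    "significant_decrease"
  } else if (!is.na(p) && p < alpha && slope > 0) {
    "significant_increase"
  } else {
    "not_significant"
  }
  tibble(species = species, slope = slope, p_value = p, percent_change = pc,
         n_decades = nrow(series), classification = cls)
}

#' Latitudinal abundance section of a species
#'
#' Mean concentration per 10-degree latitude bin, separately for the surface
#' layer (0 to `depth_split` m) and the deeper layer (below `depth_split`),
#' restricted to spring/summer records since `since`.
#'
#' @param records harmonized census tibble.
#' @param species species name.
#' @param depth_split metres separating the two layers, default 100.
#' @param bin latitude bin width, default 10 degrees.
#' @param since first sampling year, default 1980.
#' @param seasons default spring + summer.
#' @return tibble `bin_lo`, `layer` (`"surface"`/`"deep"`), `mean_conc`, `n`.
#' @export
latitudinal_section <- function(records, species, depth_split = 100, bin = 10,
                                since = 1980,
                                seasons = c("spring", "summer")) {
  d <- suppressWarnings(filter_records(records, seasons = seasons))
  d <- d[d$year >= since, , drop = FALSE]
  d$layer <- ifelse(d$depth_upper < depth_split, "surface", "deep")
  sp <- species
  species_means(d, sp, c("latitude", "layer")) |>
    dplyr::mutate(bin_lo = bin * floor(.data$latitude / bin)) |>
    dplyr::summarise(mean_conc = mean(.data$concentration), n = dplyr::n(),
                     .by = c("bin_lo", "layer")) |>
    dplyr::arrange(.data$bin_lo, .data$layer)
}

#' Thermal response of a species on 1-degree temperature bins
#'
#' Mean concentration per in-situ temperature bin (records must carry a
#' `temperature` column, see [attach_environment()]), min-max normalized to
#' `[0, 1]` per species and period.  The record set is restricted to the
#' upper `depth_max` metres; `period` splits at `cutoff_year`.
#'
#' @param records harmonized census tibble with `temperature`.
#' @param species species name.
#' @param bin temperature bin width in degrees C, default 1.
#' @param period `"all"`, `"before"` or `"after"` the cutoff.
#' @param cutoff_year period split, default 1990.
#' @param depth_max maximum `depth_lower`, default 100 m.
#' @return tibble `temp_bin` (bin centre), `n`, `mean_raw`, `value`
#'   (normalized); all-zero species are flagged via attribute `all_zero`.
#' @export
thermal_response <- function(records, species, bin = 1,
                             period = c("all", "before", "after"),
                             cutoff_year = 1990, depth_max = 100) {
  period <- match.arg(period)
  d <- suppressWarnings(filter_records(records, depth_range = c(0, depth_max)))
  d <- d[!is.na(d$temperature), , drop = FALSE]
  if (period == "before") d <- d[d$year < cutoff_year, , drop = FALSE]
  if (period == "after") d <- d[d$year >= cutoff_year, , drop = FALSE]
  out <- species_means(d, species, "temperature") |>
    dplyr::mutate(temp_bin = bin * floor(.data$temperature / bin) + bin / 2) |>
    dplyr::summarise(n = dplyr::n(), mean_raw = mean(.data$concentration),
                     .by = "temp_bin") |>
    dplyr::arrange(.data$temp_bin)
  all_zero <- all(out$mean_raw == 0)
  out$value <- if (all_zero) rep(NA_real_, nrow(out)) else
    if (nrow(out) == 1) 1 else min_max(out$mean_raw)
  if (all_zero) rlang::warn("thermal_response(): species absent everywhere")
  structure(out, species = species, period = period, all_zero = all_zero)
}

#' Cluster species by their thermal-response shapes
#'
#' Principal-coordinate analysis on the Euclidean inter-species distances of
#' the response matrix (equivalent to PCA of the centred matrix), retaining
#' the first `n_components` coordinate scores; agglomerative clustering
#' (average linkage by default) on the Euclidean distances between score
#' vectors, cut at `k` clusters.  Reports the variance explained by each
#' retained component.
#'
#' @param mat numeric matrix, species x temperature bin, normalized
#'   abundances; align bins across species beforehand (missing bins as 0).
#' @param n_components number of principal coordinates retained, default 2.
#' @param k number of clusters, `1 <= k <= nrow(mat)`.
#' @param linkage hclust agglomeration method, default `"average"`.
#' @return list: `labels` (named cluster assignment), `scores`
#'   (species x component), `var_explained` (fraction per retained
#'   component), `tree` (the hclust object).
#' @export
assemblage_clustering <- function(mat, n_components = 2, k = 2,
                                  linkage = "average") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) {
    foram_abort("assemblage_clustering() needs at least 3 species",
                "foramshift_parameter_error")
  }
  if (k > nrow(mat) || k < 1) {
    foram_abort("k must be between 1 and the number of species",
                "foramshift_parameter_error")
  }
  pco <- cmdscale(dist(mat), k = min(n_components, nrow(mat) - 1), eig = TRUE)
  scores <- pco$points
  pos <- pco$eig[pco$eig > 0]
  var_explained <- pco$eig[seq_len(ncol(scores))] / sum(pos)
  tree <- hclust(dist(scores), method = linkage)
  labels <- cutree(tree, k = k)
  names(labels) <- rownames(mat)
  list(labels = labels, scores = scores, var_explained = var_explained,
       tree = tree)
}

#' Assemble the species x temperature-bin response matrix
#'
#' Convenience wrapper running [thermal_response()] for each species and
#' aligning the bins (missing bins filled with 0).
#'
#' @inheritParams thermal_response
#' @param species character vector of species names.
#' @return numeric matrix, species x bin centres.
#' @export
thermal_response_matrix <- function(records, species, bin = 1,
                                    period = c("all", "before", "after"),
                                    cutoff_year = 1990, depth_max = 100) {
  period <- match.arg(period)
  resp <- lapply(species, function(sp) {
    r <- thermal_response(records, sp, bin, period, cutoff_year, depth_max)
    setNames(r$value, r$temp_bin)
  })
  bins <- sort(unique(as.numeric(unlist(lapply(resp, names)))))
  mat <- matrix(0, nrow = length(species), ncol = length(bins),
                dimnames = list(species, bins))
  for (i in seq_along(resp)) {
    v <- resp[[i]]
    v[is.na(v)] <- 0
    mat[i, names(v)] <- v
  }
  mat
}
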