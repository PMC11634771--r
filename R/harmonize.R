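# Size-normalized catch model: makes catches taken with different mesh /
# sieve windows comparable by expressing every concentration as the
# concentration of individuals >= a common normalization size (default
# 100 um), i.e. as if everything had been sampled with a 100 um net.
#
# The model is a saturating size-accumulation curve: f(S) is the
# multiplication factor accumulated up to the upper bound S of a size class,
#
#   f(S) = 1 + (f_max - 1) * (S - S_sup1) / ((S - S_sup1) + (S_half - S_sup1))
#
# rising from 1 at the upper limit of the first size class (S_sup1) towards
# the asymptote f_max, with half-saturation at S_half.  A measured
# concentration C in the size window [sz_inf, sz_sup) converts to the
# >= sz_norm concentration as
#
#   C_norm = C * (f_max - f(sz_norm)) / (f(sz_sup) - f(sz_inf)).

#' Size-normalized catch model parameters
#'
#' `f_max` and `S_half` are species- and application-specific fitted
#' constants; the defaults here (`f_max = 3`, `S_half = 200`) are synthetic
#' values used by the package's simulator and tests, and real analyses should
#' supply fitted values.
#'
#' @param f_max dimensionless asymptotic multiplication factor, > 1.
#' @param S_half um; size at which f reaches the midpoint between 1 and f_max.
#' @param S_sup1 um; upper limit of the first size class, 0 < S_sup1 < S_half.
#' @param sz_norm um; normalization size (100 um = "as sampled by a 100 um
#'   net").
#' @return an object of class `size_norm_model`.
#' @export
size_norm_model <- function(f_max = 3, S_half = 200, S_sup1 = 100,
                            sz_norm = 100) {
  if (!(f_max > 1)) foram_abort("f_max must be > 1", "foramshift_model_error")
  if (!(S_half > S_sup1 && S_sup1 > 0)) {
    foram_abort("requires S_half > S_sup1 > 0", "foramshift_model_error")
  }
  if (!(sz_norm > 0)) foram_abort("sz_norm must be > 0", "foramshift_model_error")
  structure(list(f_max = f_max, S_half = S_half, S_sup1 = S_sup1,
                 sz_norm = sz_norm),
            class = "size_norm_model")
}

#' @export
print.size_norm_model <- function(x, ...) {
  cat("Size-normalized catch model: f_max =", x$f_max,
      ", S_half =", x$S_half, "um, S_sup1 =", x$S_sup1,
      "um, sz_norm =", x$sz_norm, "um\n")
  invisible(x)
}

#' Multiplication factor f(S) of the size-normalized catch model
#'
#' Strictly increasing in `S` on `[S_sup1, Inf)`, with `f(S_sup1) = 1`,
#' `f(S_half) = (1 + f_max) / 2` and `f -> f_max` as `S -> Inf`.  `NA` or
#' `Inf` encode the OPEN (unbounded) upper fraction and give `f_max`.
#'
#' @param S size in um, vectorized; `NA`/`Inf` = OPEN.
#' @param model a [size_norm_model()].
#' @return factor values in `[1, f_max]`.
#' @export
size_factor <- function(S, model = size_norm_model()) {
  open <- is.na(S) | is.infinite(S)
  if (any(S[!open] < model$S_sup1)) {
    foram_abort("size_factor() undefined below S_sup1 (first size-class bound)",
                "foramshift_domain_error")
  }
  d <- S - model$S_sup1
  f <- 1 + (model$f_max - 1) * d / (d + (model$S_half - model$S_sup1))
  f[open] <- model$f_max
  f
}

#' Normalize a measured concentration to the >= sz_norm size basis
#'
#' @param concentration individuals per m^3 in the measured fraction,
#'   vectorized.
#' @param sz_inf,sz_sup lower/upper size limits of the measured fraction (um);
#'   `sz_sup = NA`/`Inf` for the OPEN top fraction.
#' @param model a [size_norm_model()].
#' @return concentration of individuals >= `sz_norm`, per m^3.
#' @export
normalize_concentration <- function(concentration, sz_inf, sz_sup,
                                    model = size_norm_model()) {
  f_inf <- size_factor(sz_inf, model)
  f_sup <- size_factor(sz_sup, model)
  denom <- f_sup - f_inf
  if (any(denom <= 0)) {
    foram_abort("degenerate size fraction: f(sz_sup) must exceed f(sz_inf)",
                "foramshift_degenerate_fraction")
  }
  concentration * (model$f_max - size_factor(model$sz_norm, model)) / denom
}

#' Convert a raw count to a concentration
#'
#' @param count individuals, >= 0.
#' @param volume_filtered m^3, > 0.
#' @return individuals per m^3.
#' @export
to_concentration <- function(count, volume_filtered) {
  if (any(is.na(volume_filtered)) || any(volume_filtered <= 0)) {
    foram_abort("volume_filtered must be present and > 0",
                "foramshift_unit_error")
  }
  count / volume_filtered
}

#' Harmonize a census table to concentrations at a common size basis
#'
#' Converts raw counts to concentrations (rows with `count_kind =
#' "raw_count"` but no usable volume are excluded and collected), merges the
#' sieve fractions of one aliquot (same `sample_id` and depth interval) into a
#' single effective fraction spanning their union, and size-normalizes every
#' concentration to the >= `sz_norm` basis.  Merging before normalizing is
#' what makes split sieve fractions consistent with a whole catch: summing
#' measured concentrations over adjacent windows telescopes the factor
#' differences, `(f_b - f_a) + (f_max - f_b) = f_max - f_a`.
#'
#' Provenance of each output row is recorded in `harmonization`:
#' \describe{
#'   \item{normalized}{size-normalized to the `sz_norm` basis.}
#'   \item{raw}{already a concentration on the target basis (fraction starts
#'     at `sz_norm` with an OPEN top) — values unchanged.}
#'   \item{not_quantifiable}{fraction lies wholly below `sz_norm`
#'     (small/rare-species domain, never extrapolated); `concentration` is NA.}
#'   \item{below_model_domain}{fraction starts below the model's first size
#'     class bound, where f is undefined; `concentration` is NA.}
#' }
#'
#' @param records long census tibble.
#' @param model a [size_norm_model()], the global default.
#' @param per_species optional named list of [size_norm_model()]s overriding
#'   the global model for individual species (the model is fitted per species
#'   in practice).
#' @param merge_fractions merge sieve fractions of an aliquot before
#'   normalizing (default TRUE).
#' @return tibble with one row per (aliquot, species): subsample metadata
#'   (`subsample_id` of the first merged fraction kept), `concentration`
#'   (individuals per m^3 at >= `sz_norm`) and `harmonization`; excluded rows
#'   in attribute `"excluded"`.
#' @export
harmonize_table <- function(records, model = size_norm_model(),
                            per_species = NULL, merge_fractions = TRUE) {
  if (!is.null(per_species)) {
    parts <- split(records, records$species %in% names(per_species))
    out <- list()
    if (!is.null(parts$`FALSE`)) {
      out[[1]] <- harmonize_table(parts$`FALSE`, model,
                                  merge_fractions = merge_fractions)
    }
    if (!is.null(parts$`TRUE`)) {
      by_sp <- split(parts$`TRUE`, parts$`TRUE`$species)
      out <- c(out, lapply(names(by_sp), function(sp) {
        harmonize_table(by_sp[[sp]], per_species[[sp]],
                        merge_fractions = merge_fractions)
      }))
    }
    res <- dplyr::bind_rows(out)
    attr(res, "excluded") <- dplyr::bind_rows(lapply(out, attr, "excluded"))
    return(res)
  }
  recs <- records
  # raw counts -> concentrations; collect rows without usable volume
  is_raw <- recs$count_kind == "raw_count"
  no_vol <- is_raw & (is.na(recs$volume_filtered) | recs$volume_filtered <= 0)
  excluded <- recs[no_vol, , drop = FALSE] |>
    dplyr::mutate(reason = "raw count without usable volume_filtered")
  recs <- recs[!no_vol, , drop = FALSE]
  recs$concentration <- ifelse(recs$count_kind == "raw_count",
                               recs$value / recs$volume_filtered, recs$value)

  if (merge_fractions && nrow(recs) > 0) {
    # one aliquot = one sample x depth interval; its (adjacent) sieve
    # fractions merge into a single effective fraction spanning their union
    key <- paste(recs$sample_id, recs$depth_upper, recs$depth_lower,
                 recs$species, sep = "\r")
    ord <- order(key, recs$size_lower)
    recs <- recs[ord, , drop = FALSE]
    key <- key[ord]
    firsts <- !duplicated(key)
    lasts <- !duplicated(key, fromLast = TRUE)
    merged <- recs[firsts, , drop = FALSE]
    merged$size_upper <- recs$size_upper[lasts]
    merged$concentration <- unname(rowsum(recs$concentration, key,
                                          reorder = FALSE)[, 1])
    recs <- merged
  }

  open_top <- is.na(recs$size_upper)
  below_norm <- !open_top & recs$size_upper <= model$sz_norm
  below_domain <- !below_norm & recs$size_lower < model$S_sup1
  identity_rows <- !below_norm & !below_domain &
    recs$size_lower == model$sz_norm & open_top
  to_norm <- !below_norm & !below_domain & !identity_rows

  recs$harmonization <- dplyr::case_when(
    below_norm ~ "not_quantifiable",
    below_domain ~ "below_model_domain",
    identity_rows ~ "raw",
    TRUE ~ "normalized"
  )
  recs$concentration[below_norm | below_domain] <- NA_real_
  if (any(to_norm)) {
    recs$concentration[to_norm] <- normalize_concentration(
      recs$concentration[to_norm], recs$size_lower[to_norm],
      recs$size_upper[to_norm], model
    )
  }
  attr(recs, "excluded") <- excluded
  recs
}
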