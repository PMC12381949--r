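# Reference ("national") incidence and mortality rate tables.
#
# A rate table is a long-format data.table with one row per
# (attained-age band, calendar year, deprivation fifth, cancer type) cell,
# plus an all-cause mortality pseudo-type "death" used only by the simulator.
# Rates are annual, per woman-year.

#' Construct and validate a reference rate table
#'
#' Wraps a long-format table of annual incidence rates (per woman-year) into a
#' validated `rate_table` object. The grid must be complete: every combination
#' of age band, calendar year and deprivation fifth must be present for every
#' cancer type, so that any stratum queried during follow-up resolves.
#'
#' @param x data.frame with columns `age_band_start`, `year`, `imd_fifth`,
#'   `cancer_type`, `rate`.
#' @param band_width width of the attained-age bands in years (default 5).
#' @return A `rate_table` (a keyed data.table with attributes `band_width`,
#'   `age_range`, `years`, `fifths`, `cancer_types`).
#' @export
rate_table <- function(x, band_width = 5) {
  dt <- data.table::as.data.table(x)
  need <- c("age_band_start", "year", "imd_fifth", "cancer_type", "rate")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("rate table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyNA(dt$rate) || any(!is.finite(dt$rate)) || any(dt$rate < 0)) {
    stop("rate table contains missing, non-finite or negative rates")
  }
  bands <- sort(unique(dt$age_band_start))
  years <- sort(unique(dt$year))
  fifths <- sort(unique(dt$imd_fifth))
  types <- sort(unique(dt$cancer_type))
  full <- data.table::CJ(age_band_start = bands, year = years,
                         imd_fifth = fifths, cancer_type = types)
  if (nrow(dt) != nrow(full) ||
      nrow(dt[full, on = names(full), nomatch = NULL]) != nrow(full)) {
    missing_cells <- dt[full, on = names(full)][is.na(rate)]
    if (nrow(missing_cells)) {
      ex <- missing_cells[1]
      stop(sprintf(
        "incomplete rate grid: %d missing cells, e.g. (age_band_start=%s, year=%s, imd_fifth=%s, cancer_type=%s)",
        nrow(missing_cells), ex$age_band_start, ex$year, ex$imd_fifth,
        ex$cancer_type))
    }
    stop("rate table has duplicated cells")
  }
  if (length(bands) > 1 && !all(diff(bands) == band_width)) {
    stop("age_band_start values are not spaced by band_width = ", band_width)
  }
  data.table::setkeyv(dt, c("cancer_type", "age_band_start", "year", "imd_fifth"))
  data.table::setattr(dt, "band_width", band_width)
  data.table::setattr(dt, "age_range", c(min(bands), max(bands) + band_width))
  data.table::setattr(dt, "years", years)
  data.table::setattr(dt, "fifths", fifths)
  data.table::setattr(dt, "cancer_types", setdiff(types, "death"))
  data.table::setattr(dt, "class", c("rate_table", class(dt)))
  dt[]
}

#' Generate a synthetic reference rate table
#'
#' Stand-in for a national incidence-rate table stratified by attained-age band
#' x calendar year x deprivation fifth x cancer type, plus all-cause mortality
#' ("death") used by the cohort simulator. The baseline shape is log-linear in
#' attained age (rate doubles every `age_doubling` years, evaluated at band
#' midpoints relative to age `ref_age`), with an optional multiplicative
#' deprivation gradient per fifth step and an optional log-linear calendar
#' trend. Deterministic given its arguments; optional lognormal cell noise is
#' controlled by `noise_sd` and `seed`.
#'
#' @param age_range two ages; bands of `band_width` years cover
#'   `[age_range[1], age_range[2])`. Must span at least 20-85 for cohort
#'   follow-up to age 85.
#' @param band_width age band width in years.
#' @param years calendar years covered (diagnosis and follow-up span).
#' @param fifths deprivation fifths (1 = least deprived).
#' @param base_rate named vector of annual rates per woman-year at
#'   `ref_age`, middle fifth, first year; names are the cancer-type groups.
#' @param death_rate annual all-cause mortality rate at `ref_age`.
#' @param age_doubling named vector (or scalar recycled) of ages over which
#'   each type's rate doubles; `Inf` gives an age-flat rate.
#' @param death_age_doubling doubling age for the mortality rate.
#' @param deprivation_gradient multiplicative factor per fifth step
#'   (applied as `gradient^(fifth - 3)`).
#' @param year_trend multiplicative factor per calendar year.
#' @param ref_age age at which `base_rate` applies.
#' @param noise_sd sd of lognormal cell-level noise (0 = none).
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @return A [rate_table()].
#' @export
make_reference_rates <- function(age_range = c(20, 85),
                                 band_width = 5,
                                 years = 1993:2021,
                                 fifths = 1:5,
                                 base_rate = c(breast = 24e-4, lung = 7e-4,
                                               uterus = 3.5e-4,
                                               leukaemia = 0.6e-4,
                                               other = 35e-4),
                                 death_rate = 60e-4,
                                 age_doubling = 14,
                                 death_age_doubling = 8,
                                 deprivation_gradient = 1.04,
                                 year_trend = 1.0,
                                 ref_age = 62.5,
                                 noise_sd = 0,
                                 seed = NULL) {
  if (diff(age_range) <= 0 || (diff(age_range) %% band_width) != 0) {
    stop("age_range must be a positive span divisible by band_width")
  }
  types <- names(base_rate)
  if (is.null(types) || any(!nzchar(types))) {
    stop("base_rate must be a named vector of cancer-type groups")
  }
  if ("death" %in% types) stop("'death' is reserved for the mortality rate")
  if (length(age_doubling) == 1) {
    age_doubling <- stats::setNames(rep(age_doubling, length(types)), types)
  }
  bands <- seq(age_range[1], age_range[2] - band_width, by = band_width)
  grid <- data.table::CJ(age_band_start = bands, year = years,
                         imd_fifth = fifths,
                         cancer_type = c(types, "death"))
  mid <- grid$age_band_start + band_width / 2
  base <- c(base_rate, death = unname(death_rate))
  dbl <- c(age_doubling, death = unname(death_age_doubling))
  grid[, rate := base[cancer_type] *
         2 ^ ((mid - ref_age) / dbl[cancer_type]) *
         deprivation_gradient ^ (imd_fifth - 3L) *
         year_trend ^ (year - min(years))]
  if (noise_sd > 0) {
    with_seed(seed, {
      grid[, rate := rate * stats::rlnorm(.N, -noise_sd^2 / 2, noise_sd)]
    })
  }
  rate_table(grid, band_width = band_width)
}

# Fast lookup structure: a dense array indexed by
# (band index, year index, fifth index, cause index), NA where no cell exists.
# Access through this object errors with the missing cell named.
rate_lookup <- function(rates, causes = NULL) {
  stopifnot(inherits(rates, "rate_table"))
  bw <- attr(rates, "band_width")
  bands <- sort(unique(rates$age_band_start))
  years <- attr(rates, "years")
  fifths <- attr(rates, "fifths")
  if (is.null(causes)) causes <- sort(unique(rates$cancer_type))
  arr <- array(NA_real_,
               dim = c(length(bands), length(years), length(fifths),
                       length(causes)))
  sub <- rates[cancer_type %in% causes]
  arr[cbind(match(sub$age_band_start, bands), match(sub$year, years),
            match(sub$imd_fifth, fifths), match(sub$cancer_type, causes))] <-
    sub$rate
  list(arr = arr, band0 = bands[1], band_width = bw, n_bands = length(bands),
       year0 = years[1], n_years = length(years), fifths = fifths,
       causes = causes)
}

# Vectorised rate query; age/year are continuous attained age and calendar
# time, mapped to cells with half-open [start, end) convention.
rate_query <- function(lk, age, year, fifth, cause_idx) {
  eps <- 1e-9
  bi <- floor((age - lk$band0 + eps) / lk$band_width) + 1L
  yi <- floor(year + eps) - lk$year0 + 1L
  fi <- match(fifth, lk$fifths)
  bad <- bi < 1L | bi > lk$n_bands | yi < 1L | yi > lk$n_years | is.na(fi)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "rate table cell not found: attained age %.2f (band), year %d, fifth %s, cause '%s'",
      age[i], floor(year[i] + eps), as.character(fifth[i]),
      lk$causes[cause_idx[i]]))
  }
  r <- lk$arr[cbind(bi, yi, fi, cause_idx)]
  if (anyNA(r)) {
    i <- which(is.na(r))[1]
    stop(sprintf(
      "rate table cell missing: age_band_start=%d, year=%d, imd_fifth=%s, cancer_type='%s'",
      lk$band0 + (bi[i] - 1L) * lk$band_width, lk$year0 + yi[i] - 1L,
      as.character(fifth[i]), lk$causes[cause_idx[i]]))
  }
  r
}

# Evaluate an expression with a temporary RNG state seeded by `seed`
# (NULL = use current stream). Restores .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
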