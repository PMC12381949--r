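# Standardised incidence ratios and absolute excess rates.
#
# Observed counts are treated as Poisson with the expected counts fixed, so
# confidence limits come from the exact (Garwood) Poisson interval for the
# Poisson mean, via chi-square quantiles, divided by E (or transformed to the
# excess-rate scale with E and PY held fixed).

# exact Poisson interval for the mean given an observed count
poisson_ci <- function(o, level = 0.95) {
  alpha <- 1 - level
  lo <- ifelse(o == 0, 0, stats::qchisq(alpha / 2, 2 * o) / 2)
  hi <- stats::qchisq(1 - alpha / 2, 2 * (o + 1)) / 2
  cbind(lo = lo, hi = hi)
}

#' Standardised incidence ratio with exact Poisson interval
#'
#' Point estimate O/E with Garwood (chi-square) exact limits for the Poisson
#' mean of O divided by the fixed expected count E. `O = 0` gives a lower
#' bound of exactly 0.
#'
#' @param O observed event count (non-negative integer, vectorised).
#' @param E expected event count (> 0).
#' @param level confidence level.
#' @return data.table: `O`, `E`, `sir`, `sir_lo`, `sir_hi`, `level`.
#' @export
sir_with_ci <- function(O, E, level = 0.95) {
  if (any(E <= 0)) stop("E must be > 0")
  if (any(O < 0) || any(O != round(O))) {
    stop("O must be a non-negative integer count")
  }
  ci <- poisson_ci(O, level)
  data.table::data.table(O = O, E = E, sir = O / E,
                         sir_lo = ci[, "lo"] / E, sir_hi = ci[, "hi"] / E,
                         level = level)
}

#' Absolute excess rate with exact Poisson interval
#'
#' `(O - E) / PY`, scaled (default per 10 000 woman-years). The interval is
#' the exact Poisson interval for O transformed with E and PY fixed, so the
#' AER interval excludes 0 exactly when the SIR interval excludes 1.
#'
#' @param O observed count; `E` expected count; `PY` woman-years (> 0).
#' @param scale person-time scale of the reported rate.
#' @param level confidence level.
#' @return data.table: `O`, `E`, `PY`, `aer`, `aer_lo`, `aer_hi`, `level`.
#' @export
aer_with_ci <- function(O, E, PY, scale = 1e4, level = 0.95) {
  if (any(PY <= 0)) stop("PY must be > 0")
  if (any(E <= 0)) stop("E must be > 0")
  ci <- poisson_ci(O, level)
  data.table::data.table(O = O, E = E, PY = PY,
                         aer = (O - E) / PY * scale,
                         aer_lo = (ci[, "lo"] - E) / PY * scale,
                         aer_hi = (ci[, "hi"] - E) / PY * scale,
                         level = level)
}

#' Share of the total excess attributable to one component
#'
#' `aer_a / (aer_a + aer_b)`: e.g. the proportion of the overall excess of
#' second cancers attributable to contralateral breast cancer when `aer_a`
#' is the contralateral and `aer_b` the non-breast absolute excess rate.
#'
#' @param aer_a,aer_b absolute excess rates on a common scale.
#' @return The proportion (scalar in \[0, 1\] when both rates are >= 0).
#' @export
excess_share <- function(aer_a, aer_b) {
  if (aer_a + aer_b == 0) stop("zero denominator: aer_a + aer_b = 0")
  aer_a / (aer_a + aer_b)
}

#' SIR and AER analysis for one or more cancer-type groups
#'
#' Runs [tally()] per target type, sums (O, E, PY) over strata and reports
#' the standardised incidence ratio and absolute excess rate with exact
#' intervals.
#'
#' @param x a `cohort` (post-eligibility).
#' @param rates a [rate_table()].
#' @param targets character vector of cancer-type groups; each becomes one
#'   [analysis_spec()] row (target `"breast"` = contralateral analysis with
#'   halved reference rates).
#' @param band_width attained-age band width.
#' @param level confidence level.
#' @param mode `"first"` or `"anytime"` event selection.
#' @return data.table, one row per target: `cancer_type`, `O`, `E`, `PY`,
#'   `sir`, `sir_lo`, `sir_hi`, `aer`, `aer_lo`, `aer_hi`, `level`.
#' @export
sir_analysis <- function(x, rates, targets, band_width = 5, level = 0.95,
                         mode = "first") {
  res <- lapply(targets, function(tg) {
    sp <- analysis_spec(tg, mode = mode)
    tl <- collapse_tally(tally(x, sp, rates, band_width))
    s <- sir_with_ci(tl$o, tl$e, level)
    a <- aer_with_ci(tl$o, tl$e, tl$py, level = level)
    data.table::data.table(cancer_type = tg, O = tl$o, E = tl$e, PY = tl$py,
                           sir = s$sir, sir_lo = s$sir_lo, sir_hi = s$sir_hi,
                           aer = a$aer, aer_lo = a$aer_lo, aer_hi = a$aer_hi,
                           level = level)
  })
  data.table::rbindlist(res)
}
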