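# Observed and expected cumulative risk of a second cancer under competing
# events, on annual time windows since cohort entry (diagnosis + 3 months).
#
# Two-step estimator: for window w let n(w) be the number at risk at the
# window start, d(w) the target-cause events and c(w) the competing events
# (any other qualifying second cancer, or death) during the window. Then
#   p(w)   = d(w) / n*(w)
#   S(1)   = 1;  S(w+1) = S(w) * (1 - (d(w) + c(w)) / n*(w))
#   R(t)   = sum_{w <= t} S(w) * p(w)
# with n*(w) the within-window-censoring-adjusted size (actuarial: half a
# unit per woman censored in the window; configurable off).
#
# The expected curve replaces only the target-cause hazard with its
# general-population value: ehat(w) is the person-time-weighted mean
# reference rate of the target cause over the women actually at risk in
# window w (halved breast rates for the contralateral analysis), converted
# to a window probability 1 - exp(-ehat); the competing hazard stays the
# cohort's own. This keeps observed-minus-expected risks consistent with the
# standardised incidence ratio.

# Per-woman per-window at-risk records, with expected-rate person-time.
cif_window_data <- function(x, spec, rates, band_width = 5) {
  iv <- at_risk_intervals(x, spec)
  ivi <- iv[included == TRUE]
  if (nrow(ivi) == 0) stop("no women at risk")
  eps <- 1e-9
  tau <- ivi$exit - ivi$entry
  w_exit <- pmax(1L, as.integer(ceiling(tau - eps)))
  risk <- data.table::data.table(
    id = rep(ivi$id, w_exit),
    window = sequence(w_exit))
  last <- cumsum(w_exit)
  risk[, `:=`(d_target = 0L, d_comp = 0L, cens = 0L)]
  reason <- ivi$reason
  risk[last[reason == "event"], d_target := 1L]
  risk[last[reason %in% c("competing-event", "death")], d_comp := 1L]
  risk[last[reason %in% c("age85", "admin")], cens := 1L]
  ## expected-rate person-time per woman-window
  segs <- lexis_split(iv, x$women, rates, band_width,
                      target = spec$target, halve = spec$halve_reference,
                      window_cuts = TRUE)
  pw <- segs[, .(len = sum(len), ratelen = sum(len * rate)),
             by = .(id, window)]
  risk <- pw[risk, on = c("id", "window")]
  risk[is.na(len), `:=`(len = 0, ratelen = 0)]
  data.table::setorder(risk, id, window)
  structure(list(risk = risk, n_women = nrow(ivi), target = spec$target,
                 spec = spec),
            class = "cif_window_data")
}

# Aggregate window tallies, optionally with per-woman resampling weights
# (a vector named by woman id); used by the bootstrap.
window_tallies <- function(wd, weights = NULL) {
  r <- wd$risk
  if (is.null(weights)) {
    tal <- r[, .(n = as.numeric(.N), d_target = sum(d_target),
                 d_comp = sum(d_comp), cens = sum(cens),
                 len = sum(len), ratelen = sum(ratelen)),
             by = window]
  } else {
    r2 <- data.table::copy(r)
    r2[, .wt := weights[match(id, as.integer(names(weights)))]]
    tal <- r2[, .(n = sum(.wt), d_target = sum(d_target * .wt),
                  d_comp = sum(d_comp * .wt), cens = sum(cens * .wt),
                  len = sum(len * .wt), ratelen = sum(ratelen * .wt)),
              by = window]
  }
  data.table::setorder(tal, window)
  tal
}

# Two-step curves from window tallies. Returns the tallies with S, p_target,
# R_obs (and e_hat, S_exp, R_exp when expected = TRUE) appended.
two_step_curves <- function(tal, cens_adjust = c("actuarial", "none"),
                            expected = TRUE,
                            expected_survival = c("expected", "observed")) {
  cens_adjust <- match.arg(cens_adjust)
  expected_survival <- match.arg(expected_survival)
  tal <- data.table::copy(tal)
  n_eff <- if (cens_adjust == "actuarial") tal$n - tal$cens / 2 else tal$n
  if (any(n_eff <= 0 & (tal$d_target > 0 | tal$d_comp > 0))) {
    stop("inconsistent window tallies: events in a window with no one at risk")
  }
  safe <- pmax(n_eff, .Machine$double.eps)
  p_t <- ifelse(n_eff > 0, tal$d_target / safe, 0)
  p_c <- ifelse(n_eff > 0, tal$d_comp / safe, 0)
  S <- cumprod(c(1, (1 - p_t - p_c)))[seq_along(p_t)]
  tal[, `:=`(n_eff = n_eff, p_target = p_t, S = S,
             R_obs = cumsum(S * p_t))]
  if (expected) {
    e_hat <- ifelse(tal$len > 0, tal$ratelen / tal$len, 0)
    p_e <- 1 - exp(-e_hat)
    if (expected_survival == "expected") {
      S_exp <- cumprod(c(1, (1 - p_e - p_c)))[seq_along(p_e)]
    } else {
      S_exp <- S
    }
    tal[, `:=`(e_hat = e_hat, S_exp = S_exp, R_exp = cumsum(S_exp * p_e))]
  }
  tal
}

#' Observed cumulative incidence of a second cancer (two-step estimator)
#'
#' @param x a `cohort` (post-eligibility).
#' @param spec an [analysis_spec()] (first-event mode).
#' @param rates a [rate_table()] (needed for the at-risk bookkeeping grid; the
#'   observed curve itself uses only cohort events).
#' @param band_width attained-age band width for the expected-rate lookup.
#' @param cens_adjust within-window censoring handling: `"actuarial"` counts
#'   a woman censored inside a window as half a unit at risk; `"none"` keeps
#'   the full unit (the convention under which the estimator equals the
#'   Aalen-Johansen estimator on window-discretised data).
#' @return data.table per window with `n`, `d_target`, `d_comp`, `cens`,
#'   `p_target`, `S` and the observed cumulative risk `R_obs`.
#' @export
observed_cif <- function(x, spec, rates, band_width = 5,
                         cens_adjust = "actuarial") {
  wd <- cif_window_data(x, spec, rates, band_width)
  two_step_curves(window_tallies(wd), cens_adjust, expected = FALSE)
}

#' Expected cumulative incidence from reference rates under cohort competing risks
#'
#' @inheritParams observed_cif
#' @param expected_survival `"expected"` (default): the expected curve's
#'   survival recursion uses the expected target hazard together with the
#'   cohort's observed competing hazard; `"observed"`: use the fully observed
#'   survival (sensitivity option).
#' @return data.table per window with `e_hat` (person-time-weighted reference
#'   rate), `S_exp` and the expected cumulative risk `R_exp` (alongside the
#'   observed columns).
#' @export
expected_cif <- function(x, spec, rates, band_width = 5,
                         cens_adjust = "actuarial",
                         expected_survival = "expected") {
  wd <- cif_window_data(x, spec, rates, band_width)
  two_step_curves(window_tallies(wd), cens_adjust, expected = TRUE,
                  expected_survival = expected_survival)
}

#' Observed, expected and excess cumulative risk with bootstrap bands
#'
#' One-stop computation of the annual-window cumulative-risk curves and
#' their difference, with optional pointwise percentile confidence bands
#' from a nonparametric bootstrap over women (reference rates treated as
#' fixed).
#'
#' @inheritParams observed_cif
#' @inheritParams expected_cif
#' @param boot number of bootstrap replicates (0 = no bands).
#' @param level band level.
#' @param seed RNG seed for the bootstrap.
#' @return A `cif_curve` data.table: `window`, `n`, `d_target`, `d_comp`,
#'   `cens`, `S`, `p_target`, `e_hat`, `R_obs`, `R_exp`, `excess`, and
#'   `band_lo`/`band_hi` (excess bands) when `boot > 0`.
#' @export
cif_curve <- function(x, spec, rates, band_width = 5,
                      cens_adjust = "actuarial",
                      expected_survival = "expected",
                      boot = 0, level = 0.95, seed = NULL) {
  wd <- cif_window_data(x, spec, rates, band_width)
  cur <- two_step_curves(window_tallies(wd), cens_adjust, TRUE,
                         expected_survival)
  cur[, excess := R_obs - R_exp]
  if (boot > 0) {
    ids <- unique(wd$risk$id)
    nw <- length(ids)
    reps <- with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        cnt <- tabulate(sample.int(nw, nw, replace = TRUE), nbins = nw)
        wts <- stats::setNames(cnt, ids)
        bc <- two_step_curves(window_tallies(wd, wts), cens_adjust, TRUE,
                              expected_survival)
        bc$R_obs - bc$R_exp
      }, numeric(nrow(cur)))
    })
    alpha <- 1 - level
    qs <- apply(reps, 1, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
    cur[, `:=`(band_lo = qs[1, ], band_hi = qs[2, ])]
  }
  data.table::setattr(cur, "spec", wd$spec)
  data.table::setattr(cur, "class", c("cif_curve", class(cur)))
  cur[]
}

#' Excess cumulative risk at a time point
#'
#' @param curve a [cif_curve()] result.
#' @param t time since entry in whole years (must lie on the annual grid).
#' @return list with `excess` (= R_obs(t) - R_exp(t)) and, when the curve
#'   carries bootstrap bands, `lo`/`hi`.
#' @export
excess_risk <- function(curve, t) {
  row <- which(curve$window == t)
  if (length(row) != 1) {
    stop("t = ", t, " is not on the curve's annual grid (1..",
         max(curve$window), ")")
  }
  out <- list(excess = curve$excess[row])
  if ("band_lo" %in% names(curve)) {
    out$lo <- curve$band_lo[row]
    out$hi <- curve$band_hi[row]
  }
  out
}
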