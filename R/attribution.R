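# Attributable fractions and excess-cancer counts for flagged treatment
# associations, summed under trial-consistency scenarios.

#' Attributable fraction in the exposed
#'
#' `(rr - 1) / rr`. Negative for protective associations (rr < 1); always
#' below 1. The inverse relation `rr = 1 / (1 - AF)` holds exactly.
#'
#' @param rr rate ratio(s), > 0.
#' @return Attributable fraction(s).
#' @export
attributable_fraction <- function(rr) {
  if (any(rr <= 0)) stop("rr must be > 0")
  (rr - 1) / rr
}

#' Default trial-consistency lookup for treatment associations
#'
#' Which (exposure, cancer type) associations are supported by randomised
#' trial evidence: radiotherapy with contralateral breast and lung cancer;
#' endocrine therapy with uterine cancer and (protectively) contralateral
#' breast cancer; chemotherapy with acute leukaemias. Supplied as a default
#' configuration; users analysing differently grouped cancer types should
#' provide their own table.
#'
#' @return data.table: `exposure`, `cancer_type`, `trial_consistent`.
#' @export
trial_consistency_default <- function() {
  data.table::data.table(
    exposure = c("radiotherapy", "radiotherapy", "endocrine", "endocrine",
                 "chemotherapy"),
    cancer_type = c("breast", "lung", "uterus", "breast", "leukaemia"),
    trial_consistent = TRUE)
}

#' Excess cancers attributable to treatments, by scenario
#'
#' For every flagged rate-ratio estimate, the per-type excess count is the
#' attributable fraction in the exposed times the observed number of events
#' among exposed women (negative for the protective endocrine-contralateral
#' association). Counts are summed under two scenarios: associations
#' consistent with randomised-trial evidence only, and all flagged
#' associations.
#'
#' @param estimates data.frame of rate-ratio estimates with columns
#'   `cancer_type`, `exposure`, `rr`, `flagged`.
#' @param exposed_counts data.frame with `cancer_type`, `exposure`, `count`:
#'   observed target events among exposed women. Every flagged estimate must
#'   have a count.
#' @param trial_consistency lookup of trial-supported associations (default
#'   [trial_consistency_default()]); pairs absent from the lookup are
#'   treated as not trial-consistent.
#' @param total_second_cancers optional denominator: all second cancers in
#'   the cohort.
#' @param total_population_excess optional denominator: excess count vs the
#'   general population, see [population_excess()].
#' @return An `attribution_result` list: `table` (per flagged association:
#'   `af`, `exposed`, `excess`, `trial_consistent`), `totals` (named vector,
#'   scenarios `trial_consistent` and `all_flagged`), and `proportions`
#'   (scenario totals over each supplied denominator, in percent).
#' @export
excess_counts <- function(estimates, exposed_counts,
                          trial_consistency = trial_consistency_default(),
                          total_second_cancers = NULL,
                          total_population_excess = NULL) {
  est <- data.table::as.data.table(estimates)[flagged == TRUE]
  cnt <- data.table::as.data.table(exposed_counts)
  tc <- data.table::as.data.table(trial_consistency)
  if (nrow(est) == 0) {
    empty <- est[, .(cancer_type, exposure, rr)]
    empty[, `:=`(count = integer(), trial_consistent = logical(),
                 af = numeric(), excess = numeric())]
    return(structure(list(table = empty,
                          totals = c(trial_consistent = 0, all_flagged = 0),
                          proportions = list()),
                     class = "attribution_result"))
  }
  if (nrow(cnt) == 0 || !all(c("cancer_type", "exposure", "count") %in%
                             names(cnt))) {
    stop("missing exposed count for flagged estimate (",
         est$cancer_type[1], ", ", est$exposure[1], ")")
  }
  tab <- cnt[est, on = c("cancer_type", "exposure")]
  if (anyNA(tab$count)) {
    bad <- tab[is.na(count)][1]
    stop(sprintf("missing exposed count for flagged estimate (%s, %s)",
                 bad$cancer_type, bad$exposure))
  }
  tab <- tc[tab, on = c("cancer_type", "exposure")]
  tab[is.na(trial_consistent), trial_consistent := FALSE]
  tab[, af := attributable_fraction(rr)]
  tab[, excess := af * count]
  totals <- c(trial_consistent = sum(tab[trial_consistent == TRUE, excess]),
              all_flagged = sum(tab$excess))
  props <- list()
  if (!is.null(total_second_cancers)) {
    props$of_second_cancers <- 100 * totals / total_second_cancers
  }
  if (!is.null(total_population_excess)) {
    props$of_population_excess <- 100 * totals / total_population_excess
  }
  structure(list(table = tab[], totals = totals, proportions = props),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("Excess second cancers attributable to adjuvant treatments\n")
  print(x$table[, .(cancer_type, exposure, rr, af, exposed = count, excess,
                    trial_consistent)])
  cat(sprintf("Totals: %.0f (trial-consistent) to %.0f (all flagged)\n",
              x$totals["trial_consistent"], x$totals["all_flagged"]))
  for (nm in names(x$proportions)) {
    cat(sprintf("  %s: %.1f%% to %.1f%%\n", nm,
                x$proportions[[nm]]["trial_consistent"],
                x$proportions[[nm]]["all_flagged"]))
  }
  invisible(x)
}

#' Excess cancer count relative to the general population
#'
#' `O_total - E_total`: the number of second cancers beyond those expected
#' under reference rates.
#'
#' @param O_total total observed second cancers (>= 0).
#' @param E_total total expected second cancers (>= 0).
#' @return The (possibly negative) excess count.
#' @export
population_excess <- function(O_total, E_total) {
  if (any(O_total < 0) || any(E_total < 0)) stop("counts must be >= 0")
  O_total - E_total
}
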