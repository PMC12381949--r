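# At-risk intervals, Lexis splitting and stratum tallies.
#
# Follow-up runs from 3 months after diagnosis of the index breast cancer to
# the earliest of the first qualifying second-cancer event, the 85th birthday,
# death, or the administrative censoring date. Person-time is split into
# segments homogeneous in (attained-age band, calendar year, deprivation
# fifth); all stratum intervals are half-open [start, end), so a birthday or
# event falling exactly on a boundary belongs to the later stratum.

#' Analysis specification for one second-cancer outcome
#'
#' @param target cancer-type group under analysis. `"breast"` means
#'   contralateral breast cancer: ipsilateral second breast cancers are never
#'   counted as outcomes (they act as competing events only) and, by default,
#'   second breast cancers of unknown laterality are grouped with
#'   contralateral ones.
#' @param outcome `"invasive"`: non-invasive second cancers are ignored
#'   entirely. `"noninvasive"`: women are censored at any invasive cancer and
#'   the outcome is a non-invasive event of the target type.
#' @param mode `"first"` counts only the first qualifying event and censors
#'   follow-up at any qualifying event (target or competing cancer);
#'   `"anytime"` counts every target event more than three months after
#'   diagnosis, with person-time running to death/85/administrative end (the
#'   sensitivity analysis).
#' @param include_unknown_laterality group unknown-laterality breast events
#'   with contralateral ones (default TRUE).
#' @param halve_reference halve the reference breast-cancer rates when
#'   computing expected counts/risks (only one breast is at risk); defaults
#'   to TRUE for the contralateral analysis.
#' @param entry_offset entry delay after diagnosis in years (3 months).
#' @param age_cap censoring age (85th birthday).
#' @return An `analysis_spec`.
#' @export
analysis_spec <- function(target,
                          outcome = c("invasive", "noninvasive"),
                          mode = c("first", "anytime"),
                          include_unknown_laterality = TRUE,
                          halve_reference = identical(target, "breast"),
                          entry_offset = 0.25,
                          age_cap = 85) {
  stopifnot(is.character(target), length(target) == 1)
  structure(list(target = target, outcome = match.arg(outcome),
                 mode = match.arg(mode),
                 include_unknown_laterality = include_unknown_laterality,
                 halve_reference = isTRUE(halve_reference),
                 entry_offset = entry_offset, age_cap = age_cap),
            class = "analysis_spec")
}

# Role of each recorded event under a spec: "target", "competing" (ends
# at-risk time in first-event mode but is never counted), or "ignored".
classify_events <- function(events, spec) {
  role <- rep("ignored", nrow(events))
  inv <- isTRUE_vec(events$invasive)
  lat <- if ("laterality" %in% names(events)) events$laterality else
    rep(NA_character_, nrow(events))
  is_breast <- events$cancer_type == "breast"
  ipsi <- is_breast & !is.na(lat) & lat == "ipsilateral"
  contra_ok <- is_breast & !is.na(lat) &
    (lat == "contralateral" |
       (spec$include_unknown_laterality & lat == "unknown"))
  if (spec$outcome == "invasive") {
    role[inv] <- "competing"
    if (spec$target == "breast") {
      role[inv & contra_ok] <- "target"
    } else {
      role[inv & events$cancer_type == spec$target] <- "target"
    }
    role[inv & ipsi] <- "competing"  # never an outcome, retained for censoring
  } else {
    role[inv] <- "competing"
    ni <- !inv
    if (spec$target == "breast") {
      role[ni & contra_ok] <- "target"
    } else {
      role[ni & events$cancer_type == spec$target] <- "target"
    }
  }
  role
}

#' Compute at-risk intervals for every woman under an analysis spec
#'
#' @param x a `cohort` (typically post-eligibility).
#' @param spec an [analysis_spec()].
#' @return data.table, one row per woman: `id`, `entry`, `exit` (years since
#'   diagnosis), `reason` (one of `event`, `competing-event`, `death`,
#'   `age85`, `admin`, or an exclusion reason `pre_entry_event` /
#'   `zero_length`), `included` (logical), and `event_time` (the counted
#'   target-event time, first-event mode).
#' @export
at_risk_intervals <- function(x, spec) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "analysis_spec"))
  w <- x$women
  ev <- data.table::copy(x$events)
  entry <- spec$entry_offset
  t85 <- spec$age_cap - w$age_dx
  death <- ifelse(is.na(w$death_time), Inf, w$death_time)
  admin <- w$fu_end
  out <- data.table::data.table(id = w$id, entry = entry,
                                exit = NA_real_, reason = NA_character_,
                                included = FALSE, event_time = NA_real_)
  ev[, role := classify_events(ev, spec)]
  rel <- ev[role != "ignored"]
  if (spec$mode == "first") {
    pre <- rel[time <= entry, unique(id)]
    firsts <- rel[!(id %in% pre)][, .SD[which.min(time)], by = id]
    out[w$id %in% pre, reason := "pre_entry_event"]
    # candidate exits in tie-priority order: event, death, age85, admin
    cand <- data.table::data.table(
      id = w$id,
      t_evt = Inf, r_evt = NA_character_,
      t_death = death, t_85 = t85, t_admin = admin)
    if (nrow(firsts)) {
      m <- match(firsts$id, cand$id)
      cand$t_evt[m] <- firsts$time
      cand$r_evt[m] <- ifelse(firsts$role == "target", "event",
                              "competing-event")
    }
    exits <- cbind(cand$t_evt, cand$t_death, cand$t_85, cand$t_admin)
    j <- max.col(-exits, ties.method = "first")
    exit_v <- exits[cbind(seq_len(nrow(exits)), j)]
    reason_v <- cbind(cand$r_evt, "death", "age85", "admin")[
      cbind(seq_len(nrow(exits)), j)]
    keep <- is.na(out$reason)  # not pre-entry
    out[, `:=`(exit = ifelse(keep, exit_v, exit),
               reason = ifelse(keep, reason_v, reason))]
    out[keep & exit <= entry, `:=`(reason = "zero_length", exit = NA_real_)]
    out[, included := !is.na(exit)]
    out[included == TRUE & reason == "event", event_time := exit]
  } else {
    exits <- cbind(death, t85, admin)
    j <- max.col(-exits, ties.method = "first")
    exit_v <- exits[cbind(seq_len(nrow(exits)), j)]
    reason_v <- c("death", "age85", "admin")[j]
    out[, `:=`(exit = exit_v, reason = reason_v)]
    out[exit <= entry, `:=`(reason = "zero_length", exit = NA_real_)]
    out[, included := !is.na(exit)]
  }
  data.table::setattr(out, "spec", spec)
  out[]
}

#' At-risk interval for a single woman
#'
#' Convenience wrapper around [at_risk_intervals()].
#'
#' @param x a `cohort`; `id` the woman's id; `spec` an [analysis_spec()].
#' @return One-row data.table (see [at_risk_intervals()]), or a row with
#'   `included = FALSE` and the exclusion reason.
#' @export
at_risk_interval <- function(x, id, spec) {
  iv <- at_risk_intervals(x, spec)
  iv[iv$id == id]
}

# Vectorised Lexis point generation: boundary crossing times of a linear
# clock `origin + t` at multiples of `width`, strictly inside (entry, exit).
boundary_cuts <- function(origin, entry, exit, width) {
  eps <- 1e-9
  v1 <- origin + entry
  v2 <- origin + exit
  m1 <- floor(v1 / width + eps) + 1
  m2 <- ceiling(v2 / width - eps) - 1
  cnt <- pmax(0L, as.integer(m2 - m1 + 1))
  idx <- rep(seq_along(origin), cnt)
  t_cut <- (rep(m1, cnt) + sequence(cnt) - 1) * width - origin[idx]
  list(idx = idx, t = t_cut)
}

#' Split at-risk intervals into Lexis segments with expected rates
#'
#' Partitions each included interval at every attained-age band boundary and
#' calendar-year boundary (and optionally at annual window boundaries since
#' entry), then attaches the stratum key and, if `target` is given, the
#' reference rate of the target cause in that stratum (halved for breast when
#' `halve = TRUE`). Segment lengths sum exactly to the interval length.
#'
#' @param intervals output of [at_risk_intervals()].
#' @param women the cohort's `women` table.
#' @param rates a [rate_table()], required when `target` is given.
#' @param band_width attained-age band width in years.
#' @param target cancer-type group whose reference rate to attach (NULL to
#'   skip the lookup).
#' @param halve halve the reference rate (contralateral breast convention).
#' @param window_cuts also cut at integer years since entry (used by the
#'   cumulative-risk windows).
#' @return data.table: `id`, `start`, `end`, `len`, `age_band_start`, `year`,
#'   `imd_fifth`, and `rate` when `target` is given (plus `window` when
#'   `window_cuts`).
#' @export
lexis_split <- function(intervals, women, rates = NULL, band_width = 5,
                        target = NULL, halve = FALSE, window_cuts = FALSE) {
  iv <- intervals[intervals$included == TRUE]
  if (nrow(iv) == 0) stop("no included at-risk intervals to split")
  d <- data.table::as.data.table(women)[iv, on = "id",
    .(id, age_dx, year_dx, imd_fifth, entry = i.entry, exit = i.exit)]
  eps <- 1e-9
  ca <- boundary_cuts(d$age_dx, d$entry, d$exit, band_width)
  cy <- boundary_cuts(d$year_dx, d$entry, d$exit, 1)
  rows <- list(seq_len(nrow(d)), ca$idx, cy$idx)
  ts <- list(d$entry, ca$t, cy$t)
  if (window_cuts) {
    cw <- boundary_cuts(-d$entry, d$entry, d$exit, 1)
    rows <- c(rows, list(cw$idx)); ts <- c(ts, list(cw$t))
  }
  pts <- data.table::data.table(row = unlist(rows), t = unlist(ts))
  data.table::setorder(pts, row, t)
  # drop (near-)duplicate cut points within a row
  pts <- pts[c(TRUE, !(diff(row) == 0 & diff(t) <= eps))]
  segs <- pts[, .(row, start = t,
                  end = data.table::shift(t, -1, fill = NA))]
  segs[is.na(end) | c(diff(row) != 0, TRUE), end := d$exit[row]]
  segs <- segs[end - start > eps / 2]
  segs[, `:=`(id = d$id[row],
              len = end - start,
              age_band_start = floor((d$age_dx[row] + start + eps) /
                                       band_width) * band_width,
              year = as.integer(floor(d$year_dx[row] + start + eps)),
              imd_fifth = d$imd_fifth[row])]
  if (window_cuts) segs[, window := as.integer(
    floor(start - d$entry[row] + eps) + 1)]
  segs[, row := NULL]
  if (!is.null(target)) {
    stopifnot(inherits(rates, "rate_table"))
    rt <- rates[rates$cancer_type == target,
                .(age_band_start, year, imd_fifth, rate)]
    if (nrow(rt) == 0) stop("no reference rates for cancer type '", target, "'")
    segs <- rt[segs, on = c("age_band_start", "year", "imd_fifth")]
    if (anyNA(segs$rate)) {
      bad <- segs[is.na(rate)][1]
      stop(sprintf(
        "rate table cell missing: age_band_start=%d, year=%d, imd_fifth=%s, cancer_type='%s'",
        bad$age_band_start, bad$year, as.character(bad$imd_fifth), target))
    }
    if (halve) segs[, rate := rate / 2]
  }
  segs[]
}

#' Tally observed events, expected events and woman-years per stratum
#'
#' Observed events are counted in the stratum of their event time; expected
#' events are the sum over Lexis segments of segment length times the
#' reference rate; woman-years are summed segment lengths. Totals are
#' invariant to stratum refinement.
#'
#' @param x a `cohort` (post-eligibility).
#' @param spec an [analysis_spec()].
#' @param rates a [rate_table()].
#' @param band_width attained-age band width in years.
#' @return A `stratum_tally` data.table: `age_band_start`, `year`,
#'   `imd_fifth`, `o`, `e`, `py`; attributes `spec`, `band_width`,
#'   `reconciliation` (exit-reason counts) and `n_dropped` (women without a
#'   positive-length interval).
#' @export
tally <- function(x, spec, rates, band_width = 5) {
  iv <- at_risk_intervals(x, spec)
  segs <- lexis_split(iv, x$women, rates, band_width,
                      target = spec$target, halve = spec$halve_reference)
  agg <- segs[, .(e = sum(len * rate), py = sum(len)),
              by = .(age_band_start, year, imd_fifth)]
  ## observed events with their event-time stratum
  if (spec$mode == "first") {
    oev <- iv[reason == "event", .(id, time = event_time)]
  } else {
    ev <- data.table::copy(x$events)
    ev[, role := classify_events(ev, spec)]
    oev <- ev[role == "target"][iv[included == TRUE],
                                on = "id", nomatch = NULL][
      time > entry & time <= exit, .(id, time)]
  }
  eps <- 1e-9
  if (nrow(oev)) {
    wd <- data.table::as.data.table(x$women)[oev, on = "id"]
    obs <- wd[, .(age_band_start = floor((age_dx + time + eps) / band_width) *
                    band_width,
                  year = as.integer(floor(year_dx + time + eps)),
                  imd_fifth = imd_fifth)][
      , .(o = .N), by = .(age_band_start, year, imd_fifth)]
  } else {
    obs <- data.table::data.table(age_band_start = numeric(),
                                  year = integer(), imd_fifth = integer(),
                                  o = integer())
  }
  out <- merge(agg, obs, by = c("age_band_start", "year", "imd_fifth"),
               all = TRUE)
  out[is.na(o), o := 0L]
  out[is.na(e), e := 0]
  out[is.na(py), py := 0]
  data.table::setcolorder(out, c("age_band_start", "year", "imd_fifth",
                                 "o", "e", "py"))
  data.table::setorder(out, age_band_start, year, imd_fifth)
  data.table::setattr(out, "spec", spec)
  data.table::setattr(out, "band_width", band_width)
  data.table::setattr(out, "reconciliation",
                      iv[, .N, by = reason][order(reason)])
  data.table::setattr(out, "n_dropped", sum(!iv$included))
  data.table::setattr(out, "class", c("stratum_tally", class(out)))
  out[]
}

#' Collapse a stratum tally over one or more axes
#'
#' Summing tallies is lossless: `O`, `E` and `PY` totals are preserved under
#' any merge of strata.
#'
#' @param tallies a `stratum_tally`.
#' @param by stratum columns to keep (default none: grand totals).
#' @return data.table of summed `o`, `e`, `py`.
#' @export
collapse_tally <- function(tallies, by = character()) {
  data.table::as.data.table(tallies)[, .(o = sum(o), e = sum(e),
                                         py = sum(py)),
                                     by = by]
}
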