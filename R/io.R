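# Delimited-text I/O: cohorts (women + long-format events), reference rate
# tables, cancer-type grouping maps. Comma-separated, UTF-8, header row;
# dates and times as decimal years.

#' Write / read a cohort as delimited text
#'
#' A cohort is stored as two CSV files: one row per woman, and a companion
#' long-format event file keyed by `id`. Reading validates the record
#' invariants (unique ids, positive sorted event times, no events after
#' death) and aborts with the offending id or line on malformed input.
#'
#' @param x a `cohort`.
#' @param women_path,events_path file paths.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` returns
#'   a `cohort`.
#' @export
write_cohort <- function(x, women_path, events_path) {
  stopifnot(inherits(x, "cohort"))
  data.table::fwrite(x$women, women_path, na = "NA")
  data.table::fwrite(x$events, events_path, na = "NA")
  invisible(c(women = women_path, events = events_path))
}

#' @rdname write_cohort
#' @param grouping optional [cancer_grouping()]; when supplied, the events'
#'   `cancer_type` column is treated as raw diagnosis codes and mapped to
#'   analysis groups (unmapped codes go to `"unspecified"` with a warning).
#' @export
read_cohort <- function(women_path, events_path, grouping = NULL) {
  for (p in c(women_path, events_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  women <- data.table::fread(women_path)
  events <- data.table::fread(events_path)
  if (anyDuplicated(women$id)) {
    stop("duplicate woman id: ", women$id[duplicated(women$id)][1],
         " in ", women_path)
  }
  if (nrow(events)) {
    unknown <- setdiff(events$id, women$id)
    if (length(unknown)) {
      stop("event for unknown woman id ", unknown[1], " in ", events_path)
    }
    if (anyNA(events$time) || any(events$time <= 0)) {
      bad <- which(is.na(events$time) | events$time <= 0)[1]
      stop("unparseable or non-positive event time at line ", bad + 1,
           " of ", events_path)
    }
    if (!is.null(grouping)) {
      events[, cancer_type := group_codes(cancer_type, grouping)]
    }
  }
  cohort(women, events)
}

#' Cancer-type grouping map
#'
#' Maps diagnosis codes (ICD-10-style strings) to analysis group names. No
#' code may map to two groups; codes not in the map are routed to
#' `"unspecified"`.
#'
#' @param map named character vector: `names` are codes, values group names.
#' @return A `cancer_grouping`.
#' @export
cancer_grouping <- function(map) {
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    dup <- names(map)[duplicated(names(map))][1]
    stop("grouping map must have unique code names",
         if (!is.null(names(map))) paste0(" (duplicate: ", dup, ")"))
  }
  structure(as.character(map), names = names(map), class = "cancer_grouping")
}

#' @rdname cancer_grouping
#' @param codes character vector of diagnosis codes to map.
#' @param grouping a `cancer_grouping`.
#' @export
group_codes <- function(codes, grouping) {
  stopifnot(inherits(grouping, "cancer_grouping"))
  out <- unname(grouping[codes])
  if (anyNA(out)) {
    warning("unmapped diagnosis codes routed to 'unspecified': ",
            paste(unique(codes[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- "unspecified"
  }
  out
}

#' Write / read a reference rate table as delimited text
#'
#' Columns: `age_band_start`, `year`, `imd_fifth`, `cancer_type`, `rate`.
#'
#' @param x a [rate_table()]; `path` a CSV path.
#' @return `read_rates` returns a validated [rate_table()].
#' @export
write_rates <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}

#' @rdname write_rates
#' @param band_width age band width; inferred from the band spacing when NULL.
#' @export
read_rates <- function(path, band_width = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  if (is.null(band_width)) {
    bands <- sort(unique(dt$age_band_start))
    band_width <- if (length(bands) > 1) min(diff(bands)) else 5
  }
  rate_table(dt, band_width = band_width)
}
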