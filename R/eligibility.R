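# Cohort eligibility filtering, applied as an ordered sequence of toggleable
# rules. A woman excluded by rule i is not counted against later rules, so the
# per-rule counts reproduce an exclusion flow chart.

#' Eligibility rule set
#'
#' The default rules, in application order: age at diagnosis outside 20-75
#' completed years; under three months of follow-up (death or administrative
#' end before diagnosis + 3 months); index morphology not invasive breast
#' cancer; a second invasive cancer of any type within three months of the
#' index diagnosis; likely metastatic disease; neoadjuvant therapy. Each rule
#' can be toggled off independently.
#'
#' @param age_min,age_max bounds on completed years of age at diagnosis.
#' @param min_followup minimum follow-up in years (3 months = 0.25).
#' @param age,followup,non_invasive_index,early_second,metastatic,neoadjuvant
#'   logical toggles for the individual rules.
#' @return An `eligibility_rules` list.
#' @export
eligibility_rules <- function(age_min = 20, age_max = 75,
                              min_followup = 0.25,
                              age = TRUE, followup = TRUE,
                              non_invasive_index = TRUE,
                              early_second = TRUE,
                              metastatic = TRUE,
                              neoadjuvant = TRUE) {
  structure(list(age_min = age_min, age_max = age_max,
                 min_followup = min_followup,
                 toggles = c(age = age, followup = followup,
                             non_invasive_index = non_invasive_index,
                             early_second = early_second,
                             metastatic = metastatic,
                             neoadjuvant = neoadjuvant)),
            class = "eligibility_rules")
}

#' Apply eligibility rules to a cohort
#'
#' Rules are applied sequentially in the order of [eligibility_rules()]; the
#' returned exclusion table gives, for each enabled rule, the number of women
#' it removed from those still eligible when it ran.
#'
#' @param x a `cohort`.
#' @param rules an [eligibility_rules()].
#' @return list with `cohort` (the eligible subset), and `exclusions`
#'   (data.table: `rule`, `n_excluded`, `n_remaining`).
#' @export
apply_eligibility <- function(x, rules = eligibility_rules()) {
  stopifnot(inherits(x, "cohort"), inherits(rules, "eligibility_rules"))
  w <- x$women
  ev <- x$events
  keep <- rep(TRUE, nrow(w))
  # per-woman predicate of exclusion, given the full tables
  preds <- list(
    age = function() {
      floor(w$age_dx + 1e-9) < rules$age_min |
        floor(w$age_dx + 1e-9) > rules$age_max
    },
    followup = function() {
      fu <- pmin(ifelse(is.na(w$death_time), Inf, w$death_time), w$fu_end)
      fu < rules$min_followup
    },
    non_invasive_index = function() {
      if (is.null(w$index_invasive)) return(rep(FALSE, nrow(w)))
      !is.na(w$index_invasive) & !w$index_invasive
    },
    early_second = function() {
      if (nrow(ev) == 0) return(rep(FALSE, nrow(w)))
      bad <- ev[invasive & time <= rules$min_followup, unique(id)]
      w$id %in% bad
    },
    metastatic = function() isTRUE_vec(w$metastatic),
    neoadjuvant = function() isTRUE_vec(w$neoadjuvant)
  )
  out <- data.table::data.table(rule = character(), n_excluded = integer(),
                                n_remaining = integer())
  for (nm in names(preds)) {
    if (!isTRUE(rules$toggles[[nm]])) next
    hit <- preds[[nm]]() & keep
    keep <- keep & !hit
    out <- rbind(out, data.table::data.table(
      rule = nm, n_excluded = sum(hit), n_remaining = sum(keep)))
  }
  if (!any(keep)) warning("no women remain after eligibility filtering")
  ids <- w$id[keep]
  list(cohort = cohort(w[keep], ev[id %in% ids], config = x$config),
       exclusions = out)
}

# treat missing columns / NAs as FALSE
isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}
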