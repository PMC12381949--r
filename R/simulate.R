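# Event-history simulation of a breast-cancer survivor cohort with known
# ground truth. Each woman's competing second-cancer and death times are drawn
# from piecewise-constant cause-specific hazards
#   h_k(t) = reference rate of cause k in her current (attained age band,
#            calendar year, deprivation fifth) stratum x multiplier(k, exposures)
# using exact inverse-transform sampling on each constant-hazard segment
# (no time discretisation).

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate the marginal structure of a 1993-2016 English early
#' breast-cancer cohort followed to 31 October 2021: age at diagnosis 20-75
#' (whole months), diagnosis year by calendar period, deprivation fifths,
#' tumour covariates with "unknown" levels, and treatment assignment in which
#' radiotherapy follows surgery type, endocrine therapy follows ER status, and
#' chemotherapy use declines with age at diagnosis (the
#' confounding-by-indication knob, since cancer and death rates rise with age).
#'
#' @param n number of women (must be >= 1).
#' @param seed RNG seed; a fixed seed gives byte-identical cohorts.
#' @param age_breaks,age_probs age-at-diagnosis groups `[b_i, b_{i+1})` and
#'   their sampling probabilities; ages are drawn uniformly on the 1/12-year
#'   (whole-month) grid within the group.
#' @param year_breaks,year_probs same for calendar period of diagnosis.
#' @param imd_probs probabilities of deprivation fifths 1-5 (1 = least).
#' @param covariates named list of category-probability vectors for the
#'   tumour covariates.
#' @param treatment list of treatment-assignment parameters: `p_bcs`,
#'   `p_rt_bcs`, `p_rt_mastectomy`, `p_endocrine_erpos`, `p_endocrine_other`,
#'   and a chemotherapy log-odds model `chemo_intercept + chemo_age_coef *
#'   (age - 55)/10 + chemo_rt_coef * radiotherapy`. The age and radiotherapy
#'   coefficients are the confounding-by-indication knobs: age links
#'   chemotherapy use to the age-increasing baseline rates (controlled by
#'   stratification), and the radiotherapy term clusters intensive
#'   treatments so that adjusted and unadjusted rate ratios separate when a
#'   co-treatment has its own effect.
#' @param multipliers data.frame with columns `cancer_type`, `exposure`,
#'   `multiplier`: multiplicative hazard factors (1 = null). `exposure` is one
#'   of `"(all)"` (applies to everyone), `"radiotherapy"`, `"endocrine"`,
#'   `"chemotherapy"`, `"bcs"`, `"mastectomy"`. `cancer_type` may be `"death"`.
#'   Multipliers must be >= 0 (0 switches a hazard off).
#' @param admin_date administrative censoring date in decimal years
#'   (default 31 October 2021 = 2021 + 10/12).
#' @param p_noninvasive named per-type probability that a simulated event is
#'   non-invasive (in situ); unnamed types default to 0.
#' @param laterality_probs probabilities that a second breast event is
#'   contralateral / ipsilateral / of unknown laterality.
#' @param breast_hazard_scale factor applied to the reference breast rate in
#'   the second-breast-cancer hazard. The default,
#'   `0.5 / (contralateral + unknown laterality probability)`, makes the true
#'   hazard of a countable (contralateral or unknown-laterality) second
#'   breast cancer exactly half the population breast rate: one breast at
#'   risk, so the null standardised incidence ratio against halved reference
#'   rates is 1 and a configured breast multiplier is recovered as the
#'   contralateral SIR.
#' @param endocrine_mask_prob probability that a true endocrine user's
#'   recorded flag is masked to FALSE (under-recording emulation); the truth
#'   is kept in `endocrine_true` and drives the hazards.
#' @param continue_after_event continue drawing further events (same hazards)
#'   after a first cancer event, up to `max_events`, so that "any time"
#'   sensitivity analyses are exercised.
#' @param max_events cap on simulated cancer events per woman.
#' @param p_index_noninvasive,p_metastatic,p_neoadjuvant probabilities of
#'   planting eligibility-rule violations (default 0: the generator emulates
#'   the analysed, post-exclusion cohort).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 10000,
                       seed = 1L,
                       age_breaks = c(20, 40, 50, 60, 70, 76),
                       age_probs = c(0.07, 0.20, 0.31, 0.30, 0.12),
                       year_breaks = c(1993, 2000, 2005, 2010, 2017),
                       year_probs = c(0.22, 0.21, 0.24, 0.33),
                       imd_probs = c(0.23, 0.23, 0.21, 0.18, 0.15),
                       covariates = list(
                         er_status = c(positive = 0.54, negative = 0.05,
                                       unknown = 0.41),
                         screen_detected = c(yes = 0.28, no = 0.30,
                                             not_eligible = 0.42),
                         size_class = c("1-20" = 0.51, "21-50" = 0.28,
                                        ">50" = 0.03, unknown = 0.18),
                         node_class = c("0" = 0.36, "1-3" = 0.17,
                                        "4-9" = 0.05, "10+" = 0.02,
                                        unknown = 0.40),
                         grade = c(low = 0.18, medium = 0.44, high = 0.31,
                                   unknown = 0.07),
                         morphology = c(nst = 0.81, lobular = 0.11,
                                        other = 0.08),
                         laterality_index = c(left = 0.5, right = 0.5)),
                       treatment = list(p_bcs = 0.63,
                                        p_rt_bcs = 0.90,
                                        p_rt_mastectomy = 0.32,
                                        p_endocrine_erpos = 0.85,
                                        p_endocrine_other = 0.05,
                                        chemo_intercept = -0.62,
                                        chemo_age_coef = -0.55,
                                        chemo_rt_coef = 0.5),
                       multipliers = NULL,
                       admin_date = 2021 + 10 / 12,
                       p_noninvasive = c(breast = 0.15),
                       laterality_probs = c(contralateral = 0.86,
                                            ipsilateral = 0.11,
                                            unknown = 0.03),
                       breast_hazard_scale = NULL,
                       endocrine_mask_prob = 0,
                       continue_after_event = TRUE,
                       max_events = 3L,
                       p_index_noninvasive = 0,
                       p_metastatic = 0,
                       p_neoadjuvant = 0) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("empty cohort: n must be >= 1")
  stopifnot(length(age_probs) == length(age_breaks) - 1,
            length(year_probs) == length(year_breaks) - 1,
            abs(sum(age_probs) - 1) < 1e-8,
            abs(sum(year_probs) - 1) < 1e-8,
            abs(sum(imd_probs) - 1) < 1e-8)
  if (is.null(multipliers)) {
    multipliers <- data.frame(cancer_type = character(),
                              exposure = character(),
                              multiplier = numeric())
  }
  multipliers <- as.data.frame(multipliers)
  if (nrow(multipliers)) {
    if (anyNA(multipliers$multiplier) || any(multipliers$multiplier < 0)) {
      stop("configuration error: hazard multipliers must be >= 0")
    }
    ok_exp <- c("(all)", "radiotherapy", "endocrine", "chemotherapy",
                "bcs", "mastectomy")
    bad <- setdiff(multipliers$exposure, ok_exp)
    if (length(bad)) stop("unknown exposure in multipliers: ",
                          paste(bad, collapse = ", "))
  }
  if (is.null(breast_hazard_scale)) {
    # reference rates describe invasive incidence: calibrate so the hazard of
    # a countable event (invasive, contralateral or unknown laterality) is
    # exactly half the population breast rate
    pni <- unname(p_noninvasive["breast"])
    if (is.na(pni)) pni <- 0
    countable <- sum(laterality_probs[c("contralateral", "unknown")],
                     na.rm = TRUE) * (1 - pni)
    breast_hazard_scale <- if (isTRUE(countable > 0)) 0.5 / countable else 1
  }
  cfg <- list(n = as.integer(n), seed = seed, age_breaks = age_breaks,
              age_probs = age_probs, year_breaks = year_breaks,
              year_probs = year_probs, imd_probs = imd_probs,
              covariates = covariates, treatment = treatment,
              multipliers = multipliers, admin_date = admin_date,
              p_noninvasive = p_noninvasive,
              laterality_probs = laterality_probs,
              breast_hazard_scale = breast_hazard_scale,
              endocrine_mask_prob = endocrine_mask_prob,
              continue_after_event = isTRUE(continue_after_event),
              max_events = as.integer(max_events),
              p_index_noninvasive = p_index_noninvasive,
              p_metastatic = p_metastatic, p_neoadjuvant = p_neoadjuvant)
  class(cfg) <- "sim_config"
  cfg
}

# sample categories from a named probability vector
sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Simulate a cohort of women with competing second-cancer and death events
#'
#' Draws each woman's event history from the piecewise-constant cause-specific
#' hazards implied by `rates` and the configured multipliers. Within each
#' constant-hazard segment (delimited by attained-age band and calendar-year
#' boundaries) the time to the next event is sampled exactly by
#' inverse-transform on the exponential distribution; the cause is then drawn
#' proportional to the cause-specific hazards. Simulation stops at the
#' administrative censoring date or the 85th birthday, whichever is earlier
#' (reference rates end at age 85), at death, or after `max_events` cancer
#' events.
#'
#' @param config a [sim_config()].
#' @param rates a [rate_table()] covering the simulated age and year span and
#'   containing a `"death"` mortality row per stratum.
#' @return A `cohort`: list with `women` (one row per woman) and `events`
#'   (long format keyed by `id`, columns `time` in years since diagnosis,
#'   `cancer_type`, `laterality`, `invasive`), plus the generating `config`.
#' @export
simulate_cohort <- function(config, rates) {
  stopifnot(inherits(config, "sim_config"), inherits(rates, "rate_table"))
  types <- attr(rates, "cancer_types")
  if (!("death" %in% unique(rates$cancer_type))) {
    stop("rate table must include a 'death' mortality rate for simulation")
  }
  bad_type <- setdiff(unique(config$multipliers$cancer_type),
                      c(types, "death"))
  if (length(bad_type)) {
    stop("multiplier refers to cancer types absent from the rate table: ",
         paste(bad_type, collapse = ", "))
  }
  n <- config$n
  with_seed(config$seed, {
    ## -- covariates ---------------------------------------------------------
    gi <- sample.int(length(config$age_probs), n, replace = TRUE,
                     prob = config$age_probs)
    lo_m <- config$age_breaks[gi] * 12
    hi_m <- pmin(config$age_breaks[gi + 1] * 12, 76 * 12) - 1
    age_dx <- (lo_m + floor(stats::runif(n) * (hi_m - lo_m + 1))) / 12
    yi <- sample.int(length(config$year_probs), n, replace = TRUE,
                     prob = config$year_probs)
    yr_int <- config$year_breaks[yi] +
      floor(stats::runif(n) * (config$year_breaks[yi + 1] -
                               config$year_breaks[yi]))
    year_dx <- yr_int + floor(stats::runif(n) * 12) / 12
    imd <- sample.int(length(config$imd_probs), n, replace = TRUE,
                      prob = config$imd_probs)
    cov <- lapply(config$covariates, function(p) sample_cat(n, p))
    tr <- config$treatment
    surgery <- ifelse(stats::runif(n) < tr$p_bcs, "bcs", "mastectomy")
    radiotherapy <- stats::runif(n) <
      ifelse(surgery == "bcs", tr$p_rt_bcs, tr$p_rt_mastectomy)
    endocrine_true <- stats::runif(n) <
      ifelse(cov$er_status == "positive", tr$p_endocrine_erpos,
             tr$p_endocrine_other)
    chemo <- stats::runif(n) <
      stats::plogis(tr$chemo_intercept +
                    tr$chemo_age_coef * (age_dx - 55) / 10 +
                    (tr$chemo_rt_coef %||% 0) * radiotherapy)

    ## -- per-woman, per-cause hazard multipliers ---------------------------
    causes <- c(types, "death")
    K <- length(causes)
    M <- matrix(1, n, K, dimnames = list(NULL, causes))
    if ("breast" %in% causes) {
      M[, "breast"] <- config$breast_hazard_scale
    }
    if (nrow(config$multipliers)) {
      expo <- list("(all)" = rep(TRUE, n), radiotherapy = radiotherapy,
                   endocrine = endocrine_true, chemotherapy = chemo,
                   bcs = surgery == "bcs", mastectomy = surgery == "mastectomy")
      for (r in seq_len(nrow(config$multipliers))) {
        k <- match(config$multipliers$cancer_type[r], causes)
        w <- expo[[config$multipliers$exposure[r]]]
        M[w, k] <- M[w, k] * config$multipliers$multiplier[r]
      }
    }

    ## -- event-history simulation ------------------------------------------
    lk <- rate_lookup(rates, causes = causes)
    fu_admin <- config$admin_date - year_dx
    horizon <- pmin(fu_admin, 85 - age_dx)
    if (any(horizon <= 0)) stop("rate/censoring span leaves zero follow-up")
    t_cur <- numeric(n)
    active <- rep(TRUE, n)
    n_ev <- integer(n)
    death_time <- rep(NA_real_, n)
    ev_id <- vector("list", 512); ev_t <- ev_id; ev_k <- ev_id
    it <- 0L
    eps <- 1e-9
    bw <- lk$band_width
    while (any(active)) {
      it <- it + 1L
      if (it > length(ev_id)) stop("simulation failed to terminate")
      idx <- which(active)
      tt <- t_cur[idx]
      age <- age_dx[idx] + tt
      yr <- year_dx[idx] + tt
      next_age <- (floor((age + eps) / bw) + 1) * bw - age_dx[idx]
      next_yr <- floor(yr + eps) + 1 - year_dx[idx]
      seg_end <- pmin(next_age, next_yr, horizon[idx])
      h <- matrix(0, length(idx), K)
      for (k in seq_len(K)) {
        h[, k] <- rate_query(lk, age, yr, imd[idx], rep(k, length(idx))) *
          M[idx, k]
      }
      H <- rowSums(h)
      dt_draw <- ifelse(H > 0, stats::rexp(length(idx)) / H, Inf)
      te <- tt + dt_draw
      has_event <- te < seg_end
      if (any(has_event)) {
        ei <- which(has_event)
        u <- stats::runif(length(ei)) * H[ei]
        kk <- integer(length(ei))
        cum <- 0
        for (k in seq_len(K)) {
          cum <- cum + h[ei, k]
          kk[kk == 0L & u <= cum] <- k
        }
        kk[kk == 0L] <- K  # numerical guard
        who <- idx[ei]
        is_death <- causes[kk] == "death"
        if (any(is_death)) {
          dw <- who[is_death]
          death_time[dw] <- te[ei[is_death]]
          active[dw] <- FALSE
        }
        if (any(!is_death)) {
          cw <- who[!is_death]
          ev_id[[it]] <- cw
          ev_t[[it]] <- te[ei[!is_death]]
          ev_k[[it]] <- causes[kk[!is_death]]
          n_ev[cw] <- n_ev[cw] + 1L
          stopped <- !config$continue_after_event |
            n_ev[cw] >= config$max_events
          active[cw[stopped]] <- FALSE
          t_cur[cw[!stopped]] <- te[ei[!is_death]][!stopped]
        }
      }
      no_event <- idx[!has_event]
      t_cur[no_event] <- seg_end[!has_event]
      done <- no_event[t_cur[no_event] >= horizon[no_event] - 1e-12]
      active[done] <- FALSE
    }

    ## -- event attributes ---------------------------------------------------
    events <- data.table::data.table(
      id = unlist(ev_id), time = unlist(ev_t),
      cancer_type = unlist(ev_k))
    if (nrow(events) == 0) {
      events <- data.table::data.table(id = integer(), time = numeric(),
                                       cancer_type = character())
    }
    p_ni <- config$p_noninvasive[events$cancer_type]
    p_ni[is.na(p_ni)] <- 0
    events[, invasive := stats::runif(.N) >= p_ni]
    events[, laterality := NA_character_]
    nb <- events$cancer_type == "breast"
    if (any(nb)) {
      events[nb, laterality := sample_cat(sum(nb), config$laterality_probs)]
    }
    data.table::setorder(events, id, time)

    ## -- women table --------------------------------------------------------
    women <- data.table::data.table(
      id = seq_len(n), age_dx = age_dx, year_dx = year_dx, imd_fifth = imd,
      er_status = cov$er_status, screen_detected = cov$screen_detected,
      size_class = cov$size_class, node_class = cov$node_class,
      grade = cov$grade, morphology = cov$morphology,
      laterality_index = cov$laterality_index,
      surgery = surgery, radiotherapy = radiotherapy,
      endocrine_true = endocrine_true,
      endocrine = endocrine_true &
        (stats::runif(n) >= config$endocrine_mask_prob),
      chemotherapy = chemo,
      index_invasive = stats::runif(n) >= config$p_index_noninvasive,
      metastatic = stats::runif(n) < config$p_metastatic,
      neoadjuvant = stats::runif(n) < config$p_neoadjuvant,
      death_time = death_time,
      fu_end = fu_admin)
    cohort(women, events, config = config)
  })
}

#' Construct a cohort object
#'
#' Bundles the per-woman table and the long-format event table and checks the
#' record invariants: unique ids, strictly positive sorted event times, no
#' event after death, laterality present (possibly "unknown") for breast
#' events.
#'
#' @param women data.frame, one row per woman (see [simulate_cohort()] for
#'   the column set).
#' @param events data.frame keyed by `id` with `time`, `cancer_type`,
#'   `laterality`, `invasive`.
#' @param config optional generating [sim_config()].
#' @return A `cohort` object.
#' @export
cohort <- function(women, events, config = NULL) {
  women <- data.table::as.data.table(women)
  events <- data.table::as.data.table(events)
  if (anyDuplicated(women$id)) {
    stop("duplicate woman id: ",
         women$id[anyDuplicated(women$id)])
  }
  if (nrow(events)) {
    if (!all(events$id %in% women$id)) stop("event with unknown woman id")
    if (any(events$time <= 0)) stop("event times must be strictly positive")
    data.table::setorder(events, id, time)
    if ("death_time" %in% names(women)) {
      dt_look <- women[events, on = "id"]
      if (any(!is.na(dt_look$death_time) &
              dt_look$time > dt_look$death_time + 1e-12)) {
        stop("event recorded after death")
      }
    }
    if ("laterality" %in% names(events)) {
      br <- events$cancer_type == "breast"
      if (any(br & is.na(events$laterality))) {
        stop("breast events must have laterality (or explicit 'unknown')")
      }
    }
  }
  structure(list(women = women, events = events, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d women, %d second-cancer events\n",
              nrow(x$women), nrow(x$events)))
  invisible(x)
}
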