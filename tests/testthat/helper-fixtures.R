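# A single-stratum world: flat rates for one cancer type plus mortality,
# so cause-specific hazards are constant and closed forms apply.
flat_rates <- function(lambda1 = 0.02, lambda_death = 0.08, type = "A",
                       years = 1995:2035) {
  br <- stats::setNames(lambda1, type)
  make_reference_rates(years = years, base_rate = br,
                       death_rate = lambda_death,
                       age_doubling = Inf, death_age_doubling = Inf,
                       deprivation_gradient = 1, year_trend = 1)
}

flat_config <- function(n, seed, admin_date = 2030, multipliers = NULL,
                        age_breaks = c(30, 31), year_breaks = c(2000, 2001)) {
  sim_config(n = n, seed = seed,
             age_breaks = age_breaks, age_probs = 1,
             year_breaks = year_breaks, year_probs = 1,
             p_noninvasive = numeric(), admin_date = admin_date,
             multipliers = multipliers)
}

# Hand-built cohort rows with sensible defaults for all required columns.
make_women <- function(n, age_dx = 50, year_dx = 2000, imd_fifth = 3,
                       death_time = NA_real_, fu_end = 21 + 10 / 12,
                       surgery = "bcs", radiotherapy = TRUE,
                       endocrine = FALSE, er_status = "unknown",
                       chemotherapy = FALSE) {
  data.table::data.table(id = seq_len(n), age_dx = age_dx, year_dx = year_dx,
             imd_fifth = imd_fifth, er_status = er_status,
             screen_detected = "no", size_class = "1-20", node_class = "0",
             grade = "medium", morphology = "nst", laterality_index = "left",
             surgery = surgery, radiotherapy = radiotherapy,
             endocrine_true = endocrine, endocrine = endocrine,
             chemotherapy = chemotherapy, index_invasive = TRUE,
             metastatic = FALSE, neoadjuvant = FALSE,
             death_time = death_time, fu_end = fu_end)
}

make_events <- function(id, time, cancer_type = "lung",
                        laterality = NA_character_, invasive = TRUE) {
  data.table::data.table(id = id, time = time, cancer_type = cancer_type,
             laterality = laterality, invasive = invasive)
}

# Daily-step brute-force person-time oracle: walk each interval in steps of
# 1/360 year (30-day months, matching the package's 1/12-year calendar grid,
# so stratum boundaries fall exactly on step ends), assigning each step to
# the stratum at its start. Returns per-stratum expected counts and
# woman-years.
brute_force_tally <- function(x, spec, rates, band_width = 5,
                              step = 1 / 360) {
  iv <- at_risk_intervals(x, spec)
  iv <- iv[iv$included == TRUE]
  w <- data.table::as.data.table(x$women)[iv, on = "id"]
  rt <- data.table::as.data.table(rates)[cancer_type == spec$target]
  data.table::setkey(rt, age_band_start, year, imd_fifth)
  pieces <- vector("list", nrow(w))
  for (i in seq_len(nrow(w))) {
    tgrid <- seq(w$entry[i], w$exit[i], by = step)
    if (w$exit[i] - tgrid[length(tgrid)] > 1e-12) {
      tgrid <- c(tgrid, w$exit[i])
    }
    st <- tgrid[-length(tgrid)]
    en <- tgrid[-1]
    keep <- en - st > 1e-12
    st <- st[keep]; en <- en[keep]
    band <- floor((w$age_dx[i] + st + 1e-9) / band_width) * band_width
    yr <- as.integer(floor(w$year_dx[i] + st + 1e-9))
    pieces[[i]] <- data.table::data.table(age_band_start = band, year = yr,
                              imd_fifth = w$imd_fifth[i], len = en - st)
  }
  all <- data.table::rbindlist(pieces)
  all <- rt[all, on = c("age_band_start", "year", "imd_fifth")]
  if (spec$halve_reference) all[, rate := rate / 2]
  all[, .(e = sum(len * rate), py = sum(len)),
      by = .(age_band_start, year, imd_fifth)]
}

# Aalen-Johansen oracle on window-discretised exits, via survival::survfit.
aj_cif_oracle <- function(x, spec, rates, band_width = 5) {
  iv <- at_risk_intervals(x, spec)
  iv <- iv[iv$included == TRUE]
  tau <- iv$exit - iv$entry
  w_exit <- pmax(1L, as.integer(ceiling(tau - 1e-9)))
  status <- factor(
    ifelse(iv$reason == "event", "target",
           ifelse(iv$reason %in% c("competing-event", "death"),
                  "competing", "censor")),
    levels = c("censor", "target", "competing"))
  fit <- survival::survfit(survival::Surv(w_exit, status) ~ 1)
  times <- seq_len(max(w_exit))
  sm <- summary(fit, times = times)
  sm$pstate[, which(colnames(fit$pstate) == "target")]
}
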