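flat_r <- flat_rates(0.001, 0.001, type = "lung", years = 1990:2035)

test_that("entry is 3 months after diagnosis; exit takes the earliest cause", {
  # woman 1: death precedes administrative end; woman 2: target event first;
  # woman 3: a non-qualifying (non-invasive) event at 5.0 does not pre-empt
  # the earlier death at 4.0
  w <- make_women(3)
  w$death_time <- c(4.0, NA, 4.0)
  ev <- make_events(c(2L, 3L), time = c(3.0, 3.9),
                    invasive = c(TRUE, FALSE))
  co <- cohort(w, ev)
  iv <- at_risk_intervals(co, analysis_spec("lung"))
  expect_equal(iv$entry, rep(0.25, 3))
  expect_equal(iv[id == 1L, .(exit, reason)],
               data.table::data.table(exit = 4.0, reason = "death"))
  expect_equal(iv[id == 2L, .(exit, reason)],
               data.table::data.table(exit = 3.0, reason = "event"))
  expect_equal(iv[id == 3L, .(exit, reason)],
               data.table::data.table(exit = 4.0, reason = "death"))
})

test_that("diagnosis close to the 85th birthday yields no interval", {
  w <- make_women(2)
  w$age_dx <- c(84.80, 84.50)
  co <- cohort(w, make_events(integer(), numeric()))
  iv <- at_risk_intervals(co, analysis_spec("lung"))
  expect_false(iv[id == 1L, included])  # 85 - 84.80 - 0.25 < 0
  expect_equal(iv[id == 1L, reason], "zero_length")
  expect_true(iv[id == 2L, included])
  expect_equal(iv[id == 2L, exit], 0.5)
  expect_equal(iv[id == 2L, reason], "age85")
})

test_that("non-invasive events are ignored under the invasive outcome", {
  w <- make_women(1)
  ev <- make_events(c(1L, 1L), time = c(2, 6),
                    invasive = c(FALSE, TRUE))
  co <- cohort(w, ev)
  iv <- at_risk_interval(co, 1L, analysis_spec("lung"))
  expect_equal(iv$exit, 6)
  expect_equal(iv$reason, "event")
})

test_that("non-invasive analyses censor at any invasive cancer", {
  w <- make_women(1)
  ev <- make_events(c(1L, 1L), time = c(3, 8),
                    cancer_type = c("lung", "breast"),
                    laterality = c(NA, "contralateral"),
                    invasive = c(TRUE, FALSE))
  co <- cohort(w, ev)
  sp <- analysis_spec("breast", outcome = "noninvasive")
  iv <- at_risk_interval(co, 1L, sp)
  expect_equal(iv$exit, 3)
  expect_equal(iv$reason, "competing-event")
})

test_that("ipsilateral breast events censor but never count; unknown joins contralateral", {
  w <- make_women(3)
  ev <- make_events(1:3, time = c(4, 4, 4), cancer_type = "breast",
                    laterality = c("ipsilateral", "unknown", "contralateral"))
  co <- cohort(w, ev)
  iv <- at_risk_intervals(co, analysis_spec("breast"))
  expect_equal(iv[order(id), reason],
               c("competing-event", "event", "event"))
  iv2 <- at_risk_intervals(co, analysis_spec(
    "breast", include_unknown_laterality = FALSE))
  expect_equal(iv2[id == 2L, reason], "competing-event")
})

test_that("a pre-entry qualifying event removes the woman with a named reason", {
  w <- make_women(1)
  ev <- make_events(1L, time = 0.2)
  co <- cohort(w, ev, config = NULL)
  iv <- at_risk_interval(co, 1L, analysis_spec("lung"))
  expect_false(iv$included)
  expect_equal(iv$reason, "pre_entry_event")
})

test_that("lexis segments partition the interval across boundaries", {
  # attained age crosses one band boundary 0.7 years after entry
  w <- make_women(1, age_dx = 44.05, year_dx = 2000.5, fu_end = 2.0)
  co <- cohort(w, make_events(integer(), numeric()))
  iv <- at_risk_intervals(co, analysis_spec("lung"))
  segs <- lexis_split(iv, co$women, flat_r, target = "lung")
  expect_equal(sum(segs$len), 2.0 - 0.25, tolerance = 1e-12)
  expect_equal(segs[age_band_start == 40, sum(len)], 0.7, tolerance = 1e-12)
  expect_equal(segs[age_band_start == 45, sum(len)], 1.05, tolerance = 1e-12)
  # each segment sits wholly inside one calendar year
  expect_true(all(floor(2000.5 + segs$start + 1e-9) ==
                    floor(2000.5 + segs$end - 1e-9)))
})

test_that("one woman-year at rate 0.001 contributes e = 0.001", {
  w <- make_women(1, fu_end = 1.25)
  co <- cohort(w, make_events(integer(), numeric()))
  tl <- tally(co, analysis_spec("lung"), flat_r)
  tot <- collapse_tally(tl)
  expect_equal(tot$o, 0L)
  expect_equal(tot$py, 1.0, tolerance = 1e-12)
  expect_equal(tot$e, 0.001, tolerance = 1e-12)
})

test_that("an event exactly on a band boundary belongs to the later band", {
  w <- make_women(1, age_dx = 40, fu_end = 30)
  ev <- make_events(1L, time = 5.0)  # attained age exactly 45
  co <- cohort(w, ev)
  tl <- tally(co, analysis_spec("lung"), flat_r)
  expect_equal(tl[o == 1L, age_band_start], 45)
})

test_that("missing rate cells abort with the cell named", {
  narrow <- flat_rates(0.001, 0.001, type = "lung", years = 2000:2005)
  w <- make_women(1, year_dx = 2000, fu_end = 10)
  co <- cohort(w, make_events(integer(), numeric()))
  expect_error(tally(co, analysis_spec("lung"), narrow), "year=2006")
})

test_that("tallies conserve totals and are invariant to stratum merging", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 2000, seed = 31), r)
  el <- apply_eligibility(co)$cohort
  sp <- analysis_spec("lung")
  iv <- at_risk_intervals(el, sp)
  t5 <- tally(el, sp, r, band_width = 5)
  # conservation against interval lengths and event counts
  expect_equal(sum(t5$py), iv[included == TRUE, sum(exit - entry)],
               tolerance = 1e-9)
  expect_equal(sum(t5$o), iv[, sum(reason == "event")])
  # merging strata preserves (O, E, PY): compare against a coarser split
  coarse <- collapse_tally(t5, by = c("year"))
  expect_equal(sum(coarse$e), sum(t5$e), tolerance = 1e-12)
  expect_equal(sum(coarse$o), sum(t5$o))
  expect_equal(sum(coarse$py), sum(t5$py), tolerance = 1e-12)
})

test_that("any-time person-time exceeds first-event person-time iff events occur", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 1500, seed = 19), r)
  el <- apply_eligibility(co)$cohort
  iv1 <- at_risk_intervals(el, analysis_spec("lung", mode = "first"))
  iv2 <- at_risk_intervals(el, analysis_spec("lung", mode = "anytime"))
  m <- merge(iv1[included == TRUE, .(id, py1 = exit - entry, reason)],
             iv2[included == TRUE, .(id, py2 = exit - entry)], by = "id")
  had_event <- m$reason %in% c("event", "competing-event")
  expect_true(all(m$py2[had_event] > m$py1[had_event]))
  expect_equal(m$py2[!had_event], m$py1[!had_event], tolerance = 1e-12)
})

test_that("lexis tallies match the daily-step brute-force oracle", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 120, seed = 57), r)
  el <- apply_eligibility(co)$cohort
  sp <- analysis_spec("breast")
  tl <- data.table::as.data.table(tally(el, sp, r))
  bf <- brute_force_tally(el, sp, r)
  m <- merge(tl, bf, by = c("age_band_start", "year", "imd_fifth"),
             all = TRUE, suffixes = c("", ".bf"))
  m[is.na(py.bf), `:=`(py.bf = 0, e.bf = 0)]
  expect_lt(max(abs(m$py - m$py.bf)), 1e-6)
  expect_lt(max(abs(m$e - m$e.bf)), 1e-6)
})
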