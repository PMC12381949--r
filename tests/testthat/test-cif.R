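zero_r <- flat_rates(0, 0, type = "A", years = 1990:2035)

test_that("with no competing events the estimator is the Kaplan-Meier complement", {
  w <- make_women(10, fu_end = 30)
  ev <- make_events(1:3, time = c(0.5, 1.5, 2.5), cancer_type = "A")
  co <- cohort(w, ev)
  oc <- observed_cif(co, analysis_spec("A"), zero_r)
  # three annual windows: p = 1/10, 1/9, 1/8; R = 1 - prod(1 - p)
  p <- c(1 / 10, 1 / 9, 1 / 8)
  expect_equal(oc$R_obs[1:3], 1 - cumprod(1 - p), tolerance = 1e-12)
})

test_that("no target events gives an identically zero curve", {
  w <- make_women(5, fu_end = 10)
  w$death_time[1] <- 3
  co <- cohort(w, make_events(integer(), numeric(), cancer_type = character()))
  oc <- observed_cif(co, analysis_spec("A"), zero_r)
  expect_true(all(oc$R_obs == 0))
})

test_that("one event among ten with zero expected rates gives excess 0.1", {
  w <- make_women(10, fu_end = 30)
  ev <- make_events(1L, time = 0.5, cancer_type = "A")
  co <- cohort(w, ev)
  cc <- cif_curve(co, analysis_spec("A"), zero_r)
  expect_equal(cc$R_exp, rep(0, nrow(cc)))
  expect_equal(excess_risk(cc, 1)$excess, 0.1, tolerance = 1e-12)
  expect_error(excess_risk(cc, 1000), "grid")
})

test_that("curves are monotone and conserve total probability", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 4000, seed = 23), r)
  el <- apply_eligibility(co)$cohort
  cc <- cif_curve(el, analysis_spec("breast"), r)
  expect_true(all(diff(cc$R_obs) > -1e-12))
  expect_true(all(diff(cc$R_exp) > -1e-12))
  expect_true(all(cc$R_obs >= 0 & cc$R_obs <= 1))
  # R_obs(t) + cumulative competing + event-free survival = 1
  p_c <- cc$d_comp / cc$n_eff
  S_next <- cc$S * (1 - cc$p_target - p_c)
  total <- cc$R_obs + cumsum(cc$S * p_c) + S_next
  expect_true(all(abs(total - 1) < 1e-9))
})

test_that("two-step estimator equals Aalen-Johansen on window-discretised data", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 1000, seed = 42), r)
  el <- apply_eligibility(co)$cohort
  for (tg in c("breast", "other")) {
    sp <- analysis_spec(tg)
    oc <- observed_cif(el, sp, r, cens_adjust = "none")
    aj <- aj_cif_oracle(el, sp, r)
    expect_lt(max(abs(oc$R_obs - aj)), 1e-12)
  }
})

test_that("reference rates equal to truth reproduce the observed curve", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 12000, seed = 6), r)
  el <- apply_eligibility(co)$cohort
  cc <- cif_curve(el, analysis_spec("other"), r, boot = 40, seed = 2)
  se <- (cc$band_hi - cc$band_lo) / (2 * qnorm(0.975))
  z <- cc$excess / pmax(se, 1e-12)
  expect_lt(max(abs(z[cc$n >= 50])), 3)
})

test_that("zero reference rate for the target gives an identically zero expected curve", {
  r <- make_reference_rates()
  z0 <- data.table::as.data.table(r)
  z0[cancer_type == "uterus", rate := 0]
  rz <- rate_table(z0)
  co <- simulate_cohort(sim_config(n = 1500, seed = 14), r)
  el <- apply_eligibility(co)$cohort
  cc <- cif_curve(el, analysis_spec("uterus"), rz)
  expect_true(all(cc$R_exp == 0))
})

test_that("in the rare-event regime the observed/expected ratio approaches the multiplier", {
  r <- flat_rates(0.001, 0.05)
  mult <- data.frame(cancer_type = "A", exposure = "(all)", multiplier = 2)
  co <- simulate_cohort(flat_config(30000, seed = 91, multipliers = mult), r)
  cc <- cif_curve(co, analysis_spec("A"), r)
  t <- 20
  ratio <- cc$R_obs[t] / cc$R_exp[t]
  n_events <- sum(cc$d_target[1:t])
  # MC error of the ratio ~ ratio / sqrt(events); discretisation adds O(lambda)
  tol <- 3 * 2 / sqrt(n_events) + 0.05
  expect_lt(abs(ratio - 2), tol)
})

test_that("bootstrap bands cover the true excess at near-nominal rate (scaled)", {
  # population limit of the discrete two-step curves in the flat world with
  # multiplier 2 (independent recursion oracle)
  l1 <- 0.004; l2 <- 0.05; m <- 2; W <- 10
  q_all <- exp(-(m * l1 + l2))
  p_t <- m * l1 / (m * l1 + l2) * (1 - q_all)       # observed target prob
  p_c <- l2 / (m * l1 + l2) * (1 - q_all)           # observed competing prob
  p_e <- 1 - exp(-l1)                               # expected target prob
  S <- cumprod(c(1, rep(1 - p_t - p_c, W - 1)))
  Se <- cumprod(c(1, rep(1 - p_e - p_c, W - 1)))
  truth <- sum(S * p_t) - sum(Se * p_e)
  r <- flat_rates(l1, l2)
  mult <- data.frame(cancer_type = "A", exposure = "(all)", multiplier = m)
  hits <- 0L
  for (k in 1:30) {
    co <- simulate_cohort(flat_config(3000, seed = 300 + k,
                                      multipliers = mult), r)
    cc <- cif_curve(co, analysis_spec("A"), r, boot = 100, level = 0.95,
                    seed = k)
    ex <- excess_risk(cc, W)
    hits <- hits + as.integer(ex$lo <= truth && truth <= ex$hi)
  }
  # 30 replicates: >= 24/30 compatible with nominal 95% coverage
  expect_gte(hits, 24L)
})
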