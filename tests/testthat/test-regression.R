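# minimal hand-built regression cell table
cell_table <- function(stratum, exposure, events, py) {
  dt <- data.table::data.table(
    stratum = stratum, radiotherapy = exposure, endocrine = 0L,
    chemotherapy = 0L, mastectomy = 0L, events = events, py = py,
    fu_start = 0)
  data.table::setattr(dt, "target", "lung")
  data.table::setattr(dt, "fu_width", 5)
  dt
}

test_that("single stratum, single exposure: fitted rr is the crude rate ratio", {
  tab <- cell_table(stratum = c("s", "s"), exposure = c(1L, 0L),
                    events = c(20L, 10L), py = c(1000, 1000))
  f <- fit_rate_ratios(tab, exposures = "radiotherapy", adjust = FALSE)
  expect_equal(f$rr, 2.0, tolerance = 1e-8)
})

test_that("absorbed fit agrees with explicit stratum dummies (glm)", {
  set.seed(2)
  s <- rep(1:8, each = 4)
  x1 <- rep(c(0L, 1L), 16)
  x2 <- rbinom(32, 1, 0.4)
  py <- runif(32, 50, 200)
  y <- rpois(32, py * exp(-4 + 0.15 * s + 0.5 * x1 - 0.3 * x2))
  f1 <- secondcancer:::poisson_absorbed(y, py, cbind(x1 = x1, x2 = x2), s)
  f2 <- glm(y ~ x1 + x2 + factor(s), family = poisson, offset = log(py))
  expect_lt(max(abs(f1$beta - coef(f2)[c("x1", "x2")])), 1e-6)
  expect_lt(max(abs(sqrt(diag(f1$vcov)) -
                      sqrt(diag(vcov(f2)))[c("x1", "x2")])), 1e-6)
})

test_that("fitted rr matches a direct likelihood maximiser on small tables", {
  y <- c(4L, 9L, 3L, 7L, 2L)
  py <- c(100, 120, 80, 90, 60)
  x <- c(0, 1, 0, 1, 1)
  s <- c(1, 1, 2, 2, 2)
  fit <- secondcancer:::poisson_absorbed(y, py, cbind(x = x), s)
  grid <- optimize(function(b) {
    w <- py * exp(x * b)
    -(sum(y * x * b) - sum(tapply(y, s, sum) * log(tapply(w, s, sum))))
  }, c(-4, 4), tol = 1e-12)
  expect_lt(abs(fit$beta - grid$minimum), 1e-6)
})

test_that("rr is invariant to record duplication and person-time rescaling", {
  tab <- cell_table(stratum = c("a", "a", "b", "b"),
                    exposure = c(1L, 0L, 1L, 0L),
                    events = c(12L, 6L, 9L, 8L), py = c(500, 700, 300, 450))
  f0 <- fit_rate_ratios(tab, exposures = "radiotherapy", adjust = FALSE)
  dup <- rbind(tab, tab)
  data.table::setattr(dup, "target", "lung")
  f1 <- fit_rate_ratios(dup, exposures = "radiotherapy", adjust = FALSE)
  sc <- data.table::copy(tab)[, py := py * 7.3]
  data.table::setattr(sc, "target", "lung")
  f2 <- fit_rate_ratios(sc, exposures = "radiotherapy", adjust = FALSE)
  expect_equal(f1$rr, f0$rr, tolerance = 1e-7)
  expect_equal(f2$rr, f0$rr, tolerance = 1e-7)
})

test_that("zero events in an exposure arm yields a flagged, non-crashing estimate", {
  tab <- cell_table(stratum = rep("s", 2), exposure = c(1L, 0L),
                    events = c(0L, 15L), py = c(800, 900))
  f <- fit_rate_ratios(tab, exposures = "radiotherapy", adjust = FALSE)
  expect_false(f$converged)
  expect_equal(f$lo, 0)
  expect_equal(f$hi, Inf)
})

test_that("the decision rule follows the pre-specified directions", {
  est <- data.table::data.table(
    cancer_type = c("uterus", "breast", "lung", "breast", "lung"),
    exposure = c("endocrine", "endocrine", "radiotherapy", "radiotherapy",
                 "chemotherapy"),
    rr = c(1.14, 0.87, 1.5, 0.80, 1.2),
    p = c(0.003, 0.001, 0.02, 0.001, 0.5))
  expect_equal(decision_rule(est), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("build_regression_table codes BCS as radiotherapy and ER+ as endocrine", {
  w <- make_women(2, surgery = c("bcs", "mastectomy"),
                  radiotherapy = FALSE, er_status = c("unknown", "positive"),
                  endocrine = FALSE, fu_end = 3)
  co <- cohort(w, make_events(integer(), numeric()))
  tab <- build_regression_table(co, analysis_spec("lung"))
  expect_equal(nrow(tab), 2L)  # one cell per woman here (same stratum axes)
  expect_equal(tab[mastectomy == 0L, radiotherapy], 1L)
  expect_equal(tab[mastectomy == 1L, radiotherapy], 0L)
  expect_equal(tab[mastectomy == 1L, endocrine], 1L)
  expect_equal(sum(tab$py), 2 * (3 - 0.25), tolerance = 1e-9)
})

test_that("regression cells reconcile with person-time module totals", {
  r <- make_reference_rates()
  co <- simulate_cohort(sim_config(n = 1200, seed = 44), r)
  el <- apply_eligibility(co)$cohort
  sp <- analysis_spec("lung")
  tab <- build_regression_table(el, sp)
  tl <- collapse_tally(tally(el, sp, r))
  expect_equal(sum(tab$py), tl$py, tolerance = 1e-9)
  expect_equal(sum(tab$events), tl$o)
})

test_that("period split partitions person-time exactly, events at 10y go late", {
  w <- make_women(1, fu_end = 30)
  ev <- make_events(1L, time = 10.0, cancer_type = "lung")
  co <- cohort(w, ev)
  tab <- build_regression_table(co, analysis_spec("lung"))
  sp <- split_by_period(tab, 10)
  expect_equal(sum(sp$late$events), 1L)
  expect_equal(sum(sp$early$events), 0L)
  expect_equal(sum(sp$early$py) + sum(sp$late$py), sum(tab$py),
               tolerance = 1e-12)
  expect_error(split_by_period(tab, boundary = 7), "nest")
})

test_that("an effect planted only after year 10 is detected only in the late period", {
  set.seed(77)
  strata <- data.table::CJ(s = 1:12, fu_start = seq(0, 20, 5), x = 0:1)
  strata[, py := runif(.N, 2000, 4000)]
  strata[, rate := 0.004 * exp(0.08 * s)]
  strata[, rr_true := ifelse(fu_start >= 10 & x == 1, 1.6, 1)]
  strata[, events := rpois(.N, py * rate * rr_true)]
  tab <- data.table::data.table(
    stratum = paste(strata$s, strata$fu_start), fu_start = strata$fu_start,
    radiotherapy = strata$x, endocrine = 0L, chemotherapy = 0L,
    mastectomy = 0L, events = strata$events, py = strata$py)
  data.table::setattr(tab, "target", "lung")
  data.table::setattr(tab, "fu_width", 5)
  sp <- split_by_period(tab, 10)
  fe <- fit_rate_ratios(sp$early, exposures = "radiotherapy", adjust = FALSE,
                        period = "0-9")
  fl <- fit_rate_ratios(sp$late, exposures = "radiotherapy", adjust = FALSE,
                        period = ">=10")
  expect_gt(fe$p, 0.01)
  expect_lt(abs(log(fe$rr)), 0.1)
  expect_lt(fl$p, 0.001)
  expect_gt(fl$rr, 1.3)
})

test_that("LR P values are calibrated under the null (type I ~ 1% at P<0.01)", {
  set.seed(123)
  n_sig <- 0L
  for (k in 1:400) {
    s <- rep(1:10, each = 2)
    x <- rep(c(0L, 1L), 10)
    py <- runif(20, 500, 1500)
    rate <- 0.01 * exp(0.1 * s)
    y <- rpois(20, py * rate)
    tab <- cell_table(stratum = s, exposure = x, events = y, py = py)
    f <- fit_rate_ratios(tab, exposures = "radiotherapy", adjust = FALSE)
    n_sig <- n_sig + as.integer(f$p < 0.01)
  }
  # Bin(400, 0.01): central 99.9% interval is [0, 12]
  expect_lte(n_sig, 12L)
})
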