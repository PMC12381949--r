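# Stratified Poisson regression of second-cancer rates on adjuvant-treatment
# exposures, with the stratum intercepts profiled out ("absorbed") rather than
# fitted as dummies. For the log-linear model
#   events_i ~ Poisson(py_i * exp(alpha_{s(i)} + x_i' beta))
# profiling alpha gives the kernel
#   l(beta) = sum_i y_i x_i'beta - sum_s O_s log(sum_{i in s} py_i e^{x_i'beta})
# whose maximiser, gradient and Hessian involve only within-stratum weighted
# means, so thousands of strata cost nothing. Strata without events drop out.

# Newton-Raphson maximiser of the absorbed Poisson kernel.
# y: event counts; py: person-time; X: model matrix (no intercept);
# stratum: factor. Returns beta, vcov, kernel loglik, convergence flag.
poisson_absorbed <- function(y, py, X, stratum, maxit = 100, tol = 1e-10) {
  if (is.null(dim(X)) || ncol(X) == 0) {
    X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  stopifnot(length(y) == nrow(X), length(py) == length(y))
  stratum <- factor(stratum)
  Os <- rowsum(y, stratum)[, 1]
  keep_s <- names(Os)[Os > 0]
  keep <- stratum %in% keep_s
  y <- y[keep]; py <- py[keep]
  X <- X[keep, , drop = FALSE]
  stratum <- droplevels(stratum[keep])
  Os <- rowsum(y, stratum)[, 1]
  p <- ncol(X)
  if (p == 0) {
    sw <- rowsum(py, stratum)[, 1]
    return(list(beta = numeric(0), vcov = matrix(0, 0, 0),
                loglik = -sum(Os * log(sw)), converged = TRUE))
  }
  kernel <- function(beta) {
    w <- py * exp(drop(X %*% beta))
    sw <- rowsum(w, stratum)[, 1]
    sum(y * drop(X %*% beta)) - sum(Os * log(sw))
  }
  beta <- numeric(p)
  ll <- kernel(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    w <- py * exp(eta)
    sw <- rowsum(w, stratum)[, 1]
    wX <- X * w
    mX <- rowsum(wX, stratum) / sw            # x-bar per stratum
    grad <- colSums(y * X) - colSums(Os * mX)
    H <- matrix(0, p, p)
    for (a in seq_len(p)) {
      wXa <- rowsum(wX * X[, a], stratum) / sw  # E_s[x x_a]
      H[a, ] <- H[, a] <- -colSums(Os * (wXa - mX * mX[, a]))
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    step <- -step
    # step halving on kernel decrease
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      llc <- kernel(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    moved <- max(abs(cand - beta))
    beta <- cand; ll <- llc
    if (moved < tol * (1 + max(abs(beta))) ||
        max(abs(grad)) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 15) break  # separation
  }
  vc <- tryCatch({
    eta <- drop(X %*% beta); w <- py * exp(eta)
    sw <- rowsum(w, stratum)[, 1]
    wX <- X * w
    mX <- rowsum(wX, stratum) / sw
    H <- matrix(0, p, p)
    for (a in seq_len(p)) {
      wXa <- rowsum(wX * X[, a], stratum) / sw
      H[a, ] <- H[, a] <- -colSums(Os * (wXa - mX * mX[, a]))
    }
    v <- solve(-H)
    dimnames(v) <- list(colnames(X), colnames(X))
    v
  }, error = function(e) {
    matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  })
  list(beta = stats::setNames(beta, colnames(X)), vcov = vc, loglik = ll,
       converged = converged)
}

#' Build the event/person-time table for treatment rate-ratio regression
#'
#' Splits each woman's at-risk interval (first-event mode for the target
#' cancer) at follow-up-interval boundaries and aggregates events and
#' person-time into cells cross-classified by stratification axes and
#' exposures. Stratification follows the treatment-analysis convention: age at
#' index diagnosis in 5-year bands, calendar year of diagnosis, time since
#' diagnosis in 5-year intervals, and deprivation fifth. Exposure coding:
#' every woman treated with breast-conserving surgery counts as
#' "radiotherapy recorded", and every woman with ER-positive disease counts
#' as "endocrine recorded".
#'
#' @param x a `cohort` (post-eligibility).
#' @param spec an [analysis_spec()] giving the outcome cancer type.
#' @param age_width age-at-diagnosis band width (years).
#' @param fu_width follow-up interval width (years).
#' @param year_width calendar-year-of-diagnosis group width (years).
#' @return data.table of cells: `stratum`, `fu_start`, exposure indicators
#'   (`radiotherapy`, `endocrine`, `chemotherapy`, `mastectomy`), `events`,
#'   `py`. Cells with zero person-time are dropped.
#' @export
build_regression_table <- function(x, spec, age_width = 5, fu_width = 5,
                                   year_width = 1) {
  iv <- at_risk_intervals(x, spec)
  ivi <- iv[included == TRUE]
  if (nrow(ivi) == 0) stop("no women at risk")
  w <- data.table::as.data.table(x$women)
  need <- c("surgery", "radiotherapy", "endocrine", "er_status",
            "chemotherapy")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("unknown exposure coding: cohort lacks columns ",
         paste(miss, collapse = ", "))
  }
  d <- w[ivi, on = "id"]
  eps <- 1e-9
  # split person-time at follow-up boundaries k * fu_width
  cf <- boundary_cuts(rep(0, nrow(d)), d$entry, d$exit, fu_width)
  pts <- data.table::data.table(
    row = c(seq_len(nrow(d)), cf$idx),
    t = c(d$entry, cf$t))
  data.table::setorder(pts, row, t)
  segs <- pts[, .(row, start = t, end = data.table::shift(t, -1, fill = NA))]
  segs[is.na(end) | c(diff(row) != 0, TRUE), end := d$exit[row]]
  segs <- segs[end - start > eps / 2]
  segs[, fu_start := floor(start / fu_width + eps) * fu_width]
  cells <- segs[, .(py = sum(end - start)), by = .(row, fu_start)]
  # the counted event belongs to the interval of its event time
  # (half-open: an event exactly on a boundary goes to the later interval)
  evrow <- which(d$reason == "event")
  if (length(evrow)) {
    evc <- data.table::data.table(
      row = evrow,
      fu_start = floor(d$event_time[evrow] / fu_width + eps) * fu_width,
      events = 1L)
    cells <- merge(cells, evc, by = c("row", "fu_start"), all = TRUE)
  } else {
    cells[, events := 0L]
  }
  cells[is.na(py), py := 0]
  cells[is.na(events), events := 0L]
  meta <- data.table::data.table(
    row = seq_len(nrow(d)),
    age_band = floor(d$age_dx / age_width + eps) * age_width,
    year_grp = floor((d$year_dx - min(floor(d$year_dx))) / year_width + eps) *
      year_width + min(floor(d$year_dx)),
    imd_fifth = d$imd_fifth,
    radiotherapy = as.integer(d$radiotherapy | d$surgery == "bcs"),
    endocrine = as.integer(d$endocrine | d$er_status == "positive"),
    chemotherapy = as.integer(d$chemotherapy),
    mastectomy = as.integer(d$surgery == "mastectomy"))
  cells <- meta[cells, on = "row"]
  out <- cells[, .(events = sum(events), py = sum(py)),
               by = .(age_band, year_grp, imd_fifth, fu_start,
                      radiotherapy, endocrine, chemotherapy, mastectomy)]
  out <- out[py > 0 | events > 0]
  out[, stratum := paste(age_band, year_grp, imd_fifth, fu_start, sep = "|")]
  data.table::setattr(out, "target", spec$target)
  data.table::setattr(out, "fu_width", fu_width)
  out[]
}

#' Split a regression table at a follow-up boundary
#'
#' Person-time and events are partitioned exactly (the follow-up intervals
#' used in the table nest within the boundary); an event at exactly the
#' boundary belongs to the later period.
#'
#' @param table output of [build_regression_table()].
#' @param boundary follow-up split point in years (default 10).
#' @return list of two tables, `early` (0 to boundary) and `late`
#'   (>= boundary).
#' @export
split_by_period <- function(table, boundary = 10) {
  fw <- attr(table, "fu_width") %||% 5
  if (any(table$fu_start < boundary & table$fu_start + fw > boundary)) {
    stop("follow-up intervals of width ", fw,
         " do not nest within the boundary ", boundary)
  }
  out <- list(early = table[table$fu_start < boundary],
              late = table[table$fu_start >= boundary])
  for (nm in names(out)) {
    data.table::setattr(out[[nm]], "target", attr(table, "target"))
    data.table::setattr(out[[nm]], "fu_width", fw)
  }
  out
}

#' Fit treatment rate ratios by stratified Poisson regression
#'
#' Log-linear Poisson likelihood with log person-time offset and the stratum
#' intercepts absorbed. The adjusted fit includes all exposures plus surgery
#' type simultaneously; the unadjusted fit includes one exposure at a time
#' (plus strata). P values are likelihood-ratio tests of the exposure;
#' intervals are Wald on the log scale. Complete separation (no events in an
#' exposure arm) yields a flagged estimate with an infinite bound, not an
#' error.
#'
#' @param table output of [build_regression_table()].
#' @param exposures exposure columns to report.
#' @param adjust adjusted (all exposures + surgery) or unadjusted fits.
#' @param level confidence level (treatment analyses conventionally 99%).
#' @param cancer_type label attached to the estimates (defaults to the
#'   table's target attribute).
#' @param period follow-up period label for the output.
#' @return data.table of `rate_ratio_estimate` rows: `cancer_type`,
#'   `exposure`, `adjusted`, `period`, `rr`, `lo`, `hi`, `p`, `flagged`,
#'   `converged`.
#' @export
fit_rate_ratios <- function(table,
                            exposures = c("radiotherapy", "endocrine",
                                          "chemotherapy"),
                            adjust = TRUE, level = 0.99,
                            cancer_type = NULL, period = "all") {
  if (is.null(cancer_type)) {
    cancer_type <- attr(table, "target") %||% NA_character_
  }
  miss <- setdiff(exposures, names(table))
  if (length(miss)) {
    stop("unknown exposure coding: ", paste(miss, collapse = ", "))
  }
  adj_cols <- union(exposures, "mastectomy")
  z <- stats::qnorm(1 - (1 - level) / 2)
  fit_one <- function(cols, drop_col) {
    X <- as.matrix(table[, cols, with = FALSE])
    full <- poisson_absorbed(table$events, table$py, X, table$stratum)
    X0 <- as.matrix(table[, setdiff(cols, drop_col), with = FALSE])
    red <- poisson_absorbed(table$events, table$py, X0, table$stratum)
    lr <- 2 * (full$loglik - red$loglik)
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    b <- full$beta[drop_col]
    se <- sqrt(full$vcov[drop_col, drop_col])
    sep <- !full$converged || !is.finite(se) || abs(b) > 15
    list(rr = exp(b),
         lo = if (sep) 0 else exp(b - z * se),
         hi = if (sep) Inf else exp(b + z * se),
         p = p, converged = !sep)
  }
  res <- lapply(exposures, function(ex) {
    cols <- if (adjust) adj_cols else ex
    f <- fit_one(cols, ex)
    data.table::data.table(cancer_type = cancer_type, exposure = ex,
                           adjusted = adjust, period = period,
                           rr = f$rr, lo = f$lo, hi = f$hi, p = f$p,
                           level = level, converged = f$converged)
  })
  out <- data.table::rbindlist(res)
  out[, flagged := decision_rule(out)]
  out[]
}

#' Pre-specified significance decision rule for treatment associations
#'
#' An association is flagged when the rate ratio exceeds 1 with P < 0.01 --
#' except for contralateral breast cancer after endocrine therapy, where the
#' anticipated (protective) direction is a rate ratio below 1 with P < 0.01.
#'
#' @param estimates data.frame with columns `rr`, `p`, `exposure`,
#'   `cancer_type`.
#' @param p_threshold significance threshold (default 0.01).
#' @return logical vector of decision flags.
#' @export
decision_rule <- function(estimates, p_threshold = 0.01) {
  protective <- estimates$exposure == "endocrine" &
    estimates$cancer_type %in% c("breast", "contralateral_breast",
                                 "contralateral breast")
  ifelse(protective,
         estimates$rr < 1 & estimates$p < p_threshold,
         estimates$rr > 1 & estimates$p < p_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
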