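# secondcancer

Excess risk of second primary cancers in breast-cancer survivor cohorts.

Women treated for early invasive breast cancer carry a modestly higher risk
of further primary cancers — a new cancer in the contralateral breast, and
cancers of other organs, some associated with adjuvant radiotherapy,
endocrine therapy or chemotherapy. This package implements, as a reusable
and fully tested pipeline, the epidemiological machinery needed to quantify
that excess from person-level cohort data and an external
("national") incidence-rate table:

* **Eligibility filtering and Lexis person-time splitting.** Follow-up runs
  from 3 months after diagnosis to the earliest of a qualifying second
  cancer, the 85th birthday, death, or administrative censoring, and is
  split into segments homogeneous in attained-age band × calendar year ×
  deprivation fifth (half-open intervals, boundary events to the later
  stratum).
* **Standardised incidence ratios and absolute excess rates.**
  SIR = O/E and AER = (O − E)/woman-years per 10 000, with exact Poisson
  (Garwood) intervals treating expected counts as fixed. Reference breast
  rates are halved for the contralateral analysis (one breast at risk).
* **Cumulative risk under competing events.** A two-step estimator on
  annual windows: the probability of the target cancer in each window,
  times the probability of reaching that window free of any second cancer
  or death, summed over windows — equal to the Aalen–Johansen estimator on
  window-discretised data. Its "expected" counterpart substitutes the
  general-population hazard for the target cause while keeping the cohort's
  own competing risks, so observed-minus-expected risk stays consistent
  with the SIR. Pointwise bands come from a bootstrap over women.
* **Stratified Poisson rate-ratio regression** for treatment exposures,
  with stratum intercepts profiled out analytically (thousands of strata at
  no cost), likelihood-ratio P values, Wald 99% intervals, follow-up splits
  at 10 years, and the pre-specified decision rule (rate ratio > 1 and
  P < 0.01; reversed for contralateral breast cancer after endocrine
  therapy).
* **Attribution.** Attributable fraction in the exposed, (RR − 1)/RR,
  converted to excess cancer counts and summed under trial-consistency
  scenarios.
* **A synthetic cohort generator** with piecewise-constant cause-specific
  hazards (exact inverse-transform sampling, no time discretisation) and
  configurable ground-truth multipliers, so every estimator is validated by
  parameter recovery. Real cancer-registry records are confidential; the
  generator is the test bed.

See `vignettes/second-cancer-excess-risk.Rmd` for the methods account.

## Worked example

```r
library(secondcancer)

rates <- make_reference_rates()              # synthetic national rate table
mult  <- data.frame(cancer_type = c("lung", "breast"),
                    exposure    = c("chemotherapy", "endocrine"),
                    multiplier  = c(1.6, 0.8))  # planted ground truth
coh <- simulate_cohort(sim_config(n = 20000, seed = 2024,
                                  multipliers = mult), rates)
el  <- apply_eligibility(coh)

sir_analysis(el$cohort, rates, c("breast", "lung", "uterus"))
#>    cancer_type     O     E     PY    sir sir_lo sir_hi     aer
#> 1:      breast   340 374.7 259153 0.9075 0.8136  1.009 -1.3377
#> 2:        lung   265 218.6 259153 1.2125 1.0709  1.368  1.7922
#> 3:      uterus   103 109.3 259153 0.9426 0.7693  1.143 -0.2422
```

Lung cancer shows the planted excess (SIR 1.21, 95% CI 1.07–1.37; AER 1.79
per 10 000 woman-years): the chemotherapy multiplier of 1.6 acts on the
~45% of treated women. Breast and uterus are compatible with their null
(the endocrine multiplier 0.8 pulls the contralateral SIR slightly below
1). The cumulative-risk curves with bootstrap bands:

```r
cc <- cif_curve(el$cohort, analysis_spec("breast"), rates,
                boot = 200, seed = 7)
as.data.frame(cc)[c(10, 20), c("window", "n", "d_target", "R_obs",
                               "R_exp", "excess", "band_lo", "band_hi")]
#>    window     n d_target  R_obs  R_exp   excess  band_lo  band_hi
#> 10     10 13838       19 0.0113 0.0123 -0.00101 -0.00254 0.000545
#> 20     20  3736        7 0.0247 0.0260 -0.00128 -0.00411 0.002503
```

By 20 years, 2.47% of women have a contralateral breast cancer against
2.60% expected — the small deficit matches the protective endocrine
multiplier. The treatment regression recovers the planted chemotherapy
effect and flags it under the decision rule:

```r
tab <- build_regression_table(el$cohort, analysis_spec("lung"))
fit_rate_ratios(tab, adjust = TRUE, level = 0.99)
#>        exposure    rr    lo    hi       p flagged
#> 1: radiotherapy 1.347 0.772  2.35 0.17299   FALSE
#> 2:    endocrine 0.955 0.686  1.33 0.72153   FALSE
#> 3: chemotherapy 1.461 1.039  2.06 0.00439    TRUE
```

and the attribution step converts it to excess cancers (AF 0.32 × 124
exposed cases ≈ 39 of the cohort's 708 second cancers, 5.5%; the
"share of population excess" denominator is near zero in this synthetic
world because all other multipliers are 1):

```r
att <- excess_counts(fit_rate_ratios(tab, adjust = TRUE), cnt,
                     total_second_cancers = sum(sir$O),
                     total_population_excess =
                       population_excess(sum(sir$O), sum(sir$E)))
#> Totals: 0 (trial-consistent) to 39 (all flagged)
```

`run_pipeline(run_config(...))` chains all stages and writes every table as
CSV with a configuration hash; `inst/cli/secondcancer` exposes the same as
a command line (`simulate`, `tabulate`, `sir`, `cif`, `regress`,
`attribute`, `all`).

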