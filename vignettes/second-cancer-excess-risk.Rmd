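---
title: "Methods: quantifying excess second-cancer risk after early breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying excess second-cancer risk after early breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondcancer)
```

## The problem

Women treated for early invasive breast cancer remain at risk of further
primary cancers: a new cancer in the contralateral breast, and cancers of
other organs, some of which may be promoted by adjuvant radiotherapy,
endocrine therapy or chemotherapy. Quantifying that risk in a way that is
useful to survivors requires three distinct comparisons:

1. **External rate comparison.** Person-time in the cohort is classified by
   attained age, calendar year and deprivation fifth (Lexis splitting), and
   observed event counts are compared with those expected under
   general-population incidence rates: the standardised incidence ratio
   $\mathrm{SIR} = O/E$ and the absolute excess rate
   $\mathrm{AER} = (O-E)/\mathrm{woman\mbox{-}years}$, scaled per 10 000.
2. **Absolute cumulative risk under competing events.** The probability of a
   given second cancer by time $t$ since entry, accounting for the competing
   risks of any other second cancer and of death, together with the
   counterpart *expected* cumulative risk a general-population woman would
   face under the same competing risks.
3. **Internal comparisons.** Poisson rate-ratio regression of second-cancer
   incidence on adjuvant-treatment exposures within the cohort, finely
   stratified, followed by attributable-fraction accounting of how many
   second cancers the flagged associations represent.

The package implements all three, plus a synthetic cohort generator with
known ground truth so that every estimator can be validated by parameter
recovery. Real registry records are confidential; the generator is the
package's test bed, not a substitute for data.

## Person-time and eligibility

A woman enters the at-risk population 3 months (0.25 years, with months
defined as 1/12 year throughout) after the diagnosis of her index breast
cancer, and leaves at the earliest of: her first qualifying second-cancer
event, her 85th birthday, death, or the administrative censoring date.
Eligibility filters (age 20--75 in completed years at diagnosis, at least 3
months of follow-up, invasive index morphology, no second invasive cancer
within 3 months, non-metastatic, no neoadjuvant therapy) are applied
sequentially and each rule's exclusion count is reported, so the filter
reproduces a study flow chart. Every rule can be toggled.

Conventions worth stating precisely:

* All stratum intervals are half-open $[\mathrm{start}, \mathrm{end})$: an
  event or birthday exactly on a boundary belongs to the later stratum.
  This is the standard Lexis convention and removes double counting.
* Attained-age bands default to 5 years and calendar strata to single
  years; both are configurable, since registry analyses agree on the three
  stratification axes but not on canonical widths.
* Censoring at the 85th birthday is absolute: follow-up ends there even if
  events occur later.
* Analyses of invasive cancers ignore non-invasive (in situ) events
  entirely; analyses of non-invasive outcomes censor at any invasive
  cancer. Ipsilateral second breast cancers are never counted as outcomes
  (they cannot be reliably distinguished from recurrence) but do censor
  follow-up; second breast cancers of unknown laterality are grouped with
  contralateral ones.
* Women whose interval is empty (e.g. diagnosis within 3 months of the 85th
  birthday, or a qualifying event before entry) are dropped from tallies
  but retained in a reconciliation log.
* Time is continuous in years internally; ages and diagnosis dates sit on a
  1/12-year (whole-month) grid, and no day-level calendar arithmetic (leap
  years, month lengths) is attempted. The analysis strata are annual or
  5-yearly, so finer resolution would add nothing testable.

## SIR and AER intervals

Observed counts are modelled as Poisson with expected counts fixed.
Intervals are exact Garwood intervals obtained from chi-square quantiles,
$[\tfrac12\chi^2_{\alpha/2}(2O),\ \tfrac12\chi^2_{1-\alpha/2}(2O+2)]$,
divided by $E$; AER intervals transform the same Poisson interval with $E$
and person-time fixed, so the SIR interval excludes 1 exactly when the AER
interval excludes 0. Published registry analyses rarely state their exact
interval recipe; Garwood is the conservative standard choice and is recorded
in the output metadata, with the caveat that independently published interval
endpoints for the same counts could differ in the third decimal. For the contralateral
analysis, reference breast rates are halved: only one breast remains at
risk.

## The two-step cumulative-risk estimator

Follow-up since entry is divided into annual windows $w = 1, 2, \dots$.
With $n(w)$ women at risk at the window start, $d(w)$ target events and
$c(w)$ competing events (any other qualifying cancer, or death) in the
window,

$$p(w) = d(w)/n^*(w), \qquad S(1) = 1,\qquad
  S(w{+}1) = S(w)\,\bigl(1 - \tfrac{d(w)+c(w)}{n^*(w)}\bigr),$$
$$R_\mathrm{obs}(t) = \sum_{w \le t} S(w)\, p(w).$$

$n^*(w)$ applies the actuarial within-window censoring adjustment (a woman
censored inside the window counts half a unit); the annual-window formulation
leaves within-window censoring open, so the adjustment is configurable
and switching it off makes the estimator *identical* to the Aalen--Johansen
estimator computed on window-discretised data — a property the test suite
checks to $10^{-12}$.

The **expected** curve replaces only the target-cause hazard: $\hat e(w)$
is the person-time-weighted mean reference rate of the target cause over
the women actually at risk in window $w$ (halved breast rates for the
contralateral analysis), converted to a window probability
$1 - e^{-\hat e(w)}$, while the competing hazard in the survival recursion
stays the cohort's own. This is a deliberate, literal reading of "population
rates under the cohort's competing risks": it keeps the difference between
observed and expected cumulative risks consistent with the SIR (in the
rare-event limit, cumulative excess over cumulative expected approaches
$\mathrm{SIR}-1$; a simulation test checks this). The alternative of using
the fully observed survival in the expected curve is available behind the
`expected_survival = "observed"` flag for sensitivity.

Confidence bands are pointwise percentile bands from a nonparametric
bootstrap over women (default 500 replicates; reference rates fixed), a
choice made here because no closed-form band is standard for the coupled
observed/expected construction. Greenwood-type formulas were
deliberately not used: the excess curve couples the observed and expected
curves through shared competing-event terms, which the woman-level
bootstrap handles automatically.

## Treatment rate-ratio regression

The treatment analysis fits a log-linear Poisson model with a log
person-time offset, stratified by age at diagnosis (5-year bands), calendar
year of diagnosis, time since diagnosis (5-year intervals by default, width
configurable down to single years) and deprivation fifth. Exposure coding
follows the registry convention for incompletely recorded treatments: all
women with breast-conserving surgery
count as radiotherapy-recorded, and all women with ER-positive disease
count as endocrine-recorded.

With thousands of strata, one dummy per stratum is wasteful and fragile, so
the stratum intercepts are profiled out analytically: for strata $s$ with
event totals $O_s$,

$$\ell(\beta) = \sum_i y_i x_i'\beta
  - \sum_s O_s \log\Bigl(\sum_{i \in s} \mathrm{py}_i e^{x_i'\beta}\Bigr),$$

maximised by Newton iteration on within-stratum weighted means (strata with
no events drop out, as in conditional likelihood). The absorbed fit is
tested to agree with explicit stratum dummies via `glm` to $10^{-6}$ on
small instances, and against a direct likelihood grid search on tables of
up to five cells. P values are likelihood-ratio tests; intervals are Wald
on the log scale (99% for treatment analyses by convention). Complete
separation returns a flagged estimate with an infinite bound rather than an
error.

The pre-specified decision rule flags associations with rate ratio above 1
and $P < 0.01$ — except contralateral breast cancer after endocrine
therapy, where the anticipated protective direction (rate ratio below 1,
$P < 0.01$) is flagged.

## Attribution

For each flagged association the attributable fraction in the exposed is
$(\mathrm{RR}-1)/\mathrm{RR}$, and the excess count is that fraction times
the observed number of target events among exposed women (negative for the
protective endocrine association). Excess counts are summed under two
scenarios — associations consistent with randomised-trial evidence only,
and all flagged associations — and reported as a range, together with their
share of all second cancers and of the excess over the general population
($O_\mathrm{total} - E_\mathrm{total}$). Trial consistency is a
configuration lookup; the shipped default marks radiotherapy with
contralateral breast and lung cancer, endocrine therapy with uterine and
(protectively) contralateral breast cancer, and chemotherapy with acute
leukaemias.

## The synthetic cohort generator

`simulate_cohort()` draws each woman's event history from piecewise-constant
cause-specific hazards: reference rate of the cause in her current stratum
times a configurable multiplier for her exposures. Within each
constant-hazard segment the time to the next event is drawn exactly by
inverse transform on the exponential distribution (no time stepping), the
cause is drawn proportionally to the cause-specific hazards, and the first
event wins; simulation continues past a first cancer (same hazards, up to a
configurable cap) so that "any time" sensitivity analyses have something to
count.

Default parameters state a world resembling the marginal structure of a
1993--2016 English cohort followed to 31 October 2021: age, diagnosis
period, deprivation and tumour-covariate distributions with explicit
"unknown" levels; breast-conserving surgery for 63% with radiotherapy
following surgery type; endocrine therapy following ER status; chemotherapy
declining with age at diagnosis and clustering with radiotherapy (the two
confounding-by-indication knobs); second breast events 86% contralateral,
11% ipsilateral, 3% unknown laterality, 15% non-invasive. Reference rates
are log-linear in attained age (doubling every 14 years for cancer
incidence and 8 years for mortality around age 62.5) with a 4% gradient per
deprivation fifth; these shapes are a functional stand-in — no attempt is
made to match England's actual national rates, the cohort's covariate joint
distribution, or genetic/familial clustering, so a green test establishes
estimator correctness under the stated hazard model, not realism of any
particular rate.

Two calibration choices deserve note:

* **Contralateral ground truth.** The reference table describes invasive
  breast-cancer incidence across both breasts. The generator scales the
  second-breast-event hazard so that the hazard of a *countable* event
  (invasive and contralateral or of unknown laterality) is exactly half the
  population rate. Under that stated world the null contralateral SIR
  against halved reference rates is 1, and a configured breast multiplier
  is recovered as the contralateral SIR.
* **Endocrine under-recording** is emulated by masking the recorded flag
  with a configurable probability after simulation; the truth (which drives
  hazards) is retained alongside, so tests can probe the effect of
  under-recording without changing it.

Eligibility-violation probabilities default to zero: the generator emulates
the analysed, post-exclusion cohort, with knobs available for testing the
filter itself.

## Numerical choices and degenerate inputs

* Boundary classification adds $10^{-9}$ years before flooring, so values
  that are exact grid points by construction classify into the later
  stratum deterministically; segment lengths are required to exceed half
  that tolerance.
* Segment sums are exact partitions: woman-years reproduce interval lengths
  to $10^{-9}$, and the daily-step brute-force oracle (1/360-year steps on
  the whole-month grid) agrees to $10^{-6}$.
* A rate-table cell missing for any queried stratum aborts with the cell
  named; zero rates are legal (they switch a hazard off).
* Multipliers must be non-negative; zero is allowed deliberately (the
  zero-hazard degenerate case is part of the test surface) and negative
  values are configuration errors.
* In `sir_with_ci`, $O = 0$ yields a lower bound of exactly 0; $E \le 0$ or
  $\mathrm{PY} \le 0$ are errors rather than silent NaNs.
* Window tallies with events recorded while nobody is at risk are rejected
  as inconsistent.

## What the tests do and do not establish

The acceptance suite checks (i) the published self-contained arithmetic
(excess shares, excess counts, attribution percentages, interval width at
the published scale); (ii) closed-form recovery of the competing-risks CIF
at $n = 100\,000$; (iii) exact equivalences against independent oracles
(Aalen--Johansen, daily-step Lexis accumulation, numerical inversion of the
Poisson distribution); (iv) parameter recovery of planted SIR multipliers
and treatment rate ratios, including separation of adjusted from unadjusted
estimates under planted confounding; and (v) null calibration (SIR near 1,
likelihood-ratio type-I error near 1% at $P < 0.01$ over 1000 replicates,
within binomial error). Some module-level properties stated at larger
scales (bootstrap band coverage, interval coverage) are exercised at
reduced replicate counts and sample sizes to keep the default test run
within budget; the scaling is noted in the corresponding test files.

Because real registry inputs are confidential, no test reproduces any real
cohort's headline estimates; the synthetic world is the package's ground
truth and parameter recovery is the fidelity standard.

## Known limitations

* No day-precision calendar handling; no left truncation other than the
  3-month entry.
* The expected-curve construction and the exact-interval recipe are
  principled choices among under-specified published conventions;
  third-decimal differences from other implementations are possible.
* Attribution totals carry no uncertainty interval (no standard construction
  exists for these sums).
* No propensity-score machinery and no time-varying treatment modelling;
  the regression estimates are stratified associations, not causal effects.
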