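---
title: "Measuring schedule adherence and vaccination timeliness in birth cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring schedule adherence and vaccination timeliness in birth cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxtiming)
```

## The problem

National vaccine-coverage figures are usually cross-sectional: they say what
fraction of children have a dose by some age, but not *when* doses were
given, how delays compound across a multi-dose series, or whether children
who miss a dose are lost to care or attending and declining. Prospective
birth cohorts followed through a clinic can answer those questions, but they
need analysis machinery that handles staggered enrolment, attrition, and
right-censoring honestly. This package provides that machinery for
three-dose infant series such as DTP under the WHO EPI schedule, with the
Zambian 6-10-14-week calendar built in.

## The schedule model

A schedule is declarative: per dose, a target age and an admissible window
in whole days of age (day of birth = age 0, boundaries inclusive), plus a
minimum first-dose age and a minimum inter-dose interval. The built-in
schedule targets 42/70/98 days with windows 41--69, 70--97 and 98--127 days,
a 42-day minimum first-dose age and a 28-day minimum interval. Window 1
opens one day before the target to absorb day-level uncertainty in birth and
administration timing; ages of 40 days or less are *early*. Different
national calendars load from a YAML file (see
`system.file("extdata", "zambia_epi_dtp.yaml", package = "vaxtiming")`).

Two conventions deserve note. First, the third window's upper bound is 127
days by default, with 126 available as a configuration
(`zambia_epi_schedule(window3_end = 126)`); both conventions circulate for
this schedule and the difference moves only doses administered on exactly
day 127. Second, all percentages in printed tables are rounded to one
decimal, half away from zero (`round_half_away()`), the convention under
which every tabulated cell recomputes exactly from its integer numerator and
denominator; base R's round-half-to-even disagrees on exact halves.

## Trajectory classification

`classify_infant()` is a small state machine over one infant's scheduled
visits and dose events, all reduced to integer ages:

* **visited** in window *k*: at least one *scheduled* visit age inside the
  window. Acute/unscheduled visits are excluded from window denominators.
* **received** in window *k*: at least one dose event (any dose number)
  inside the window. Two doses may legitimately fall in one window.
* **up-to-date** at window *k*: the infant possesses at least *k* doses by
  the window's last day *and* was up-to-date at window *k − 1*. The
  definition is possession-based: an early dose still counts toward
  up-to-date status, because the metric penalises lateness, not earliness.
  Once a window is missed the status is never regained, even if cumulative
  counts later catch up — catch-up doses raise cumulative coverage but not
  timeliness.
* **unvaccinated** at window *k*: zero cumulative doses by the window's last
  day.
* per dose: **early** (age at or below the early cutoff) and **compressed**
  (spacing from the previous dose below the minimum interval; never defined
  for dose 1). The compression threshold is configurable, and
  `compression_summary()` reports infant- and event-level counts at several
  thresholds (28/25/20 days by default) because published summaries differ
  in which bound they quote.

Infants with no scheduled visits are excluded before classification
(`attending_set()`); attending infants are on-study from enrolment to their
last scheduled visit. Note that the window-stratified table and the
cumulative table answer different questions with different denominators: an
infant can receive a dose in a window it never *visited* in (off-visit
vaccine-card records are allowed), so cumulative dose counts can exceed the
per-window received counts among visitors. Both statistics are exposed
rather than reconciled.

## Delay estimation under two censoring assumptions

For dose *k*, each attending infant contributes either an event (dose age)
or a right-censoring (last scheduled visit age). The cumulative
administration probability is estimated two ways:

* **standard**: the product-limit estimator, `1 − S(age)` from
  `survival::survfit()`. This assumes infants lost to follow-up go on being
  vaccinated at the same rate as those still observed — optimistic when the
  study clinic is the community's only provider.
* **worst case**: censored infants are assumed never vaccinated; the curve
  is exactly (infants with the dose by age *a*) / (all attending infants).
  It is a lower envelope of the standard curve and may plateau below 1.

Delay quantiles invert the curve with the left-continuous generalised
inverse — the smallest age at which the probability reaches *q* — minus the
dose's target age. Negative delays (vaccination before target) are
preserved. Under worst-case censoring upper quantiles can be unattainable;
they are reported with an explicit `attained = FALSE` flag rather than
coerced. Ties between events and censorings at one age follow the usual
convention (events first). The standard curve is cross-checked in the test
suite against an independent brute-force risk-set oracle on ~1000 random
small cohorts, and the worst-case curve against its closed form.

## Covariate screening

`covariate_screen()` crosses binary (or median-dichotomised numeric)
roster covariates with three end-of-study outcomes — unvaccinated, at least
one dose, full series — as unadjusted relative risks with Katz log-normal
95% intervals and Wald p-values. Zero cells receive the Haldane–Anscombe
0.5 correction (flagged); degenerate margins yield `defined = FALSE`
rather than errors. No multiplicity correction is applied: with dozens of
cells, scattered nominally significant ratios are expected under the null,
and the output is a screen, not a set of confirmatory tests.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates cohorts with the structure the analysis
assumes: staggered calendar enrolment (uniform births over ~10 months,
enrolment at about one week of age), six scheduled visits at two-week
intervals from 4 to 14 weeks with a hard ceiling of 126 days, per-visit
attendance, memoryless per-visit dropout, a persistent hesitant subgroup
that attends but never vaccinates, and non-negative right-skewed visit
delays (integer-rounded gamma, default shape 1.5, scale 1.69, median ≈ 2
days).

Two mechanisms matter for realism:

* **Appointment rescheduling.** A pending dosing visit is scheduled no
  earlier than the previous dose plus the minimum interval, as a clinic
  would rebook a late infant. Because the target gap between doses equals
  the minimum interval, a dose-1 delay of *d* days propagates fully into
  dose 2's earliest opportunity, and fresh visit delays add on top. This is
  what makes median delays grow with dose number (the 2-3/5-6/9-day pattern
  of the real-world preset) without any dose-specific delay parameters.
  Realised visit ages are strictly increasing within an infant.
* **Schedule violations.** With small probability a visit happens a few
  days (≤ 7) before schedule and staff administer anyway; this is the only
  source of early (35–41 d) and compressed (21–27 d spacing) doses, since
  visit delays are otherwise non-negative.

The real-world preset (`sim_config_realworld()`) fixes: 24% never-attend,
per-visit attendance 0.93, dropout hazard 0.07/visit, hesitancy 0.06,
violation probability 0.04. These reproduce a cohort in which roughly
three-quarters of attenders remain at the third window, first-dose coverage
sits in the high 80s–low 90s, and worst-case upper quantiles for the final
dose are unattainable. A memoryless dropout hazard cannot simultaneously
match very low early attrition and substantial late attrition, so the
preset is a compromise; real cohorts show age-varying dropout.

The generator deliberately does **not** emulate: seasonality or clinic
capacity, correlated covariate-outcome structure (covariates are drawn
independently, so risk screens should cover the null), partial hesitancy,
age-varying dropout, or the paper-trail messiness of real registries
(duplicate records, date errors). Passing tests therefore demonstrate the
*estimators'* correctness and calibration under the stated generative
model, not that the model captures every feature of field data.

## Numerical and testing choices

* Ages are whole-day integer differences; dates are ISO-8601 calendar
  dates. Deidentification (`deidentify()`) shifts every date of an infant
  by one uniform ±3-day offset, which leaves all ages — hence every
  analytic output — bit-identical; this invariance is tested end-to-end.
* The classifier is verified against an exhaustive brute-force enumerator
  over ~9500 visit/dose patterns spanning every boundary age (36–128 d).
* Parameter recovery runs at n = 5000 infants (hesitancy within 3
  Monte-Carlo SE; survival-estimated median first-dose delay within 1 day
  of generator truth). The hesitancy estimator — the zero-dose fraction of
  infants attending into the last window — is unbiased under dropout,
  which is independent of hesitancy, but not under per-visit
  non-attendance, which delays non-hesitant infants' dosing visits past
  the window-3 threshold differentially; the recovery test therefore uses
  full attendance with dropout.
* Pipeline-level tests use cohorts of 150–2000 infants so the full suite
  runs in about two minutes.

## Limitations

Classification is purely observational: it cannot distinguish a missed dose
from an unrecorded off-site dose, and post-study catch-up is invisible.
The worst-case curve is a bound, not an estimate; the truth lies between
the two curves. Relative risks are unadjusted and the covariate codings
(median splits) are pragmatic defaults, not substantive choices.
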