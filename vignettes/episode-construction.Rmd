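---
title: "Constructing episodes of illness from primary-care EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing episodes of illness from primary-care EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrepisodes)
```

## The problem

Routine general-practice EHRs record morbidity in three forms: ICPC-coded
*episodes of care* (bundles of encounters, prescriptions, and interventions
for one health problem), loose single coded encounters, and diagnosis-coded
prescriptions. For morbidity rates we need *episodes of illness* — the
interval from onset of symptoms to their complete resolution — and those are
not what GPs record. Three recording habits stand in the way:

* episodes of care are rarely closed when the patient is cured; they remain
  open or are auto-closed by the EHR system after a long time;
* GPs may open several episodes of care for the same problem;
* encounters are sometimes filed under the wrong episode of care, and many
  encounters sit outside any episode.

`ehrepisodes` implements a deterministic construction that is robust to all
three, plus the denominator machinery (person-time from quarterly
enrollment claims) needed to turn episode counts into rates.

## The model

Every ICPC-1 symptom or disease code (component numbers 01–29 and 70–99;
process codes 30–69 are excluded throughout) carries a disease category
with a **contact-free interval** (CFI): the period within which a patient
with a persisting complaint would likely revisit the GP. Acute codes use 4,
8, or 16 weeks; long-lasting reversible diseases use 1 year; chronic
diseases are treated as irreversible and have no CFI. In day units the
intervals are 28, 56, 112, and 365, with half-intervals 14, 28, 56, and 182
(`floor(CFI / 2)`; the categories are defined in weeks/years, days are
needed for date arithmetic).

For one patient and code with cleaned, de-duplicated contact dates, a gap
of **at least** one CFI between consecutive contacts starts a new episode
of illness; each episode then runs from its first contact to its last
contact plus half the CFI. The recovery date is unknown but lies between
the last contact and one full CFI after it (otherwise a further contact
would have occurred), so half the interval is the natural point estimate.
On the group level over- and under-estimation of individual recovery dates
average out; the package targets population rates, not individual episode
durations. Chronic codes form exactly one episode per patient, starting at
the earliest of the pre-study diagnosis date and the first contact and
ending only at death or end of observation.

### Numerical choices and tie-breaks

* **Tie rule.** A gap *exactly* equal to the CFI starts a new episode: the
  interval definition says a period of 4 weeks between encounters yields a
  new episode, and `split_contacts(c(0, 28), 28)` returns two runs. The
  connected-components oracle (`oracle_split()`, an igraph re-derivation
  used only for verification) applies the same rule via strict-inequality
  edges.
* **Provisional closes.** Mid-algorithm, an episode is provisionally closed
  one full CFI after its last contact; the committed stop uses the half
  interval. The provisional close is exposed as a `provisional_stop` trace
  column (`build_episodes(..., trace = TRUE)`) because it is useful when
  debugging splits, but plays no role in rates.
* **Stop capping.** Stop dates are capped at the end of the observation
  interval containing the last contact (`censored = TRUE`), keeping
  episodes inside observed person-time. Contacts falling in registration
  gaps are capped against the nearest interval end, with a warning and an
  audit trail — they indicate data problems rather than a modelling case.
* **Calendar conventions.** All intervals are closed on both ends; ISO 8601
  dates throughout; registration quarters map to civil quarters (Q1 =
  Jan 1–Mar 31, ...). Week *t* of the worked examples is day *7t*.
* **Person-time.** A registered quarter contributes exactly 0.25
  person-years; only quarters truncated by death are counted in days (over
  365.25). This keeps the headline denominator equal to registered
  quarters / 4 while handling death at day resolution. When subtracting
  in-year episode time for at-risk denominators, a patient's diseased time
  is capped at their own observed person-time in the year — in leap years
  a day count over 365.25 can otherwise exceed a quarter-counted year by a
  fraction of a day.

## Cleaning rules

Symptoms of a disease are legitimately recorded within that disease's
episode of care, so an encounter is flagged as *incorrectly recorded* only
when it is disease-coded, its host episode is disease-coded, and the codes
differ. Flagged encounters are extracted as standalone contacts under their
own code; we make no attempt to re-attribute them to the "right" episode —
the interval logic will merge them with any genuine contacts for the same
disease. A disease-coded encounter inside a *symptom*-coded episode of care
is deliberately treated as correct and recoded to the symptom code: the
flagging rule is defined only for disease-within-disease, and widening it
would be a different (and clinically debatable) cleaning policy.

Every episode-of-care *start* date counts as a contact even when no
encounter was recorded that day (e.g. an episode opened from a specialist's
letter); recorded *stop* dates are read but never used, because in routine
data they mostly reflect EHR-system auto-closing. Same-day duplicates for
one (patient, code) collapse to a single contact before episode
construction — repeat prescriptions on one day carry no information for
interval logic. `merge_contacts()` returns the full per-event contact file
(one contact per coded input event, so nothing is lost) together with an
audit: counts by origin, the flagged count and its fraction of all coded
encounters and prescriptions, and the most-flagged codes.

## Practice quality screening

`evaluate_practices()` applies three inclusive thresholds over the study
period: at least 500 listed patients; complete morbidity registration,
operationalised as at least 46 recorded weeks in *every* study year (a
"recorded week" is an ISO week containing at least one encounter of any
kind — the criterion is stated in weeks without defining them, and ISO
weeks are the natural calendar-stable choice); and at least 70% of
encounters carrying an ICPC code. The coding fraction is computed over the
whole period rather than per year: per-year coding levels in routine data
are noisy in small practices and the criterion is a practice-level
inclusion gate, not a yearly one.

## Rates

For a target calendar year:

* **Incidence** counts episodes whose start date falls in the year (one
  person can contribute several acute episodes). The denominator is total
  person-years for acute codes, and *at-risk* person-years (total minus
  the code's in-year episode time) for long-lasting and chronic codes —
  for acute codes the at-risk time is nearly the total anyway, and
  patients can remain at risk during an active episode (fractures).
  Chronic episodes with pre-study onsets are never incident.
* **Prevalence** counts *distinct persons* with an episode overlapping the
  year, over total person-years. Counting persons rather than episodes is a
  deliberate design decision: with episode counting, acute prevalence could
  never fall below acute incidence over the same denominator, yet short
  episodes plus multiple episodes per person per year make exactly that
  ordering the expected one. The person/episode asymmetry is therefore
  baked into `prevalence_rate()` vs `incidence_rate()` and documented here
  rather than hidden.
* **Episode summaries** (`episode_summary()`) select episodes with a stop
  date after December 31 of the prior year and report mean durations
  clipped to the year.
* **Sensitivity** (`cfi_sweep()`) rebuilds one code's episodes under a grid
  of interval lengths. Lengthening the interval can only merge runs, so the
  set of episode start dates shrinks (incidence non-increasing) while every
  covered day stays covered (prevalence non-decreasing). For long-lasting
  diseases the 1-year interval is kept fixed; a 2-year interval changes
  incidence very little while doubling the recovery-time overshoot risk.

## The synthetic EHR generator

`simulate_ehr()` emulates a small general-practice registry: practices and
patients, quarterly enrollment claims over a three-year horizon, true
disease episodes per (patient, code) from a renewal process (exponential
waiting times at the code's annual hazard, gamma-distributed true
durations, a minimum between-episode gap), uniform within-episode contact
times with the first contact at onset, chronic disease with optional
pre-study diagnosis dates and ongoing management contacts, and then the
recording imperfections applied *after* the truth is fixed:

* episodes of care left open (`p_open_ended_eoc`, default 0.7 — most
  recorded episodes in routine data are never closed manually);
* duplicate episodes of care for one problem (`p_duplicate_eoc`, 0.1);
* disease encounters filed under another disease's episode while keeping
  their own code (`p_miscode`, 0.05 — routine extracts show a few percent
  of coded events misfiled);
* contacts recorded loose outside any episode (`p_single_encounter`, 0.05);
* quarterly registration churn (`p_drop_quarter`, 0.02) and death
  (`p_death`, 0.01).

All degradation draws are made unconditionally before being applied, so
changing one probability never perturbs any other part of the stream:
setting `p_open_ended_eoc` from 0 to 1 changes recorded stop dates and
nothing else, which is exactly what the robustness tests exploit. Miscoding
is injected only where it is *detectable* (disease code into a different
disease's episode), so the cleaning step's flagged count can be compared
one-to-one with the injection count.

In **separable** mode (the default), true durations are capped at CFI − 1
days and consecutive true episodes are at least CFI + half-interval days
apart. Under zero degradation this makes the construction provably exact:
within-episode gaps are below the CFI, between-episode gaps above it, and
constructed episodes equal true episodes in count and contact membership.
The test suite verifies exactly that, per seed, and additionally that
pipeline incidence tracks true incidence across seeds.

What the generator does **not** emulate: age/sex structure and any
demographic gradient in hazards, seasonality, code-to-code comorbidity,
clustered contact patterns (it draws uniform contact times), practice-level
heterogeneity in recording quality, and calibration to any national
morbidity level. Passing recovery tests therefore shows the *construction*
is correct under controlled recording noise — not that rates from a real
registry are unbiased, which depends on recording completeness and coding
validity that no algorithm can restore.

## Validation scale

The shipped suite exercises: the two-episode reference scenario exactly
(contacts at weeks 0, 1, 8, 11; stops at weeks 3 and 13; provisional closes
at 5 and 15; half-interval 2 weeks); split/oracle equivalence on 10,000
randomized contact sets across all four intervals; interval-sweep
monotonicity on 100 simulated datasets of 12 patients; exact truth recovery
plus incidence agreement on 100 clean-recording simulations of 15 patients;
stop-date robustness and cleaning conservation on medium simulations
(25–40 patients). These sizes give stable Monte-Carlo behaviour while
keeping the default test run fast; all of them scale up by changing
`sim_config()` arguments.

## Known limitations

* The bundled catalog is a seed covering the most common codes per
  category, not the full 685-code ICPC-1 assignment; uncatalogued codes
  fail loudly and users supply their own catalog CSV for wider studies.
* The half-interval stop rule is a population-level heuristic; individual
  episode durations are not interpretable.
* A chronic episode spans temporary deregistration gaps (the person still
  has the disease while unobserved); person-time denominators, not episode
  clipping, account for the unobserved period. Whether the start of an
  incident chronic episode must fall inside observed person-time is left
  as-is: the calendar year is the only filter.
* ICPC-2/ICD-10 inputs are out of scope; mapping other code systems onto
  the five categories is the user's responsibility.
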