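# ehrepisodes

Construct **episodes of illness** from routinely recorded primary-care
electronic health records and estimate **incidence and prevalence rates**
per 1000 person-years from them.

General-practice EHRs in gatekeeper health systems (Netherlands, UK, Spain,
Italy, ...) record morbidity as ICPC-coded *episodes of care*, loose coded
encounters, and diagnosis-coded prescriptions. Episodes of care are a poor
basis for morbidity rates: GPs rarely close them when the patient recovers,
open several for one health problem, and sometimes file encounters under
the wrong episode. `ehrepisodes` is aimed at epidemiologists and registry
analysts who need to turn such raw extracts into defensible population
morbidity estimates, and ships a synthetic EHR generator so the whole
pipeline can be developed and validated without access to proprietary
registry data.

## The algorithm

Every ICPC-1 symptom or disease code belongs to one of five categories with
an associated **contact-free interval** (CFI) — the period within which a
patient whose complaint persists would likely revisit their GP:

| category         | CFI       | days | half-interval |
|------------------|-----------|-----:|--------------:|
| acute (short)    | 4 weeks   |   28 |            14 |
| acute (moderate) | 8 weeks   |   56 |            28 |
| acute (long)     | 16 weeks  |  112 |            56 |
| long-lasting     | 1 year    |  365 |           182 |
| chronic          | —         |    — |             — |

For one patient and code, with cleaned contact dates
`t_1 < t_2 < ... < t_n`:

1. **Clean** — disease-coded encounters filed inside *another* disease's
   episode of care are extracted as standalone contacts under their own
   code; all remaining within-episode events are recoded to the episode
   code; every episode-of-care start date counts as a contact; recorded
   stop dates are ignored entirely.
2. **Split** — a gap `t_{i+1} - t_i >= CFI` starts a new episode of
   illness.
3. **Close** — each episode runs from its first contact to its last
   contact plus `CFI/2` (the recovery date is unknown but lies within one
   CFI of the last contact), capped at the end of the patient's observed
   time.
4. **Chronic** — irreversible conditions form a single episode per patient
   from the earliest of the pre-study diagnosis date and the first contact,
   ending only at death or end of observation.

Person-time denominators come from quarterly enrollment claims (0.25
person-years per registered quarter, day-level truncation at death).
Incidence counts new episodes over total person-years for acute codes and
over *at-risk* person-years (total minus in-year episode time of that
code) for long-lasting and chronic codes; prevalence counts distinct
persons with an active episode over total person-years.

## Worked example

A patient consults for an acute complaint (4-week CFI) at weeks 0, 1, 8,
and 11:

```r
library(ehrepisodes)
library(tibble)

contacts <- tibble(patient_id = "p1",
                   date = as.Date("2012-01-02") + 7 * c(0, 1, 8, 11),
                   icpc  = "R74")                  # acute URI, 4-week CFI
windows <- tibble(patient_id = "p1",
                  start = as.Date("2012-01-01"), end = as.Date("2012-12-31"))
build_episodes(contacts, windows = windows, trace = TRUE)
#> # A tibble: 2 × 8
#>   patient_id icpc  category    start_date stop_date  n_contacts censored provisional_stop
#>   <chr>      <chr> <chr>       <date>     <date>          <int> <lgl>    <date>
#> 1 p1         R74   acute_short 2012-01-02 2012-01-23          2 FALSE    2012-02-06
#> 2 p1         R74   acute_short 2012-02-27 2012-04-02          2 FALSE    2012-04-16
```

The 7-week gap between weeks 1 and 8 exceeds the 4-week interval, so two
episodes are built: weeks 0–3 and weeks 8–13 (stop = last contact + 2
weeks). The `provisional_stop` trace column shows the mid-algorithm closes
at weeks 5 and 15 (last contact + the full interval).

End-to-end on synthetic data:

```r
sim      <- simulate_ehr(sim_config(seed = 42))
windows  <- observation_windows(sim$tables$registrations, sim$tables$patients)
cleaned  <- merge_contacts(sim$tables$encounters, sim$tables$episodes_of_care,
                           sim$tables$chronic_diagnoses)
cleaned$audit$n_flagged      # 16 of 507 coded events flagged as miscoded
episodes <- build_episodes(cleaned$contacts, windows = windows)
morbidity_rates(episodes, windows, 2012)
#> # A tibble: 5 × 11
#>   icpc   year category     cfi_days incident_episodes prevalent_persons total_py at_risk_py incidence_per_1000py prevalence_per_1000py denominator_used
#> 1 P06    2012 acute_long        112                 8                13     95.2       92.7                 84.1                 137.  total
#> 2 R74    2012 acute_short        28                24                27     95.2       93.9                252.                  284.  total
#> 3 S88    2012 long_lasting      365                 7                13     95.2       89.8                 77.9                 137.  at_risk
#> 4 T90    2012 chronic            NA                 1                 7     95.2       88.3                 11.3                  73.6 at_risk
#> 5 U71    2012 acute_moder…       56                22                21     95.2       93.0                231.                  221.  total
```

(100 simulated patients over 2010–2012 give 95.2 person-years in 2012; the
chronic code T90 is prevalent in 7 persons, mostly pre-study diagnoses,
with one incident diagnosis.)

A command-line wrapper with subcommands `simulate`, `qc`, `clean`,
`build`, `rates`, and `sweep` lives at `inst/cli/ehrepisodes.R`:

```sh
Rscript inst/cli/ehrepisodes.R simulate --seed 7 --out raw/
Rscript inst/cli/ehrepisodes.R build    --in raw/ --out out/
Rscript inst/cli/ehrepisodes.R rates    --in raw/ --year 2012 --out out/
```

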