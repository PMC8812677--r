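---
title: "Episode construction and remote-care trends for RTI contact registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episode construction and remote-care trends for RTI contact registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rtiepisodes` analyses health-care consumption for respiratory tract
infections (RTI) from a person-level contact registry: one row per
physician contact with a date, care setting (primary care, emergency
room, inpatient), modality (in-person or remote), provider class
(traditional or private telemedicine), and up to eight ICD-10
diagnoses. Three definitions drive everything:

* **Index contact** — the first physician contact carrying an
  RTI-relevant diagnosis after at least 181 diagnosis-free days (the
  *clean period* or washout). The washout guarantees that an index
  marks a new illness episode rather than continued care.
* **Follow-up contact** — any physician outpatient contact, regardless
  of diagnosis, 1–30 days after an index contact of the same person.
  Diagnosis is ignored because physicians frequently leave the
  diagnosis unregistered at return visits; the cost of this choice is
  that some attributed follow-ups are unrelated care, which is why the
  synthetic-data validation matters (below).
* **Contact typology** — in-person, remote with a traditional provider,
  or private telemedicine. Telemedicine providers are remote-only by
  construction; primary-care and emergency-room in-person visits share
  one label.

RTI relevance is decided by a configurable ICD-10 code set
(`rti_code_set()`), covering acute upper and lower respiratory
infections, influenza/pneumonia, cough, dyspnea, fever, otitis,
unspecific viral infections and COVID-19 codes including the Swedish
ICD-10-SE extension ZV100.

### Code matching semantics

Registries mix dotted ("J06.9") and undotted ("J069") dialects, so
codes are normalised by uppercasing and stripping dots. A listed
3-character code matches itself and all decimal children (J20 covers
J20.9): registry coders frequently use subcodes and excluding them
would silently lose cases. The one 4-character entry, R06.0, covers
its own subdivisions but *not* its siblings — dyspnea is listed
specifically, and R06.1 (stridor) must not qualify. Ranges such as
J00–J06 are expanded inclusively to every 3-character code they span.
Whether subcodes of listed codes should match at all is genuinely open
(code lists rarely state matching rules); prefix semantics is the
standard claims-data practice, and the code set is a plain list of
strings in the configuration, so the alternative is one edit away.

### Decisions where the definitions are silent

* *Boundary of the clean period.* "At least 181 days" is ambiguous by
  one day; the package blocks index status when an RTI contact lies
  exactly 181 days earlier, and `washout_days` in `study_config()` is
  the off-by-one knob.
* *Same-day contacts.* A second physician contact on the index date is
  not a follow-up (the window is days 1–30), and only the first
  RTI-coded contact of a day can be an index — an index is the *first*
  such contact, and otherwise two indexes could share a date. Same-day
  ties are ordered deterministically by setting, provider class,
  source register and row order.
* *RTI-coded follow-ups.* A follow-up that itself carries an RTI code
  stays a follow-up, but it still resets the washout clock — otherwise
  an RTI contact 40 days after the index (20 days after an RTI-coded
  follow-up) would wrongly start a new episode. In general *every*
  RTI-coded physician contact resets the clock, including inpatient
  stays.
* *Limbo contacts.* RTI-coded contacts that are neither index nor
  follow-up (typically 31–181 days after the last RTI contact) appear
  in no tally; they are retained in the labeled-contacts output as a
  diagnostic, because their volume measures how much care the
  index/follow-up dichotomy leaves unclassified.
* *Follow-up eligibility.* Only physician outpatient contacts can be
  follow-ups; inpatient stays never are. Non-physician contacts are
  ignored entirely.
* *Truncated lookback.* At the start of the data window the washout
  uses whatever history exists; the first months of a registry
  therefore overstate index incidence slightly, which is why the
  bundled presets include a five-month lead-in before the analysis
  periods.

Because consecutive indexes of one person are more than 181 days
apart, a contact can never fall in two follow-up windows; attribution
is unique by construction and asserted, not resolved.

## Aggregation conventions

Rates are `1000 * count / population`, with the population registered
at December 31 of the preceding year as denominator; hospitalization
rates count unique patients with at least one RTI-coded inpatient stay
in the period, against the same denominator. Displayed values use
half-up rounding to two decimals (`round_half_up()`), the convention
of registry tables, with `_raw` columns carrying unrounded values for
downstream computation. The combined remote share is reported as the
sum of the two rounded remote shares, matching how readers combine
table rows. Follow-ups are attributed to their index's calendar month
in the monthly series, which keeps per-index ratios coherent when
windows cross month ends (the alternative — attributing to the
follow-up's own month — makes monthly per-index ratios mix episodes).

## Inference

The period contrast compares March–June 2020 against the pooled
March–June of 2018 and 2019, at the index-visit level: the unit is one
index contact, the outcome its follow-up count (total or split by
follow-up typology). The difference in means is estimated as the OLS
coefficient of the group indicator — numerically identical to the
difference of group means — with heteroskedasticity-consistent
standard errors. The HC1 variant (finite-sample scaled sandwich) is
the default because count outcomes are strongly heteroskedastic across
groups and HC1 is the conventional default in applied registry work;
the variant is switchable (`hc_type`). Two-sided p-values use a t
reference with n − 2 degrees of freedom, indistinguishable from the
normal at registry sample sizes. Variances are not clustered on
person; persons contribute very few indexes each (at most one per
212 days), so within-person dependence is negligible at this design.

Composition is tested with the classic Pearson χ² statistic on the
2 × 3 table of follow-up *contact* counts (period group × follow-up
typology), df = 2, no continuity correction. Counting contacts rather
than index visits weights each follow-up equally and matches the
contact-level framing of the composition question; it is an
interpretational choice and recorded as such. Degenerate inputs are
signalled, never silently patched: a zero margin names the degenerate
row/column, zero-variance outcomes flag the row and leave p undefined,
and strata missing a period group are emitted with a note.

## The synthetic registry generator

Real care registers are not shareable, so validation runs on
`simulate_registry()`, which emulates the statistical structure the
analysis assumes and emits ground-truth labels for every contact.

**Arrival model.** Each person independently starts at most one new
RTI episode candidate per calendar month, with probability
`incidence/1000` from the monthly schedule; candidate days are uniform
within the month (registries show no strong within-month structure,
and none of the downstream statistics depend on it). Candidates are
thinned so consecutive indexes of a person are at least 212 days
apart: 181 (washout) + 30 (follow-up window) + 1, which guarantees
that *every* RTI-coded contact of an episode — the index, RTI-coded
follow-ups, the inpatient stay — lies strictly outside the next
index's clean period. The thinning makes realized incidence fall
slightly below nominal (a few percent, growing with incidence), which
is also true of real registries, where the washout censors repeat
episodes.

**Episode content.** The index draws its typology from the regime's
modality mix (regimes switch by calendar month; the pandemic regime
starts March 2020). Follow-up counts per (index typology, follow-up
typology) cell are Poisson with the configured mean — only means are
identifiable from published tables, and Poisson is the natural
maximum-entropy choice for sparse visit counts — with dates uniform on
days 1–30. With probability `hospitalization_prob` the episode
includes an RTI-coded inpatient stay 0–14 days after the index.
Follow-ups carry an RTI code with probability 0.5, a non-RTI code or
no code otherwise.

**Background care.** Non-RTI physician contacts arrive as a Poisson
stream of 0.15 contacts per person-month (roughly the non-RTI
physician-visit volume of Nordic primary care; 15% of background rows
are non-physician contacts that exercise the profession filter).
Background diagnoses are drawn from a pool of deliberate near-misses
(B34.9, R06.1, J30.9, Z- and chronic-disease codes) so matcher
specificity is tested by every run. Physician background contacts are
rejection-sampled out of 30-day follow-up windows: the configured
follow-up intensities are then *exactly* the quantity an ideal
pipeline recovers, making parameter-recovery tests sharp. The cost is
a small unrealism — real follow-up tallies include coincidental care —
which is deliberate: the attribution-of-unrelated-care question is a
property of the definitions, not of the pipeline's correctness.

**Missingness.** Diagnosis masking (by provider class × modality) is
applied *after* role assignment, so ground truth is unaffected and
tests can quantify the misclassification that unregistered diagnoses
cause — masked indexes disappear or are replaced by a later RTI-coded
follow-up promoted to index, lowering recovered index counts. The
presets set missingness to zero: their target rates describe the
*registered* contact process, so masking on top would double-count
under-registration.

**Presets.** `paper_like_params()` returns two documented presets
calibrated to published utilization figures for a large Swedish region,
2018–2020:

* *prepandemic* (Aug 2017–Jul 2018): incidence peaking in February
  (Jan–Jun schedule 15, 19, 16, 12, 10, 8 per 1000, with an autumn
  lead-in of 5–12), modality mix 0.92/0.04/0.04, follow-up intensity
  rows totalling 0.48 / 0.73 / 0.49 per index, hospitalization 0.06.
* *pandemic* (Aug 2019–Jul 2020): incidence peaking in March and then
  dropping below seasonal norms (13, 14, 16, 9, 6.3, 5), intensity
  rows 0.60 / 0.90 / 0.69, hospitalization 0.08, COVID codes in the
  diagnosis pool. The modality mix switches from 0.92/0.04/0.04 to
  0.605/0.25/0.145 in March; those regime values are derived so that
  the incidence-weighted January–June averages reproduce the reported
  half-year shares 0.74/0.16/0.10.

Published per-cell intensities are rounded to two decimals and do not
sum exactly to their published row totals; the presets rescale each
row so that totals match the published per-index rates exactly, since
the row totals are the recovery targets.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: demography (no age/sex structure, no
differential care-seeking), comorbidity and within-person correlation
of utilization, provider capacity constraints, geographic structure,
transmission dynamics, secular trends in telemedicine adoption, and
coincidental care inside follow-up windows (see above). Parameter
recovery demonstrates that the pipeline measures what the definitions
say; it cannot validate the definitions against clinical reality.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:

* the single-pass classifier against an O(n²) brute-force
  reference on 400 randomized registries (~10,000 contacts) covering
  every enum combination;
* exact ground-truth recovery (index and follow-up counts and labels)
  on a 50,000-person registry at zero missingness, plus a directional
  misclassification check at 20% missingness on remote-traditional
  contacts;
* recovery of the pandemic preset's follow-up intensities
  (0.60/0.90/0.69) on a 900,000-person registry, each typology
  exceeding 5,000 indexes, within a joint 95% Monte-Carlo interval,
  and recovery of an injected +0.25 per-index contrast through the
  full inference layer;
* null calibration of the robust test (≈5% rejection at α = 0.05 over
  1,000 replicates) and equality of the χ² statistic with the
  hand-summed Pearson formula to 1e-10;
* seasonality: February peak under the prepandemic preset, March peak
  and below-seasonal April–June under the pandemic preset.

These sizes keep the full suite near two minutes on one CPU while
leaving Monte-Carlo intervals tight enough to detect biases of a
percent or two.

## Known limitations

Episode construction is deliberately single-region: no deduplication
across registers beyond the pseudonymous id, no care-pathway modelling
beyond the 30-day window, no outcome measures (prescriptions,
severity). The limbo category is reported but unanalysed. Secular
trend adjustment of the period contrasts is out of scope; the
contrasts therefore measure the difference between periods, not the
causal effect of the pandemic.
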