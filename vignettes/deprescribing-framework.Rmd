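---
title: "Classifying T2D medication deprescribing from prescription trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying T2D medication deprescribing from prescription trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprescribr)
```

## The classification problem

Primary-care EHR exports record what was *prescribed*, when, at what
strength and frequency — not why. Deciding from such data whether a
patient's type-2-diabetes regimen was deliberately stepped down
(deprescribed) requires an operational definition that can be applied
consistently. `deprescribr` implements such a definition as a deterministic
rules engine over three medication intensity tiers:

* **insulin** — highest tier, dosed in units; basal and bolus products are
  summed into a single total-units figure;
* **other non-insulin agents** — middle tier (sulfonylureas, DPP-4
  inhibitors, GLP-1 receptor agonists, SGLT-2 inhibitors,
  thiazolidinediones, meglitinides, alpha-glucosidase inhibitors), treated
  as mutually equivalent in intensity;
* **metformin** — lowest tier, typically first prescribed and last
  discontinued.

Every free-text medication name is normalized against an editable lexicon
(`load_lexicon()`), case-insensitively and ignoring trailing strength/form
suffixes. Fixed-dose combinations are split into per-component records so a
metformin-containing combination counts as metformin exposure. Unrecognized
names (statins, antihypertensives, supplements) are counted and set aside —
a real export always contains them, and erroring would make the pipeline
unusable.

Each prescription is standardized to a daily dose, the exact product
`dose per administration × administrations per day` (a weekly injectable is
represented with frequency 1/7). No defined-daily-dose normalization and no
cross-drug unit conversion is attempted: the rules only ever compare a drug
with itself (per-drug, same units; mcg is folded into mg) or a category
with itself (insulin total units, metformin total mg).

## Trajectory reduction

A patient's history is reduced to a `trajectory_summary`:

* **baseline** regimen: the 12 months (365 days, configurable) starting at
  the first diabetes-medication record, half-open `[start, start+365)`;
* **final** regimen: the 12 months ending at the extraction date, closed at
  the right endpoint. The final window is anchored at the extraction end —
  not the last record — because the discontinuation inference below is
  defined relative to the end of the data period.

Within a window, each medication's dose is the **most recent** record's
daily dose (what the patient "ended up on"); a same-date duplicate resolves
to the *higher* dose, a deliberately conservative tie-break against
over-calling a dose reduction. Interim add/stop events between the windows
are counted; per-drug record dates are split into *prescribing runs*
wherever consecutive records are more than one window apart — under an
annual-refill policy such a gap means the drug was stopped and restarted.

Cohort eligibility mirrors the intended population: age 18–89 with at least
two encounters inside the analysis window (defaults span 2014-05-15 to
2023-03-13). Exclusions are reported by reason, never raised as errors. The
published table interfaces carry no demographics, so age arrives through an
optional third table (`patient_id,age`); a patient missing from it is
excluded with reason `missing_age`.

**Inferred discontinuation.** Practices requiring at least an annual visit
for refills justify reading an empty final year as discontinuation — but
only for patients demonstrably still in care. The flag is true iff the last
medication record predates the extraction end by more than 365 days *and*
at least one encounter follows it. It is monotone: adding a later
prescription can only clear it.

## The rules and their resolution

`evaluate_rules()` applies each predicate independently to the
baseline/final pair; `classify_patient()` resolves the matches into exactly
one `(top_level, subtype)`:

| order | condition | result |
|---|---|---|
| a | final empty, discontinuation inferred | DEPRESCRIBED, subtype = highest tier discontinued |
| a2 | final empty, no inference possible | UNCLEAR (lost to follow-up) |
| b | deprescribing rule(s), no escalation | DEPRESCRIBED, first matched subtype in order (1)–(8) |
| c | escalation only | NOT_DEPRESCRIBED / MEDICATION_INCREASE |
| d | both deprescribing and escalation | UNCLEAR (mixed signal) |
| e | lateral switch only | NOT_DEPRESCRIBED / LATERAL_CHANGE |
| f | baseline ≡ final | NOT_DEPRESCRIBED / NO_CHANGE |
| g | interim oral transitions > `max_transitions` | UNCLEAR |
| h | anything else | UNCLEAR |

Three design points here were genuinely open and deserve their rationale:

* **Pure stops versus switches.** The printed subtype order places
  "medication stopped" (4) ahead of "change to metformin" (6), yet a
  consolidation of multiple medications + metformin to metformin only must
  be labelled as the to-metformin subtype. We therefore define rule 4 as a
  *pure* stop: a non-insulin agent stopped with no replacement non-insulin
  agent started (that is lateral), no metformin newly started (that is a
  switch, rule 6), and no metformin-only consolidation (also rule 6). With
  that refinement the printed order is a true precedence and both readings
  coincide.
* **Lost to follow-up.** A final year with neither prescriptions nor
  subsequent encounters carries no information: the stop rules would
  technically fire, but inferring deprescribing without evidence the
  patient was still in care contradicts the active-patient requirement of
  the inference rule. Step (a2) routes these to review instead.
* **Mixed signals.** When one tier de-escalates while another escalates
  (insulin down, metformin up), no cross-category netting is defined — the
  case goes to review rather than to any arithmetic compromise.

Two further conventions: metformin "stopped" requires a single prescribing
run (a restart after a >1-year gap disqualifies the subtype; such
trajectories fall through to review); and insulin or metformin *product*
switches at equal category totals (glargine → NPH at the same units)
compare as no change, since those tiers are compared by total dose, not by
product identity. Dose-change rules are suppressed — presence rules kept —
for any category whose units are incomparable across the two windows
(`category_daily_total()` flags this), and any dose decrease, of whatever
magnitude, counts: the definitions say "decrease", and no clinical
materiality threshold is imposed.

`max_transitions` (default 4) bounds interim oral-agent churn before a
trajectory is routed to review; the value is a policy knob with no
published default, deliberately reached only after the lateral and
no-change checks, which explicitly tolerate interim changes.

## What the synthetic generator does and does not emulate

`generate_cohort()` emits records/encounters/demographics tables shaped
like a dashboard export, with one planted scenario per patient: the eight
deprescribing subtypes, a three-phase lateral chain, escalation, a stable
regimen, inferred discontinuation, lost to follow-up, a mixed signal, and
(on request) ineligible patients. Defaults are fixed by design, not tuned:
therapy starts within the first year of the window, one regimen change
occurs at least 90 days from window edges (phases of a lateral chain are
each ≥ 90 days), refills recur every 90–120 days, encounters every 4–6
months, ages are uniform on 25–85 (90–95 for the planted age-ineligible
scenario), and doses come from small fixed menus (insulin 10/20/40
units/day, metformin 500/1000/2000 mg/day, sitagliptin 25/50/100 mg/day) so
trajectories stay enumerable against a brute-force oracle. Scenario
assignment is multinomial, so per-scenario counts fluctuate binomially
around `n/14` under the uniform default mix. Output is byte-identical for a
fixed seed.

The generator emulates the *structure* the classifier consumes — mixed
brand/generic/suffixed name forms, refill cadence, visit cadence, planted
gaps — and nothing else: no demographic realism, no comorbidity or HbA1c
dynamics, no prescriber preference heterogeneity, no irregular dosing
instructions ("take 1–2 tablets"), no free-text sig parsing. Passing tests
therefore demonstrate that the engine implements the framework faithfully
on well-formed trajectories, not that the framework captures every
ambiguity of real charts — the original use of such a framework kept a
human review step for flagged cases, and this implementation preserves
that boundary by routing them to `NEEDS_REVIEW`.

## Verification strategy and problem sizes

The test suite checks each module against independent oracles: hand-summed
dose totals; the discontinuation predicate restated directly from its
defining dates; and, centrally, an independently coded flat transcription
of the category definitions evaluated on all 4096 baseline/final pairs over
a one-drug-per-tier grid (3 dose levels per tier plus absence) — the engine
must agree on every pair, exactly. Cohort-level properties (100% planted
label recovery, conservation of the deprescribed count over the eight
subtypes, invariance to input row shuffling and to rigid date shifts) run
on simulated cohorts of 300–700 patients, sizes chosen to exercise every
scenario many times while keeping the default suite fast.
`scripts/acceptance.R` re-runs the headline computations from scratch on a
600-patient cohort and the full grid for any seed.

## Known limitations

* Prescribing ≠ dispensing ≠ adherence: a "stop" is the absence of further
  prescriptions, with no days-supply modelling.
* The bundled lexicon is a useful stand-in compiled from public US
  brand/generic names, not an exhaustive or site-validated formulary;
  extend it locally (it is a plain CSV).
* Non-insulin dose comparisons are per-product; a switch between
  formulations of the same non-insulin generic at different milligram
  strengths is compared numerically even when clinical equivalence differs.
* The engine classifies trajectories; it makes no judgment about clinical
  appropriateness, causes of change, or links to lifestyle intervention.
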