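---
title: "How the automated trial engine works"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the automated trial engine works}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`labelrct` models a nutrition-labeling randomized controlled trial that runs
itself: every protocol step a coordinator would normally perform — consent,
eligibility screening, registration, randomization, intervention delivery,
reminders, outcome capture — is a deterministic rule evaluated against a
participant's state and a day clock. This vignette explains the model, the
choices behind its defaults, and what the synthetic cohort simulator can and
cannot tell you.

## The participant lifecycle

A participant is a state machine:

```
INSTALLED -> CONSENTED -> SCREENED_ELIGIBLE -> REGISTERED -> BASELINE
          -> RANDOMIZED -> INTERVENTION -> FOLLOW_UP_DUE -> COMPLETED
```

with terminal exits `SCREENED_INELIGIBLE` (first eligibility check),
`EXCLUDED_RUN_IN` (second check), and `WITHDRAWN` (any time). Transitions are
driven by `advance_to(participant, clock, config, alloc)`, which replays
every due timeline event exactly once and in order regardless of how
coarsely the clock moves — a participant who reopens the app after ten days
catches up deterministically, with each event logged at its *due* day rather
than the observation day. The clock is monotone; moving it backwards is an
error rather than a silent re-fire.

**Day conventions.** Days are whole 0-based indices on the participant's
local calendar, with registration on day 0. Phase boundaries: the baseline
counting window is days 0–6, randomization is due at day 7, the intervention
runs to day 34, and the follow-up questionnaire becomes due at day
`baseline_days + intervention_days` = 35. Message schedules written "day N
of a phase" resolve to N days after the phase's anchor day (registration or
randomization), so "day 3 of week 1" is day 3 and "day 28 of the
intervention phase" is day 35 — deliberately the same day the follow-up
becomes due. The progress tracker reports `floor(days/7)` capped at 5.

**Two-stage eligibility.** Screening is an opaque configurable predicate
over the questionnaire answers (real trial criteria live in protocols, not
in an engine); the default accepts a truthy `eligible` answer. The second
check is behavioural: at least `run_in_min_items` (default 15) barcoded
items on lists *submitted during days 0–6*, counting item quantities rather
than distinct barcodes — a shopper buying 15 units of one product passes.
The decision stays open for `run_in_grace_days` (default 7) after day 7
before exclusion. The grace window exists because transmission can fail and
be retried (retried lists keep their submission day); it never extends the
counting window itself. Both the threshold and the grace are configuration.

**Idempotence as a design rule.** Consent is an idempotent no-op when
repeated; questionnaires collapse to the earliest stored record per kind
(duplicate survey copies are a known failure mode of app trials, and
collapsing at the engine is the remedy); timeline events are fire-once; a
failed list transmission retries into exactly one history entry.

**Identity separation.** Registration stores only a salted SHA-256
fingerprint of the lower-cased email — enough for the duplicate-registration
check, useless for re-identification — and outcome exports carry participant
ids only. The export function refuses to emit tables containing identity
fields.

## Randomization

Allocation is blocked with variable block sizes: a pending sequence per
stratum is refilled with a uniformly shuffled block containing each arm
exactly `size/|arms|` times, the size drawn uniformly from `block_sizes`.
This bounds the arm-count spread within any stratum below
`max(block_sizes)` at every moment while making block boundaries
unpredictable. Defaults are one and two times the arm count — standard
practice where the protocol does not fix the sizes — and are configurable.

Each stratum owns an independent RNG sub-stream derived from the allocation
seed and the stratum id, so the full arm sequence of a stratum is a pure
function of (seed, within-stratum request order). Assignments in one stratum
can never perturb another, concurrent requests are resolved by the total
order the engine supplies (at most one in-flight assignment per stratum),
and replaying a trial reproduces every allocation. An audit log records
participant, stratum, arm, block id, and block position.

The Australian profile runs a single unstratified stream; the New Zealand
profile crosses ethnicity (3 levels: `maori`, `pacific`, `other`) with
interest in healthy eating (2 levels: `low`, `high`). The factor *names*
are fixed by the design; the *levels* are package defaults chosen as a
plausible minimal coding and are configuration, not constants.

## The label engine

All five formats are pure functions of a product record (nutrients per
100 g, or per 100 mL for beverages — the `is_beverage` flag selects both the
unit convention and the table variant) and a scheme table:

* **Traffic Lights**: GREEN if amount ≤ `low`, AMBER if ≤ `high`, RED above,
  for fat, saturated fat, sugars, sodium. Defaults follow the UK FSA 2013
  front-of-pack criteria with salt expressed as sodium (mg); the boundary is
  inclusive on the greener side.
* **Daily Intake Guide**: %DI = per-serving amount / reference × 100,
  rounded *half-up* to one decimal (R's banker's rounding would make 10.25
  display as 10.2, which no printed label does). References default to the
  Australian adult set (8700 kJ energy, 70 g fat, 24 g saturated fat, 90 g
  sugars, 2300 mg sodium). %DI is linear in serving size and homogeneous of
  degree 1 in nutrient content, which the tests assert.
* **Health Star Rating**: baseline points (energy, saturated fat, sugars,
  sodium) minus modifying points (fruit/veg/nut/legume %, protein, fibre),
  mapped through a monotone non-increasing score-to-star table onto
  {0.5, 1.0, …, 5.0}. Band tables award the points of the highest threshold
  strictly exceeded, so they are exhaustive over [0, ∞) by construction and
  monotone by validation; missing optional components contribute zero.
  Default bands follow the structure and, where public, the values of the
  published algorithm; all of it is editable fixture data because the
  algorithm is periodically recalibrated and trials pin their own version.
* **Warning Label**: a flag per nutrient whose per-100 amount *strictly*
  exceeds its threshold. The source protocol's exact boundary rule is not
  public, so the strict inequality is fixed here and documented: a product
  sitting exactly at a cutoff is not warned against.
* **Nutrition Information Panel** (control): seven rows, per 100 and per
  serving, and structurally nothing else — no colours, stars, percentages,
  or flags. A test asserts this control-arm purity, since an interpretive
  element leaking into the control would bias the comparison the trial
  exists to make.

`label_for()` dispatches on the participant's allocated arm using the
configuration's tables; an arm outside the profile is a configuration error.
Scheme tables round-trip through YAML/JSON so a deployment can re-pin them
without code changes.

## Messaging

Ten rules cover the trial's engagement messages. Six are clock-triggered and
evaluated by `due_messages()` (registration/baseline-questionnaire
reminders; week-1 recording reminders at days 3 and 5; intervention
keep-recording reminders at +4, +6, +9, +12, +18, +24 days from the later of
the last transmitted list and the intervention start, re-arming after every
list; ending-soon at intervention day 26; the follow-up request at
intervention day 28; follow-up reminders at +6…+30 from day 35). Four are
event-triggered and queued by the operation that observes the event: the
one-off ineligibility message with the FoodSwitch link, the two list-rules
(under-threshold encouragement during week 1, transmission success once the
week-1 total reaches 15), and the completion message.

Three mechanisms jointly prevent runaway reminders, an observed field
failure mode: records are unique on (rule, participant, due day); each rule
carries a repeat cap (the keep-recording cap is one per intervention day,
since its anchor legitimately resets); and every stream's trigger condition
clears permanently with state (follow-up reminders stop at `COMPLETED`,
registration reminders at a completed baseline questionnaire). "Once a
month" in the registration rule means every 28 days, capped at 35 days
before the recruitment window (default 180 days) closes. Delivery is
whole-day granular; the hour of day is out of scope. The rule table
round-trips through YAML with behaviourally identical schedules, which a
test verifies on a replayed trace.

## Capture and the two app modes

Scanning always appends to the participant's single open list (data
collection runs weeks 1–5); from randomization onward a matched scan
*additionally* returns the allocated label plus up to four random
same-category products and logs a label view (intervention delivery, weeks
2–5). The modes are simultaneous, not exclusive. An unmatched barcode is a
normal outcome that opens the crowdsourcing path — a submission is only
accepted for a barcode that actually failed to match, and photos are stored
as counts (image handling is out of scope). Receipts are metadata linked to
an existing transmitted list. Quantity defaults to 1 per scan but is
recordable, and the week-1 counter sums quantities over week-1 lists — the
single source of truth the run-in check reads.

## The cohort simulator

The simulator exists to exercise the engine end-to-end and to give the
acceptance checks a cohort of known construction; it is not a behavioural
model of real shoppers. Each synthetic participant draws: stage completions
as Bernoulli trials (consent 0.95, screening pass 0.8, registration 0.95,
baseline questionnaire 0.95, follow-up 0.8 per day once due), shopping as a
daily Bernoulli trip at `trips_per_week/7` (default 2.5/week) with
`1 + Poisson(7)` items per trip, a 5% unmatched-scan rate with 50%
crowdsourcing uptake, 60% receipt capture, 2% transmission failure, and a
phase-specific daily dropout hazard (1% baseline, 0.5% intervention, 1%
follow-up). None of these rates is published for the real trials — recruited
human funnels are not reproducible at a desk — so they were chosen once as
plausible for an engaged mHealth cohort and are all parameters of
`behavior_model()`. `behavior_model_compliant()` is the analytic limit:
every probability 1, a daily 5-item trip (guaranteeing the 35 ≥ 15 run-in),
zero dropout — under it, completion must equal enrolment exactly, which the
tests assert.

What passing simulations do show: the funnel is monotone by construction of
the state machine, randomization balance holds under the blocked bound,
every module interoperates over full 45-day trajectories, and the whole run
is a pure function of the seed (behaviour, the synthetic food database, and
each randomization stratum draw from independently derived sub-streams).
What they do not show: anything about real adherence, real label effects, or
real food databases — the synthetic database draws nutrients from uniform
ranges wide enough to exercise every scheme band, which no real food supply
resembles.

## Numerical and degenerate-input choices

* Duplicate barcodes in a food table keep the first occurrence and reject
  the rest — deterministic and auditable; load order matters only there.
* EAN-8/13 check-digit failures warn rather than reject: real supplier
  feeds contain nonconforming codes that still scan.
* A category containing only the scanned product yields an empty
  related-products list; sampling is without replacement and bounded by the
  category population.
* RNG streams capture and restore `.Random.seed`, so library calls never
  disturb a caller's RNG state, and nested streams (behaviour around
  allocation) compose safely. Derived seeds stay below 2^31.
* An empty event log aggregates to an all-zero report; a malformed JSON
  line fails with its line number.

## Problem sizes

The test suite drives single participants over 40–70-day grids, cohorts of
15–120, 10,000-block Monte-Carlo checks of block-size uniformity, and
600-block permutation-enumeration checks; the acceptance script simulates a
60-participant compliant New Zealand cohort, a 200-participant Australian
cohort with attrition, and a 300-product label sweep. These sizes give
stable structural statistics in well under typical CI budgets while keeping
every check exact where exactness is the point (balance counts, event
order, schedule days).

## Known limitations

Hour-of-day scheduling, push-transport semantics, image storage and OCR,
multi-device sync, and authentication are all out of scope. The default
scheme tables are faithful in structure to the public style guides but are
not a certified transcription of any regulatory instrument; pin your own
tables for anything beyond engine studies. Withdrawn participants retain
their prior data in the store (the alternative — retroactive deletion — is a
governance decision, not an engine one). The simulator's behaviour model is
deliberately simple; fitting it to real usage data is explicitly a non-goal.
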