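# labelrct

A desk-scale engine for **fully automated nutrition-labeling randomized
controlled trials**. Real-world trials of front-of-pack nutrition labels are
hard to run because the intervention (the label a shopper sees) has to reach
participants inside ordinary supermarkets, and the outcome (what they
actually buy) is expensive to capture. A "smart RCT" smartphone app solves
both with a barcode scanner: scanning a product matches it against a food
composition database, displays the nutrition label format the participant was
randomized to, and records the purchase on an electronic shopping list
transmitted to the trial server.

`labelrct` re-implements that trial logic as an R library for
methodologists, trial statisticians, and engineers who want to study, test,
or extend the design of app-run trials: consent and two-stage eligibility,
server-style stratified blocked randomization, the timeline-driven
participant lifecycle, the full notification/reminder rule set, label
computation in five formats, shopping-data capture, and a synthetic
participant-cohort simulator that exercises everything end-to-end.

## The trial design in brief

* **Timeline** (whole days from registration): a 1-week baseline/run-in
  phase, randomization at day 7, a 4-week intervention phase, follow-up
  questionnaire due at day 35.
* **Run-in (second eligibility check)**: at least 15 barcoded food or
  beverage items must be recorded during week 1, or the participant is
  excluded before randomization.
* **Randomization**: blocked with variable block sizes — each block is a
  uniform shuffle containing every arm exactly `size/|arms|` times, with the
  size drawn uniformly from a configured set, bounding the arm imbalance in
  any stratum below the largest block size while hiding block boundaries.
  The New Zealand profile (3 arms) stratifies by ethnicity and self-reported
  interest in healthy eating; the Australian profile (5 arms) does not.
* **Label arms**: Daily Intake Guide (%DI per serving = per-serving amount /
  reference daily intake × 100), Traffic Lights (GREEN/AMBER/RED per
  nutrient against low/high cutoffs per 100 g/mL), Health Star Rating
  (0.5–5.0 stars from baseline risk points minus modifying points through a
  monotone score-to-star map), Warning Label (threshold-triggered "high in"
  flags; Australian trial only), and the Nutrition Information Panel — the
  mandatory back-of-pack table — as the app-delivered control. All
  thresholds and point tables are configuration data in the structure of the
  public style guides, not code constants.
* **Messaging**: ten notification/reminder rules (in-app and push) with
  fixed day schedules, anchored re-arming, and repeat caps so no reminder
  stream can run away.

## Worked example

Label a product from the shipped synthetic database, then simulate a
100-participant New Zealand cohort:

```r
library(labelrct)

db <- read_food_db(system.file("extdata", "synthetic_food_db.csv",
                               package = "labelrct"))
p <- match_barcode(db, "9300607880793")
traffic_light(p)
#> <nutrition_label> arm=TLL barcode=9300607880793
#> # A tibble: 4 x 3
#>   nutrient per_100 colour
#>   <chr>      <dbl> <chr>
#> 1 fat          5.1 AMBER
#> 2 satfat      14.8 RED
#> 3 sugars      10.9 AMBER
#> 4 sodium     598   AMBER

health_star(p)$payload$stars
#> [1] 2

co <- simulate_cohort(100, trial_config_new_zealand(),
                      behavior_model(), seed = 42)
co$report
#> <cohort_report>
#>   funnel: downloads=100 -> consented=96 -> screened_eligible=75 ->
#>           registered=73 -> randomized=44 -> completed=41
#>   excluded at run-in: 20
#>   totals: lists=627, items=5213, receipts=374, label_views=3092,
#>           crowdsource=122
```

Reading the output: 14.8 g saturated fat per 100 g sits above the 5 g "high"
cutoff, so that row colours RED; the same nutrient profile earns 2.0 stars.
In the simulated cohort the funnel shrinks at each stage — 96 of 100
consent, 75 pass screening, 73 register with unique emails, 44 record at
least 15 items in week 1 and are randomized (20 are excluded at run-in), and
41 complete the follow-up questionnaire. The usage totals count transmitted
shopping lists, items on them, receipt photos (metadata), label views during
the intervention phase, and crowdsource submissions for unrecognized
barcodes.

`tidy(co)` gives one row per participant, `glance(co)` the one-row summary,
`autoplot(co)` the funnel plot, and `export_outcomes(co, "csv", dir = ...)`
writes the de-identified outcome streams (keyed by participant id only).

A thin command-line wrapper is installed at `exec/labelrct`:

```
labelrct validate-db <db.csv>
labelrct label <db.csv> <barcode> <arm>
labelrct simulate <n> --country new_zealand --seed 7 --out out/
labelrct report out/events.jsonl
labelrct notify-debug out/events.jsonl P0001
```

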