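---
title: "The ROB severity-scoring protocol: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ROB severity-scoring protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robscore)
```

## The problem

The endovascular circle-of-Willis perforation model of subarachnoid
hemorrhage (SAH) in mice produces realistic arterial bleeding but with
uncontrolled bleeding volume, so nominally identical surgeries yield animals
spanning the full range from near-sham to moribund. Treatment studies that
pool such animals into a single "SAH" arm confound treatment effects with
severity heterogeneity. The ROB protocol addresses this by grading each
animal daily from three objective, repeatable measurements:

* **R** — Rotarod: mean latency to fall (seconds) over three trials on an
  accelerating rod (4–40 RPM), capped at a 300-s endpoint;
* **O** — Open field: path distance of an ear marker tracked through a
  key-frame-sampled 30-FPS video window, in raw tracker pixel units;
* **B** — Body-weight loss: `(pre − post)/pre × 100%` against the
  preoperative baseline.

Each component maps to a 1–5 sub-score; the total (3–15) classifies the
animal as severe (3–6), moderate (7–10) or mild (11–15). This package
implements the full protocol — scoring, behavioral measurement, cohort
construction, survival statistics, autopsy concordance — plus a cohort
simulator so every stage is testable without animal data.

## Scoring bands and boundary conventions

The published criteria table prints touching bin edges (e.g. Rotarod bands
"51–100" and "101–200"; open-field "300–500" and "500–800"), so a scorer
must fix a convention at the shared boundaries. `rob_criteria()` centralizes
the one used here:

* Rotarod: 1 for `s ≤ 50`, 2 for `50 < s ≤ 100`, 3 for `100 < s ≤ 200`,
  4 for `200 < s < 300`, 5 only at the 300-s cap. The printed score-4 band
  "201–299" together with the score-5 row "300" implies that only a
  capped run scores 5; a latency of 299.5 s scores 4 under this reading.
  Users who prefer the opposite resolution can flip the final `strict`
  flag.
* Open field: 1 on `[0, 300)`, 2 on `[300, 500)`, 3 on `[500, 800)`,
  4 on `[800, 1000]`, 5 strictly above 1000 (the top band is printed
  strictly).
* Weight loss: 5 below 5%, 4 on `[5, 10)`, 3 on `[10, 15)`, 2 on
  `[15, 20]`, 1 strictly above 20%. Both printed end bands are strict,
  which forces the closure of the inner bands.

Every strict inequality the criteria table prints is respected; remaining
ties resolve lower-inclusive (the less severe reading at the healthy end of
each component). Weight *gain* — never observed in the validation cohort but
possible in principle — scores 5, the healthiest band. Sub-scores are always
recomputed from raw measurements; pre-binned scores are only honored under
an explicit `allow_prebinned` flag, to keep scoring traceable to raw data.

The criteria serialize to YAML (`write_criteria()` / `read_criteria()`) so a
laboratory variant is a reviewable one-file diff.

```{r}
compute_rob(rotarod_seconds = 38, openfield_distance = 130, bwl_percent = 11)
```

## Behavioral measurements

**Open field.** The protocol records a 10-s clip at 30 FPS, takes the 160
frames following the operator-chosen release frame (the first frame of
unrestricted movement — a required user input here, since no automatic rule
was specified), and samples key frames every 5 frames with both endpoints
included: 33 key positions. Note that 160 frames at 30 FPS is 5.33 s; the
frame count is treated as authoritative and the nominal "5-second window" as
a label. The scored quantity is the total path length over consecutive key
positions (`path_distance()`), not the net start-to-end displacement —
locomotor activity is the construct, and a mouse circling back has moved.
Both quantities are exposed. Distances stay in raw tracker pixel units with
no spatial calibration, matching the protocol's unitless convention; this
means distances are only comparable within a fixed camera geometry.

**Marker tracking.** `track_marker()` re-implements what point-tracking
video software computes for a high-contrast marker: per frame, the centroid
of pixels darker than a threshold (default 0.5 on a 0–1 scale) within a
bounded search radius (default 20 px) of the previous position. It exists so
the full video-to-score path can be exercised on synthetic rendered stacks
with known ground truth (recovery is within 1 px there); it makes no claim
of robustness on real video, where occlusion, lighting and fur contrast
dominate.

**Rotarod and weight.** `mean_rotarod()` averages exactly three trials,
clamping each at the 300-s endpoint first (timer overruns are recording
artifacts). `body_weight_loss()` is the signed percent of baseline.

## Cohort construction and mortality accounting

`build_valid_cohort()` applies the protocol's two-stage exclusion workflow:
animals excluded for reasons unrelated to scoring (incidental tumor,
intraoperative death, suboptimal filament placement) leave the *valid*
cohort; animals that died before the first assessment or lack day-1 data
additionally leave the *scored* cohort. Early mortality is reported over the
animals actually subjected to the induction — intraoperative deaths stay in
that denominator, tumor/filament removals do not.

Two event-kind conventions drive all downstream statistics:

* a humane-endpoint euthanasia is a **mortality event** — the animal's
  condition caused its death, the timing was merely controlled;
* a scheduled autopsy (tissue harvest of a randomly selected survivor) is
  **right-censoring** — it carries no information about the animal's
  prognosis.

Cumulative mortality through day *d* therefore counts deaths plus
humane-endpoint events with `event_day ≤ d` over the scored cohort minus
scheduled removals *strictly before* *d*: an animal harvested on day 3
stands in the day-3 denominator and leaves it on day 4. This is the only
denominator rule under which all published rates (4/29 on day 3, 8/21 from
day 4, 2/13 for the moderate class at day 7) emerge from one ledger, and the
bundled reconstruction `cwp_example_cohort()` reproduces every one of them.
The severity composition of the eight day-3 harvests was not published; the
reconstruction's split (0 severe, 5 moderate, 3 mild) is the unique
assignment consistent with every printed denominator and the survivor
breakdown, and is documented as a reconstruction, not data.

`km_curves()` and `logrank_test()` wrap the standard product-limit estimator
and k-group log-rank test (asymptotic chi-square p on k−1 degrees of
freedom, standard tie handling; deaths "on day d" occur at time d exactly).
The test suite cross-checks the statistic against an independent
from-scratch implementation and the asymptotic p-value against a
10,000-draw permutation of group labels on a small table. One caveat
uncovered while testing: the log-rank statistic is *not* invariant to
appending extra all-censored animals with late censoring times (they enter
every earlier risk set); what does hold, and is asserted, is invariance to
moving existing censoring times beyond the last event day.

`oneway_anova()` performs the protocol's group comparisons (ordinary one-way
ANOVA). The published analysis does not state its multiple-comparison
adjustment; Tukey's HSD is the default here as the standard choice for
all-pairs comparison after ANOVA, with Bonferroni and Holm available. When
every group is constant the F statistic is undefined; the function returns
p = 1 with a warning rather than failing, so screening loops over many
endpoints survive degenerate ones.

`first_decline_day()` flags the first scored day strictly below the previous
scored day's total — the deterioration signal that, in the validation
cohort, appeared on post-operative day four or five among survivors and
coincided with the mortality peak.

## Autopsy grading and concordance

`autopsy_total()` sums grades 0–3 over the six basal-cistern segments
(0–18). The severity cut-points for the total are not in the protocol's main
text; the defaults (mild 0–7, moderate 8–12, severe 13–18) follow the cited
grading convention for this scale and are an explicit, configurable
parameter rather than a hidden constant. `concordance()` reports exact
label agreement by default; because "similar severity evaluations" could
also be read as within-one-level, `tolerance = 1` implements that reading.

## The cohort simulator

`simulate_cohort()` exists so the entire pipeline — raw trials, tracks,
weights, events, autopsies — can be generated with known ground truth. Its
defaults are the validation study's conditions and are not tuned thereafter:

* subgroup sizes 6/18/5 (severe/moderate/mild), optional sham arm;
* day-1 measurements drawn from normal distributions with the published
  per-class mean and SD, truncated to the published range. The published
  summaries give only mean/SD/range, so the family is a modelling choice;
  truncated normals are the simplest family consistent with all three.
  Consequence: where the range is asymmetric about the mean (severe Rotarod
  38 ± 60 on [0, 154]), the realized mean exceeds the nominal one —
  parameter-recovery checks therefore compare against the closed-form
  truncated mean (`tnorm_moments()`), not the untruncated parameter;
* daily death hazards calibrated to the published pattern: severe 1/2 on
  day 2, 1/3 on day 3, 1 on day 4 (complete mortality by day 4); moderate
  1/9 on day 4 (two expected events among 18); mild zero. A quarter of
  mortality events are recorded as humane-endpoint euthanasias;
* decline onset drawn as day 4 with probability 2/3, day 5 otherwise
  (the 4:2 split observed among the six retrospectively analyzed
  survivors); after onset, Rotarod and open-field values decay
  geometrically (factor 0.6/day) and weight loss grows by 2.5
  points/day — a minimal trajectory model, all parameters in
  `sim_config()`;
* eight scheduled autopsies drawn uniformly among day-3 survivors;
  terminal harvest of all survivors on day 7;
* open-field distances realized as random-walk tracks whose key-frame path
  length equals the drawn distance to within 1e-6 (`make_track_fixture()`),
  so the behavior module operates on actual coordinate data end-to-end.

Correlation among the three components within an animal beyond the shared
latent class is not modelled: the published data provide no estimate of it.
Likewise the simulator targets the *statistical shape* of the measurements,
not hemorrhage physiology. Passing tests on simulated cohorts therefore
demonstrate the pipeline's arithmetic and statistical behavior under the
stated distributions — not performance on real video, real weight curves, or
distributional families other than the one assumed.

One calibration sanity check is asserted: scoring simulated day-1 data
recovers the latent class for at least 60% of animals under the default
distributions. The floor is a package convention (the classes overlap
substantially in single components, which is the protocol's own argument for
a composite score), not a published claim.

## Problem sizes and numerical conventions

The test suite and the reproduction script use desk-scale sizes chosen to
make Monte-Carlo conclusions stable: 200 replicate cohorts for
hazard-calibration and log-rank power checks, 1,000 animals per class for
parameter recovery (3-SE agreement), 10,000 permutations for the log-rank
oracle, dense grids (0.05–0.5 step) for band exhaustiveness. Displayed
mortality percentages are rounded to two decimals, matching the published
presentation; exact fractions are carried alongside. All simulation
randomness flows from a single integer seed per cohort; generated datasets
embed the seed and a configuration hash in their manifest.

## Known limitations

* The tracker is deliberately minimal and is validated only on synthetic
  stacks; real-video tracking should come from dedicated software, with
  `path_distance()` applied to its exported coordinates.
* Severity assignment uses day-1 scores only, as in the protocol; animals
  dying before day 1 are never classified.
* The log-rank test is asymptotic; at n = 29 with heavy ties the
  permutation check shows agreement within a few hundredths, which is
  adequate at the protocol's effect sizes but worth re-checking for much
  smaller cohorts.
* No Cox regression, competing-risks or longitudinal mixed modelling; the
  protocol's claims are desk-scale arithmetic and a single omnibus
  comparison, and the package keeps that scope.
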