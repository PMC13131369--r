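---
title: "Evaluating multi-camera cow-tracking systems: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-camera cow-tracking systems: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmcteval)
```

## The evaluation problem

Multi-camera multi-cow tracking (MCMCT) systems cover a freestall barn with
overlapping ceiling cameras and report, at every sampling tick, which cows
are present, who they are, what they are doing (eating, drinking, lying,
standing, walking, waiting) and in which functional zone of the barn they
are (alley, drinking trough, feeding trough, cubicle, AMS, AMS waiting
area). Identity is anchored by stationary RFID readers at the milking robot
(AMS): as a cow passes the reader her trajectory is tracked and compared,
via the discrete Fréchet distance, with a pool of reference trajectories
recorded during calibration, which ties the RFID ear-tag identity to the
visual track.

Validating such a system on a commercial farm poses a specific statistical
problem: there is no moment at which a cow can be "absent" from the barn,
so true negatives do not exist, and a cow must be *detected* before any
identity, activity or location can be assigned to her, so errors are
sequentially dependent. `mcmcteval` implements an evaluation framework
built around this structure, together with a synthetic data generator that
lets every estimator be exercised — and its statistical contracts tested —
without access to farm data, which remains on commercial farms.

## The hybrid confusion matrix

Detection is evaluated daily: the set of cows that visited the AMS at least
once between 0000 and 2359 h (ground truth of presence, via RFID) is
compared with the set of IDs the system detected that day
(`evaluate_detection_day()`). The cells are TP-D (present and detected),
FN-D (present, missed) and FP-D (a detection carrying an ID absent from the
day's herd registry — a "ghost"). There is no TN-D cell.

Identification is only defined among detected cows: TP-ID (assigned ID
matches the ear tag) and FN-ID (misidentified or unidentified). FP-ID and
TN-ID are structurally impossible, and the package's invariant
`tp_id + fn_id = tp_d` is asserted in the test suite.

The two stages merge into a single hybrid matrix (`classify_pairs()`):

* **TP** — present, detected, and task-correct;
* **FN** — present but either missed by detection or task-incorrect;
* **FP** — detection-stage spurious outputs, shared across tasks.

On the semantics of FP we follow the only reading consistent with a
published table in which TP% + FN% sums to ~100 while FP% sits outside that
sum and is constant per farm across tasks: FP counts spurious detections
(FP-D), so that precision penalises false alarms. Field descriptions of FP
are not always consistent with one another (the same source may elsewhere
describe FP as "present but not detected"), which is why the choice is
stated explicitly here.

Metrics are the standard ones,

$$\mathrm{recall} = \frac{TP}{TP+FN},\qquad
  \mathrm{precision} = \frac{TP}{TP+FP},\qquad
  F_1 = \frac{2\,PR}{P+R},$$

with two conventions worth noting (`compute_metrics()`): counts may be
fractional, so the rows of a published percentage table can be fed straight
through the equations for verification; and undefined denominators return a
flagged `NA`, never a silent zero. Percentages are formatted with half-up
rounding to two decimals (`percent()`, `round_half_up()`), the convention
of published performance tables — base R's round-half-even would disagree
on boundaries.

For activity and location the default correctness criterion is a label
match among detected cows regardless of identity correctness. This is
deliberate: a system can classify the activity of a cow it has
misidentified, and published tables show activity TP above identification
TP on the same farm, which is only possible under this scope. The
`restrict_to_identified = TRUE` switch gives the stricter scope (credit
only for correctly identified cows) when that is the question of interest.

## Sample size for the observer campaign

On-farm validation uses a single observer as gold standard. The number of
visual observations required is the classical population-proportion sample
size $n_0 = z^2 p(1-p)/e^2$ with finite-population correction
$n = n_0/(1 + (n_0-1)/N)$, rounded up (`sample_size()`). With the
conservative $p = 0.5$, a 5% absolute margin and 95% confidence, $n_0$
rounds to 385 and a 70-cow herd needs 60 observations. The z-value is the
exact quantile 1.959964, not the rounded 1.96, with an explicit `z`
override for reproducing calculators that use the rounded value (both give
60 and 385 here).

## The synthetic herd and the error model

`simulate_herd()` generates gold-standard behavior for a configured farm on
a 5-minute grid (288 ticks/day; 8,928 ticks per farm over a 31-day study
period — both defaults can be changed). Behavior is a per-cow semi-Markov
schedule: activity bouts with geometric lengths (minimum one tick), drawn
with time-of-day-modulated weights. The defaults encode what a
practitioner would call a realistic freestall time budget — roughly half
the day lying with a 2.5-fold lying boost at night (2200–0600), a morning
feeding peak (0700–0900, eating weight tripled), mean bout lengths of one
hour for lying down to one tick for drinking and walking — and a mean of
2.5 AMS visits per cow-day (zero-truncated Poisson, visit times uniform),
with every cow visiting every day by default so the daily evaluation
denominator is exactly the herd size. No field time-budget data stand
behind these defaults; they are stated modelling assumptions, chosen once.
The generator guarantees only marginal properties (event-count
conservation, closed vocabularies, activity–zone compatibility, night
lying elevation, visit coverage), not behavioral microstructure: there is
no social behavior, estrus, or spatially continuous movement model, so
passing tests say nothing about those aspects of real data.

`emulate_system()` degrades the truth into system outputs under
`error_model()`:

* **daily_miss** acts at the cow-day level — a missed cow is absent from
  the whole day's detected set — because detection is evaluated daily;
* **ghost_rate** injects spurious IDs from a disjoint `ghost*` namespace
  in short presence bouts;
* **id_correct / id_swap_share** corrupt identities per record (swap to
  another herd ID or emit `"unknown"`);
* **activity_confusion** is a row-stochastic 6×6 matrix; location errors
  co-occur with activity errors with probability `location_cooccur`
  (errors are coupled: a misread activity usually comes with a misread
  zone) and otherwise arise at a small base rate;
* **night_detect_drop** thins per-tick presence at night, producing the
  day–night detection gap the stability analysis is designed to find.

Defaults (7% daily miss, 75% correct identification, 90% activity
accuracy, 0.8 error co-occurrence, 15-point night drop, ghosts at 10% of
herd size per day) were fixed once at the operating point reported for
commercial installations of this class — detection recall in the
90s, identification recall in the 70s, day–night gaps within ~10–18
points — and are not tuned thereafter.

Detection snapshots carry the *true* identities of detected cows (plus
ghost IDs): daily detection asks "which cows did the system see", a
question the RFID anchoring answers independently of the per-record
identity errors that the identification task evaluates. Records carry a
`true_id` bookkeeping column — in a real deployment that linkage is
exactly what the human observer supplies.

### Trajectory identification

`discrete_frechet()` implements the dynamic program over the coupling
lattice; the variant is discrete (the continuous Fréchet distance requires
polyline interpolation and is not what trajectory samples on a fixed grid
support naturally), with the matching threshold exposed as an explicit
parameter since no canonical value exists. `assign_identity()` gates
matches at the threshold and, for batches, returns the injective
assignment minimising total distance with unassigned tracks priced at the
threshold — a price that makes the single-track rule ("match iff the best
reference is within the threshold") a special case of the batch rule. A
greedy lowest-distance-first heuristic agrees with this optimum in the
typical well-separated case but not always; the package implements the
optimum (exact branch-and-bound, exponential only in the number of
*competing* tracks, which is small in practice) and the tests verify it
against exhaustive enumeration. Ties are broken by lexicographic reference
ID for determinism.

## Detection stability

The per-tick detected counts are averaged within each hour
(`hourly_proportions()`; averaging, not summing — a sum differs only by
the factor 12 and breaks the interpretation as a proportion) and divided
by the day's AMS-visiting cow count. Proportions above 1 are legal and
retained on the linear scale (no logit transform): they are the signature
of overdetection and have been reported in the field (e.g. hourly means
above 100%).

`fit_hour_day_model()` fits hour as a fixed effect and day as a random
effect. The design is balanced by construction (every day contributes
every hour), so the package uses the exact moment (ANOVA) estimators,
which coincide with REML in this layout: residual variance from the
hour×day interaction mean square, day variance
$\max(0, (MS_{day} - MS_{resid})/H)$, hourly-mean standard error
$\sqrt{(\sigma^2_{day} + \sigma^2_{resid})/D}$. Unbalanced input is an
explicit error rather than a silent approximation — a general sparse
mixed-model solver is out of scope, and the balanced closed form is
verified in the tests against an iterative restricted-likelihood
optimiser. Within-day contrasts cancel the day effect, so the pairwise
contrast SE is $\sqrt{2\sigma^2_{resid}/D}$ with
$(H-1)(D-1)$ residual degrees of freedom — the classical balanced two-way
values. `tukey_pairwise()` adjusts all $\binom{H}{2}$ comparisons (276
for a 24-hour day) with the studentized range distribution; a degenerate
fit (zero residual variance with unequal means) yields p = 0 and a
boundary-case warning. The default significance threshold is 0.01.

## Numerical and reproducibility choices

* All randomness flows from one master seed via `stage_seed()` (a
  byte-level mix of the stage name, kept within 31 bits), so stages rerun
  independently yet byte-identically; `run_pipeline()` records every seed
  consumed in its log and a config hash in its manifest.
* Timestamps are (day index, minutes since midnight) on a left-closed
  0-based grid; calendar conversions live only in the I/O layer, which
  writes comma-separated UTF-8 with mandatory headers and no
  locale-dependent formatting.
* Half-up rounding adds a relative `1e-12` guard before truncation so that
  values stored just below a `.5` boundary by binary floating point round
  as printed arithmetic would.
* The test suite exercises herd-scale parameter recovery at 250 cows × 31
  days and Monte-Carlo checks (variance-component recovery, familywise
  error control) at 200 replicates; these sizes give Monte-Carlo standard
  errors comfortably below the tested tolerances while keeping the suite
  fast.

## Known limitations

* The generator's time budgets and the error model's defaults are
  assumptions, not field estimates; conclusions about a real system
  require the observer protocol, not the emulator.
* Camera geometry, occlusion, lighting and coat-pattern effects are not
  modelled — the error model summarises their consequences as rates.
* The stability model assumes exchangeable day effects; within-day
  autocorrelation of the 5-minute series beyond the hour averaging is not
  modelled.
* The finite populations behind some published sample-size figures (106
  and 140) are not stated in the field literature and cannot be reproduced
  from any herd size with the standard correction; `sample_size()`
  therefore exposes `N` as an explicit input and reproduces the derivable
  values (60 at N = 70; 385 unadjusted).

## A worked example

```{r example, eval = FALSE}
farm <- read_farm_config(example_farm_path("H1"))
manifest <- run_pipeline(farm, "h1_run", seed = 7, n_days = 31)
readLines(file.path("h1_run", "report.txt"))
```

The report lists, per task, TP/FN/FP percentages with recall, precision
and F1, followed by the stability summary (variance components, hourly SE,
number of Tukey-significant hour pairs) and the minimum observer sample
size for the farm's herd.
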