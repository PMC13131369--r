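# mcmcteval

Evaluation toolkit for **multi-camera multi-cow tracking (MCMCT)** systems
in freestall dairy barns — for animal scientists and precision-livestock
engineers who need to quantify, with defensible statistics, how well a
camera system detects cows, identifies them, and classifies their activity
and barn-zone location under commercial conditions.

Real validation data from such systems stay on commercial farms, so the
package pairs the evaluation framework with a synthetic data generator: a
configurable herd-behavior simulator and a monitoring-system emulator whose
error rates are known, letting every estimator be exercised and its
statistical contracts verified end to end.

## What it implements

**Hybrid detection→identification confusion matrix.** In a barn there are
no true negatives (every animal in view belongs to the herd), and a cow
must be detected before she can be identified, so detection and
identification errors are sequentially dependent. Detection is scored
daily against the RFID-anchored list of cows visiting the automatic
milking system (TP-D, FN-D, FP-D); identification only among detected cows
(TP-ID, FN-ID; FP-ID and TN-ID cannot exist). The merged matrix has

- TP = present, detected and task-correct,
- FN = present but missed or task-incorrect,
- FP = detection-stage spurious outputs ("ghost" IDs), shared across tasks,

with recall = TP/(TP+FN), precision = TP/(TP+FP), and F1 their harmonic
mean.

**Sample-size design** for the on-farm observer campaign:
n₀ = z²p(1−p)/e² with finite-population correction n₀/(1+(n₀−1)/N). With
p = 0.5, e = 0.05, 95% confidence: 385 unadjusted, 60 for a 70-cow herd.

**Detection stability.** Per-tick detected counts (5-minute grid, 288
ticks/day) are averaged per hour, divided by the day's AMS-visiting cow
count, and fitted with hour as a fixed effect and day as a random effect —
an exact moment/REML fit for the balanced layout — followed by
Tukey-adjusted pairwise comparisons of all 276 hour pairs via the
studentized range distribution.

**Trajectory identification.** Discrete Fréchet distance (dynamic
programming) between observed and calibration reference trajectories, with
threshold-gated, injective, minimum-total-cost batch assignment.

## Worked example

```r
library(mcmcteval)
farm <- read_farm_config(example_farm_path("H1"))  # 70 cows, 625 m2, 3 cameras
manifest <- run_pipeline(farm, "h1_run", seed = 7, n_days = 31)
writeLines(readLines(file.path("h1_run", "report.txt")))
```

```
Performance of detection, identification, activity classification, and location
Farm   Task                TP(%)    FN(%)    FP(%)   Recall  Precision       F1
H1     detection           92.86     7.14     8.89    92.86      91.26    92.05
H1     identification      66.20    33.80     0.19    66.20      99.72    79.57
H1     activity            79.39    20.61     0.19    79.39      99.77    88.42
H1     location            79.66    20.34     0.19    79.66      99.77    88.59

Detection stability: 24 hours x 31 days; hourly-mean SE 0.43%; day var 0.000527, residual var 5.71e-05
Tukey-adjusted pairwise hour comparisons: 128 of 276 significant at alpha = 0.01

Minimum visual-observation sample size (p = 0.5, e = 0.05, 95% confidence, finite herd): 60
```

Reading the numbers: the emulator was configured with a 7% daily detection
miss rate, so pooled daily detection recall lands at 92.86% over the 70 ×
31 cow-days; precision 91.26% reflects the injected ghost detections.
Identification recall 66.20% is the product of per-record identity
accuracy (75%) and per-tick detection coverage; restricted to detected
records it recovers ~75%. The stability fit flags 128 of 276 hour pairs as
significantly different at P < 0.01, driven by the emulator's 15-point
night-time detection drop (2200–0600). The sample size 60 is the minimum
observer campaign for a 70-cow herd at p = 0.5, e = 5%, 95% confidence.

A shell entry point wrapping the same stages
(`simulate,emulate,evaluate,stability,samplesize,report`) ships in
`inst/scripts/mcmct_pipeline.R`:

```sh
Rscript inst/scripts/mcmct_pipeline.R all \
  --config inst/extdata/farm_h1.yaml --seed 7 --outdir h1_run
```

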