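# darcsrf

Longitudinal prediction of subretinal fluid (SRF) — the hallmark of wet
age-related macular degeneration — from baseline **DARC** imaging
(Detection of Apoptosing Retinal Cells: fluorescent annexin V binding
phosphatidylserine exposed on stressed cells, visible as bright spots in
en-face cSLO images). The package is written for retinal-imaging
researchers who want to test whether baseline apoptosis/angiogenesis spots
anticipate where and when new fluid appears on OCT, without access to the
original trial's patient images: a synthetic cohort generator with known
ground truth stands in for the data, and every analysis stage is a tested,
reusable function.

## What it computes

For each eye, follow-up is split into half-open 6-month windows
[6k, 6(k+1)). Per visit the SRF amount is the pixel sum of the binary
segmentation masks over all B-scans; per interval the **accumulated SRF**
is the scan-count average

    A_k = (total SRF pixels across scans in interval k) / (number of scans in k),

which normalises uneven visit schedules. An interval is SRF-positive when
A_k exceeds a threshold (default 0: any fluid); **new SRF** at interval k
means positive at k after a negative preceding period, and an eye's
**conversion** is its first such interval (baseline-positive eyes cannot
newly convert and are excluded from denominators).

Baseline DARC spots are detected by matched filtering (normalized
cross-correlation with a Gaussian template + greedy non-maximum
suppression), cleaned of pre-injection autofluorescent spots, and mapped
into OCT (slice, column) coordinates through fiducial-based affine
registration (optionally refined by a multi-resolution B-spline
displacement field). A **unique DARC spot** is counted once, at the first
interval where it overlies SRF (spots over baseline fluid are excluded).
Per interval, each eye is classified

| unique spots | new SRF | label |
|---|---|---|
| ≥1 | yes | TP |
| 0  | yes | FN |
| ≥1 | no  | FP |
| 0  | no  | TN |

from which PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN)
and specificity = TN/(TN+FP) are derived (undefined cells reported as
missing, never 0 or 1). The package also computes SRF-free survival curves
split at DARC count > 5 with exact signed-rank and regression-slope
comparisons, per-interval Spearman correlation of unique-spot counts with
SRF magnitude, pixel-level precision/recall/F1/AUC for segmentation
evaluation, and Cohen's kappa for clinical-vs-automated agreement.

## Worked example

```r
library(darcsrf)

rc  <- run_config(cohort = cohort_config(n_eyes = 29, seed = 42),
                  use_planted_spots = TRUE)
res <- run_pipeline(rc)
res$confusion[, c("interval","tp","fp","fn","tn","ppv","npv",
                  "sensitivity","specificity")]
#>   interval tp fp fn tn ppv  npv sensitivity specificity
#> 1        0  0  1  1 27   0 0.96        0.00        0.96
#> 2        1  0  3  0 26   0 1.00          NA        0.90
#> 3        2  0  2  0 27   0 1.00          NA        0.93
#> 4        3  0  0  0 29  NA 1.00          NA        1.00
#> 5        4  3  0  1 25   1 0.96        0.75        1.00
#> 6        5  0  1  0 28   0 1.00          NA        0.97

res$conversion
#>   interval rate
#> 1        0    5
#> ...
#> 6        5   25
```

Row 5 reads: in months 24–30, three eyes with new SRF had a unique DARC
spot over the fluid (TP), one converted without one (FN), and no
fluid-free eye was flagged (FP = 0), giving PPV 1.0 and sensitivity 0.75
for that interval; 25% of at-risk eyes had converted by then. Under the
default (weak-association) conditions most positives are chance overlaps —
drive `association_strength` toward 1 and PPV rises to exactly 1 in the
no-nuisance limit.

The two study numbers recomputable at the desk:

```r
cohens_kappa(8, 3, 2, 16)$kappa   # baseline clinical-vs-automated agreement
#> 0.627
f1_score(0.89, 0.72)              # segmentation F1 from printed P/R
#> 0.80
```

The numbered drivers under `analysis/` (`01_simulate_cohort.R` …
`05_statistics.R`) run the stages as a narrative workflow and write their
tables under `results/`.

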