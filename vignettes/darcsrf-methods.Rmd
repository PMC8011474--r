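---
title: "Predicting subretinal fluid conversion from DARC spot imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting subretinal fluid conversion from DARC spot imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darcsrf)
```

## The problem

In age-related macular degeneration (AMD), conversion to the "wet" form —
choroidal neovascularization leaking fluid under the retina — is the event
that destroys vision, and the event clinicians most want to anticipate.
DARC (Detection of Apoptosing Retinal Cells) imaging labels stressed cells
with fluorescent annexin V: after intravenous injection, positive cells
appear as bright spots in en-face confocal scanning laser ophthalmoscope
(cSLO) images. Because phosphatidylserine exposure on endothelial cells is
one of the earliest steps of angiogenesis, a baseline DARC spot may mark a
location where subretinal fluid (SRF) will appear months later on OCT.

`darcsrf` implements the full analysis chain for testing that idea
longitudinally: align the en-face spot frame to OCT volume coordinates,
quantify SRF per 6-month interval, apply new-SRF / conversion / unique-spot
definitions, and evaluate the prediction with per-interval confusion
matrices, predictive values, SRF-free survival split by DARC count, and
SRF-magnitude correlations. Because no patient images are distributed with
the original trial, the package ships a synthetic cohort generator with
known ground truth; every downstream stage is exercised and validated
against that truth.

## The synthetic cohort model

`cohort_config()` / `generate_cohort()` emulate the structure of a 29-eye,
36-month AMD cohort:

* **Spots.** Per eye, Poisson numbers of *angiogenic* spots (mean 5),
  *nuisance* spots (mean 2, non-predictive probe signal), and baseline
  *autofluorescent* spots (mean 2, visible before injection), all at
  uniform positions within the OCT fundus footprint.
* **Visits.** Each 6-month interval receives a Poisson number of OCT visits
  (mean 2.1, minimum 1) at uniform dates, plus a baseline visit at month 0.
  This reproduces the uneven-scan problem the per-interval averaging
  normalises for; the emulated range of scans per eye per interval brackets
  the 1.7–2.6 seen in the study cohort.
* **Lesions.** Each eye draws one *activity onset* interval (uniform over
  intervals 1 to 5). Each angiogenic spot independently seeds an elliptical
  SRF lesion centred on it, with probability `association_strength`, at
  that onset. Spot-independent *spontaneous* lesions (Poisson mean 0.15,
  uniform onset) model background conversion, and a `baseline_srf_fraction`
  of eyes (default 0.34, matching 10/29 in the study) carry a lesion from
  month 0. Lesions grow by 25% per interval about a fixed centre, so masks
  are non-decreasing after onset; an optional `regression` flag lets
  lesions clear, enabling clear-and-recur scenarios.
* **Rendering.** En-face frames are flat background (20) plus Gaussian
  noise (SD 10) plus one Gaussian blob per spot (peak 100, sigma 2 px):
  amplitude/noise = 10 is the operating point at which the detector is
  gated. B-scan masks rasterise each lesion's per-slice column chord over a
  fixed 4-row axial band.

Two design choices deserve emphasis. First, the onset interval is drawn
**per eye**, not per spot: spot-seeded lesions of one eye appear together.
This is the clinically natural reading (a neovascular activity episode)
and it is what makes the designed limit exact — with `association_strength
= 1` and no nuisance input, every positive eye-interval call is a true
positive (PPV = 1), because no spot can first-overlap fluid in an interval
where the eye is not newly converting. With independent per-spot onsets
the classification rule itself would generate false positives in that
limit. Second, angiogenic spots precede onset by at least one interval,
encoding the premise that the apoptosis signal marks pre-leakage
endothelial activity.

Defaults were fixed once, from the study's printed cohort structure and a
closed form: an at-risk eye converts with probability
$1 - \exp(-(\textit{association} \times \textit{spot mean} +
\textit{spontaneous mean}))$, and $0.05 \times 5 + 0.15 = 0.4$ gives a
36-month conversion probability of 33%, the study's printed cumulative
rate. The onset-time model is uniform, so the *shape* of the cumulative
conversion curve (front-loaded in the study) is not reproduced — only its
36-month level. Counts per diagnosis subgroup were never published and the
generator does not attempt them.

What passing tests on this generator do **not** show: robustness to real
cSLO vignetting, vessel crossings and motion artefacts; OCT speckle;
intraretinal fluid or pigment-epithelial detachment (deliberately out of
scope — the analysis is SRF-only); or detector performance on real trial
images, where the original work used a trained CNN.

## Registration

The study aligned frames with an affine transform followed by a non-rigid
B-spline refinement, and mapped en-face points into the OCT volume via
manually placed fiducials.

* `fit_affine()` solves the least-squares 2×3 map from ≥ 3 non-collinear
  fiducial pairs by normal equations; with exactly 3 pairs the fit is
  exact. Degenerate configurations raise errors rather than returning
  unstable fits.
* `nonrigid_refine()` parameterises a dense displacement field as cubic
  B-spline interpolation of control-point offsets (default spacing 16 px)
  and minimises the mean squared intensity difference by gradient descent
  with a backtracking line search, over three resolution levels (4×, 2×,
  1×). Only improving steps are accepted, so the objective never rises
  above its affine initialisation; hitting the iteration cap returns the
  best-so-far field with a warning. MSE was chosen as the similarity
  metric as the simplest differentiable choice for same-modality frames;
  grid spacing, schedule and stopping tolerance are declared defaults, not
  reproductions of the original software's settings.
* `fundus_to_oct()` maps a registered point to (slice, column) by nearest
  slice row, ties broken toward the lower index — a documented,
  deterministic rule. All coordinates are 0-based pixel centres with
  (x = column, y = row); a single convention throughout prevents
  off-by-one registration bugs.

## Spot detection

The trained spot-classification CNN is unavailable, and the study states
its candidates came from template matching — so the package's detector is
the classical chain: normalized cross-correlation with a Gaussian template
(sigma 2 px, uncalibrated default since the study gives no spot-size
prior or pixel scale), local maxima above a correlation threshold (0.5),
then greedy non-maximum suppression by descending score within a 5-px
radius, ties broken by (y, x) order for determinism. Baseline
autofluorescent spots — visible before the probe is injected, hence not
probe signal — are removed by proximity matching (radius 4 px). The
DARC count is the accepted-spot count after that subtraction.

On the gate conditions (20 planted spots, amplitude/noise 10, 100 images)
the detector's sensitivity and precision both exceed 0.99; the suite
requires ≥ 0.9, an aspiration mirroring (not reproducing) the original
CNN's reported performance. Spot matching is greedy nearest-neighbour;
its agreement with the optimal assignment is only claimed, and only
tested, for jitter below half the match radius.

## SRF quantification and conversion

Per visit, the SRF amount is the raw sum of segmented SRF pixels over all
B-scans (`visit_srf_amount()`). The accumulated SRF of a 6-month interval
is that total divided by the number of scans in the interval
(`interval_accumulated_srf()`) — the scan-count average is the only
normalisation the source analysis states explicitly, so no further
per-slice normalisation is applied. Intervals are half-open
$[6k, 6(k+1))$ months from the DARC imaging date; boundary visits belong
to the later interval. SRF positivity defaults to "any detected SRF"
(threshold 0 px) with a configurable minimum to reject speckle. Scan-free
intervals carry the previous status forward and are flagged; flagged
intervals are excluded from correlation analyses.

New SRF at interval *k* means SRF-positive at *k* with an SRF-negative
preceding period (baseline status for *k* = 0). An eye's conversion is the
*first* such interval; eyes SRF-positive at baseline cannot newly convert
and are excluded from conversion denominators and survival at-risk sets.
Whether an eye may convert a second time after clearing is ambiguous in
the source; the first-occurrence rule is adopted, and later clear-and-recur
intervals still raise the interval-level new-SRF flag (used by the
confusion matrices) without redefining the eye's conversion.

`precision_recall()` evaluates segmentation quality by pooling pixel
TP/FP/FN over images, with the F1 identity 2PR/(P+R) and a trapezoidal
area over the recall axis; the printed operating point (precision 0.89,
recall 0.72) reproduces F1 0.80 through that identity.

## Unique-spot prediction

A spot overlying SRF at baseline is excluded outright. Each remaining spot
contributes once — at the first interval where it overlies SRF within the
tolerance window, default ±1 slice and ±10 columns, reflecting the
anisotropy of a 50-slice volume; the source never quantifies "overlying",
so the window is exposed in `run_config()`. Eye-interval classification is
the quoted decision rule: unique spots + new SRF → TP; new SRF only → FN;
unique spots only → FP; neither → TN. Eyes already converted remain in
later matrices, classified by that interval's new-SRF flag (false after
first conversion unless fluid clears and recurs); "an eye with SRF" in the
FN rule is read as *new* SRF, for symmetry with the TP rule. Undefined
metrics (zero denominators, common at small n) are reported as missing,
never as 0 or 1.

`srf_free_survival()` computes, per interval and DARC-count group
(> 5 vs ≤ 5), the proportion of at-risk eyes not yet converted;
`compare_groups()` pairs the per-interval proportions in a signed-rank
test and compares regression slopes via the pooled interaction term.
`spot_srf_association()` reports per-interval Spearman correlations of
unique-spot counts with accumulated SRF and a Mann-Whitney comparison
between high- and low-SRF eyes. The high/low split defaults to 2000
pixels: the source text says 2000 pixels while its figure legend says
3000 µm² — the conflict cannot be resolved from the publication, so the
threshold is a parameter and the textual value is the default.

## Exact statistics

Small-sample p-values in the source are reproducible only as exact
enumerations, so the kernels are implemented in-house
(`cohens_kappa()`, `spearman_rho()`, `mann_whitney()`,
`wilcoxon_signed_rank()`, `linreg_compare()`): the signed-rank test
enumerates all $2^m$ sign patterns for up to 12 nonzero pairs — seven
uniformly signed pairs give $2/2^7 = 0.015625$, the printed group-split
p-value — and the rank-sum test enumerates all group assignments for up
to 10 per group, handling ties through mid-ranks. Larger samples switch
to continuity-corrected normal approximations, which agree with the exact
branch to within 0.02 at the boundary sizes. All tests are two-sided (the
source does not state sidedness). Kappa is reported without a standard
error: the publication's p = 0.001 for it would need a variance model it
does not give. Base R's `wilcox.test`, `cor` and `lm` serve as independent
cross-checks in the test suite, never as the implementation.

## Numerical and degenerate-input choices

* Slice and column ties map to the lower index; NMS score ties resolve by
  (y, x) order; greedy matching processes candidate pairs by increasing
  distance. All three rules exist to make runs bit-reproducible.
* `interval_accumulated_srf` of an empty window is missing (flagged), not
  zero; `srf_positive` of a missing value is missing and triggers
  carry-forward; degenerate confusion cells yield missing metrics.
* The generator, the pipeline and the report writer are fully determined
  by `seed`; the run manifest records the seed, a config fingerprint and
  every threshold used.

## Problem sizes

Simulation-based checks run at deliberately modest sizes chosen to probe
the contracts rather than maximise realism: 128-px frames with 25-slice
volumes and 12–20 eyes for cohort-level properties, 100 rendered images
for the detector gate, 100 seeded cohorts per association limit, and a
400-replicate Monte-Carlo oracle for the chance-overlap level. The
acceptance script (`scripts/acceptance.R`) recomputes all headline
quantities from scratch at those sizes. The PPV-limit experiments feed the
generator's planted spot coordinates directly into the analysis
(`use_planted_spots`): the limit probes the spot–SRF linkage logic, and a
rare spurious detection would otherwise break an exact designed limit for
reasons already covered by the detector gate.

## Known limitations

* The classifier stand-ins (template matching, rule filters) do not aim at
  the original CNNs' performance on real images; no training is involved.
* Registration is en-face only; no axial (3-D) alignment, and no reading
  of proprietary scanner formats.
* The generator plants axis-aligned elliptical lesions with deterministic
  growth; real CNV lesions are irregular and their fluid waxes and wanes
  under treatment.
* Conversion timing is uniform over follow-up; the study's observed
  hazard was front-loaded.
* Table-1-level predictive values of the actual trial are not reproducible
  without the patient data and are not targets of this package.
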