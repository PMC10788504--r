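---
title: "Avalanche transition matrices for motor-imagery decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avalanche transition matrices for motor-imagery decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avalanchr)
```

## The scientific question

Large-scale brain activity is intermittent: brief bursts of above-threshold
activations — neuronal avalanches — spread across cortical regions and then
die out. If avalanches mediate inter-regional communication, the *routes*
they take should reconfigure with the task being performed. `avalanchr`
implements an analysis built on that idea for motor-imagery (MI)
brain-computer interfaces: it tracks, per pair of regions, the probability
that an avalanche recruits region *j* right after region *i* (the avalanche
transition matrix, ATM), tests where that probability differs between MI and
resting state, relates those differences to BCI performance, and asks
whether the ATM is a competitive decoding feature compared with common
spatial patterns (CSP).

## The data pipeline

Starting from epoched source-level recordings (trials x regions x samples):

1. **Binarization.** Each region is z-scored over time, independently and
   within each trial (epochs are the analysis unit, and per-trial scoring
   avoids session drift). A sample is *active* when `|z|` exceeds a
   threshold (default 3). Samples are then OR-merged into bins of 1-3
   samples: a bin is active if any of its samples is. Binarize-then-bin
   preserves threshold crossings, which is the standard avalanche
   convention. A region with zero variance in a trial is a hard error (the
   z-score is undefined), reported with region and trial.
2. **Segmentation.** An avalanche starts when at least one region is active
   and finishes when no region is active: maximal runs of consecutive
   non-empty bins, per trial. Runs touching an epoch edge are kept and
   flagged truncated — real epochs cut avalanches too, and dropping them
   would bias against long events.
3. **Transition matrices.** For one avalanche, entry `(i, j)` is the number
   of frames with `i` active at `t` and `j` active at `t + 1`, divided by
   the number of frames (before the last bin) with `i` active. The diagonal
   is estimated identically and encodes self-persistence. A source region
   with no successor frame yields an all-zero row rather than `NaN`, so
   averages stay defined; the convention is uniform across the package.
   Per-trial and per-condition ATMs are edge-wise arithmetic means over
   avalanches (the default); pooling transition counts before normalizing
   is available as `mode = "pooled"` since the two estimators differ on
   unbalanced avalanches and the averaged form is the one the analysis is
   defined on.
4. **Branching ratio.** For an avalanche spanning `N` bins with `n(j)`
   activations in bin `j`, the per-avalanche branching parameter is the
   geometric mean of `n(j + 1) / n(j)`; the overall estimate is the
   geometric mean over avalanches. Single-bin avalanches admit no ratio and
   are excluded (their number is reported). `sigma = 1` marks critical
   dynamics and is the criterion for choosing the bin length (bin length 1
   is the default).

## The synthetic cohort generator

Real source-reconstructed MEG/EEG cohorts of this design are not freely
redistributable, so validation runs on a generator that plants known
structure and emulates the study geometry: 20 subjects, 68 regions, 7-s
epochs at 250 Hz, 48 trials per condition, hit/miss outcomes, and one BCI
score per subject. A `"small"` profile (19 regions, 2-s epochs) keeps unit
tests fast; the suite states per test which profile it uses.

The cascade model is a branching process on a weighted directed graph:
a region active at bin `t` fires each outgoing edge independently at
`t + 1` with the edge's transmission probability; the expected offspring
count of an active region is its row sum, so rows are normalized to the
target branching ratio (`sigma_target`, default 1, i.e. critical). Because
the ATM estimand — the conditional activation probability — is then known
analytically, every downstream stage can be checked against ground truth.
The resting graph is a ring lattice (self-loop plus `out_degree = 4`
neighbours). Planted edges connect a "premotor-like" source group to a
"parietal-like" target group (8 regions each at 68 regions) in a 2-regular
bipartite layout with twice the baseline weight: strong existing pathways
whose MI up-regulation (`effect_size`, reference value 2) concentrates on
hubs without giving any single source row an explosive outflow. Miss trials
scale the MI-minus-Rest difference by `miss_attenuation` (default 0.5), so
misses interpolate between the conditions and `miss_attenuation = 1` makes
hit and miss trials exchangeable.

Design choices that deserve justification:

* **Clustered initiations.** Spontaneous activity arrives as seed events
  (per-bin rate matching a mean per-region initiation probability of
  `spontaneous_rate`, default `1e-3`), each igniting `1 + Poisson(0.25)`
  regions at once. With strictly single-region seeds the within-avalanche
  geometric estimator is almost blind to the true branching ratio: an
  avalanche that starts with one event can only keep `n >= 1` until it
  ends, so per-avalanche ratios rarely fall below 1 and the estimate pins
  near 1.06 whatever the offspring mean. Multi-event first bins — which
  real recordings show, since several regions can cross threshold in the
  same bin — restore the estimator's sensitivity. The cluster mean 0.25 is
  calibrated once, at the default 68-region critical geometry, so the
  estimator is centered on `sigma_target`; away from criticality and on
  much smaller graphs the centering is approximate.
* **Estimator conditioning.** The estimator ignores the terminal
  transition to zero activity (the bin after the avalanche is, by
  definition, empty), which is why naive single-seed processes read high.
  This is a property of the estimator, not a bug in the generator, and the
  calibration above accounts for it.
* **Subject variability and BCI scores.** Each subject's weights are the
  ground truth under multiplicative log-normal jitter (sd
  `subject_variability = 0.15`), plus a subject-level gain on the planted
  difference. The BCI score is a logistic function of the subject's
  realized mean planted effect, centered at `hit_rate` (default 0.7) for
  the nominal effect, plus Gaussian noise (sd 0.05), clipped to `[0, 1]`.
  The slope (10) is set so the between-subject spread of the realized
  effect moves scores by somewhat more than the noise floor — a monotone
  but noisy link, which is all the correlation analysis assumes.
* **Saturation.** A region cannot be recruited twice in one bin, so very
  dense planted structures make effective branching sub-multiplicative;
  at the default geometry this bias is well below the acceptance tolerance.

What the generator does **not** emulate: oscillatory (band-limited) M/EEG
content, 1/f background spectra, autocorrelated noise, volume conduction,
and source-leakage. The background is white Gaussian noise into which
active bins are embedded as deflections guaranteed to survive re-binarization
(exactly on planted cells; background samples still cross threshold at the
analytic chance rate). Passing tests therefore validate the *statistics*
of the pipeline, not its robustness to M/EEG artifacts.

## Permutation statistics

All permutation p-values include the observed statistic in the null, so
`p >= 1 / (n_permutations + 1)`; seeded runs are bit-reproducible.

* **Subject edge test.** Trial-specific ATMs are randomly reallocated to
  the two conditions; the two-sided p-value per edge ranks the observed
  absolute mean difference within the permuted ones. When at most
  `n_permutations` distinct assignments exist, the full enumeration is used
  instead. BH/FDR is applied across all edges, diagonal included.
* **A granularity caveat** worth knowing when choosing `n_permutations`:
  with `m` edges, BH at level `alpha` can only reject if at least
  `m / (alpha * (n_permutations + 1))` p-values sit near the permutation
  floor. At 68 regions (4624 edges) and `alpha = 0.05`, 1000 permutations
  require ~93 floor-level edges before anything survives, while 10,000
  (the default) requires ~10. Subject-level analyses in the test-suite use
  10,000-20,000 permutations for this reason; the null-cohort
  false-discovery check uses 1000 at both levels, which makes it strictly
  conservative.
* **Group reliability.** The observed per-edge count of subjects with a
  significant difference is compared against relocating each subject's
  significant edges uniformly at random (preserving their number per
  subject), with BH across edges. Edges passing are "reliable".
* **Node concordance.** Nodal degree (in + out, diagonal counted once) of
  the reliable mask versus degrees of uniformly random placements of the
  same number of edges; BH across regions. In the generator the planted
  effect is directed, and the secondary (network-mediated) differences
  also accumulate where avalanches arrive, so the regions this stage flags
  are the planted *targets* and their immediate downstream neighbourhood.
* **Hit/miss contrast.** Per edge,
  `|diff(MI, Rest | hit)| - |diff(MI, Rest | miss)|`, with a null that
  shuffles outcomes within each condition; one-sided (greater), evaluated
  on the reliable-edge mask, with a per-subject scalar summary (the mean
  over masked edges) for aggregation.
* **BCI-score correlation.** Spearman correlation per edge (average ranks
  for ties) between the subject's MI-minus-Rest difference and the BCI
  score, averaged within each directed pair of five functional areas
  (5 x 5 = 25 blocks, self-pairs included), against a null that reallocates
  the edge-to-block assignment of the coefficients; two-sided p per block,
  BH across the 25 blocks. Edges with constant differences across subjects
  have no defined coefficient and are excluded from both the block means
  and the reallocation pool. The shipped Desikan-Killiany map
  (`default_area_map()`) is an approximate lobe-level grouping intended to
  be edited; `synthetic_area_map()` produces the matching grouping for
  generated parcellations.

## Decoding benchmark

Fifty stratified random splits put 80% of trials in training and 20% in
test; both pipelines consume byte-identical splits. The CSP baseline
whitens the summed class covariances (Ledoit-Wolf shrinkage toward a scaled
identity, written in-package, with automatically chosen intensity — short
synthetic trials make raw covariances ill-conditioned), retains the 8
eigenvalue-extreme filters (4 per class), fixes signs so the
largest-magnitude coefficient is positive, and uses log-variance features
("average power" up to the monotone log, which conditions the classifier
input). ATM features are the full flattened directed matrix (row-major,
diagonal included) of each trial's ATM, with the binarization threshold
chosen per split by stratified inner cross-validation **on the training
split only** — the optimal-threshold idea admits a leaky reading, which is
deliberately rejected. Both feature sets feed a linear-kernel maximum-margin
classifier with regularization constant 1 (features standardized with
training statistics). Per subject, the 50 paired accuracies are compared
with a paired t-test, confirmed by a paired Wilcoxon signed-rank test, and
BH-corrected across subjects; decisions are three-way with direction.
Degenerate (zero-variance) accuracy differences fall back to the sign of
the mean difference and are flagged.

## Problem sizes and tolerances used by the test-suite

The suite validates estimator behaviour at the sizes where its guarantees
are stated: branching-ratio recovery at criticality uses >= 1000 multi-bin
avalanches on the 68-region graph (tolerance +/- 0.05); the null-cohort
false-discovery check averages 10 cohorts of 20 subjects with 48 trials per
condition (bound 0.05); planted-effect recovery uses the full 20-subject
study geometry at effect 2x; decoding checks use the small profile with 32
trials per condition and 50 splits (chance band 0.5 +/- 0.05). Exact
oracles (frame-count ATMs, exhaustive permutation enumeration at 3-vs-3,
hand-worked BH lists, dense generalized eigendecomposition at 1e-8) are
exercised on problems small enough to enumerate.

## Known limitations

* The branching-ratio calibration is specific to the estimator's
  within-avalanche conditioning; reading the estimate as an unbiased
  offspring mean on other processes is not warranted.
* Avalanche-size/duration power-law fitting is out of scope (short epochs
  under stimulation are ill-suited to tail estimation).
* The correlation stage reports area-block averages; per-edge correlation
  maps across subjects are computed but deliberately not tested for
  significance region-by-region.
* On null data the group-reliability stage is conservative at low
  permutation counts (see the granularity caveat); this makes false
  positives rarer, not more frequent.
* `run_pipeline()` orchestrates simulation-backed runs end to end; for real
  recordings, import epochs with `import_epochs()` and run the stages
  directly — no vendor M/EEG readers are included.
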