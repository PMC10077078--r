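---
title: "Methods: lifecycle tooling for a tube-position classifier"
author: "ngtmonitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifecycle tooling for a tube-position classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A nasogastric tube (NGT) delivers enteral feeding; a tube that has strayed
into the esophagus or, worse, a main bronchus must not be fed through.
Chest radiography is the reference standard for checking tube position, and
a 3-class image classifier (satisfactory / malpositioned / bronchial) can
support the feed / do-not-feed decision of non-specialist clinicians. A
deployed classifier, however, has a lifecycle: a cohort must be curated
from DICOM metadata and free-text reports; ground truth comes from
majority-voted expert labels; the model must be trained, tuned, explained
and calibrated; and once deployed it must be monitored for concept drift —
changes in the acquisition environment (new radiography systems, new wards,
different patient demographics) that silently degrade performance.

`ngtmonitor` implements that lifecycle end-to-end at desk scale. Because
clinical radiographs cannot ship with a package, every component is
exercised against a synthetic cohort generator that plants the structure
the methods are supposed to recover: class geometry in the images,
metadata-dependent intensity effects, weak label–metadata association, and
injectable drift.

## The synthetic cohort

`synth_config()` fixes the study conditions. Defaults:

* **Class priors** 0.579 / 0.353 / 0.068 — the class balance of a
  7081-image labeled NGT cohort (4100 satisfactory, 2500 malpositioned,
  481 bronchial).
* **Age** normal with mean 67 y, sd 16 y, truncated at 0 — matching the
  reported elderly NGT population (means 66–67 y, sd 15–19 y); the
  pediatric tail below 16 y is deliberate so the quality-control filter has
  genuine work.
* **Label–manufacturer association** `label_tag_r2 = 0.07` — the weak
  confounding regime reported for real cohorts (R² = 0.07 between metadata
  tags and labels). The generator plants it by sampling the manufacturer
  conditionally on the class with a mixing weight calibrated analytically
  (`uniroot` on the closed-form population R² of one-hot labels regressed
  on one-hot manufacturers).
* **Intensity offsets** between radiography systems (0 / 1500 / 3000 gray
  levels on a 16-bit scale) and a per-department vertical gradient are
  modeling choices: real inter-system pixel differences are not publicly
  characterized, so the defaults are simply large enough to be visible
  above the default pixel noise (sd 800) without dominating the class
  signal.

Image geometry is fixed by documented constants (lung ellipses, a common
tube path to a carina point, class-specific tip regions: a lower-third
"stomach" box, a mid "esophagus" band, a lateral "bronchial" branch); only
intensities and noise are configurable. This keeps the class signal
learnable by a small network in minutes while leaving tip coordinates
available as ground truth for saliency checks.

All randomness flows from one seed through a documented splitting scheme
(`derive_seed(seed, label)`, a polynomial hash mod 2^31−1), with one
sub-seed per stage and per rendered image, so any single artifact can be
regenerated in isolation.

What the generator does **not** emulate: anatomy beyond two lung fields,
pathology, exposure variation, real DICOM pixel pipelines, report language
beyond keyword templates. Passing tests therefore demonstrate the
correctness of the statistical machinery and the trainability contract,
not clinical performance.

## Cohort curation

`qc_filter()` retains records with width ≥ 1024 **and** height ≥ 1024,
body part matching "chest" case-insensitively, view AP or PA, and age
≥ 16 years at the study date; each exclusion is logged with its first
failing rule. The age rule compares true calendar birthdays (a Feb-29
birth rolls to Mar-1) rather than a fixed day count, so "exactly 16 on the
study date" is always retained; the *encoding* of age used for modeling is
still the exact day difference (`encode_age()`).

`keyword_filter()` keeps reports matching any of
nasogastric / tube / placement / insertion / bronchus, case-insensitive,
by whole-substring regular expressions (no stemming). `consensus_label()`
implements 2-of-3 majority voting; a three-way tie yields `no_consensus`
and the record is excluded from downstream metrics — an arbitrary
tie-break would bias agreement statistics.

`grouped_stratified_split()` must satisfy two constraints that make exact
stratification NP-hard: all records of one patient share one split, and
per-stratum (label × sex × view) frequencies approximate the global ones
in every split. We use deterministic greedy assignment: patients (with
their modal stratum) are shuffled by seed and assigned to the split with
the largest remaining deficit for their stratum. The contract is
tolerance-based (±2 percentage points at n ≥ 1000 by default); an
unachievable tolerance warns and flags the result rather than failing.

## The classifier

The training engine is written in R on BLAS matrix operations: 3×3 valid
convolutions via patch-gathering (im2col) so each layer's forward and
backward pass is one matrix product, a precomputed sparse scatter for the
backward image gradient, 2×2 max pooling, global average pooling (GAP),
one dense ReLU layer with inverted dropout, softmax with categorical
cross-entropy, and Adam. Gradients are verified against central
differences to ~1e-10 relative error in the unit tests' engine checks.

Architecture and recipe follow the production design at reduced scale:
`conv_widths = c(8, 16, 32)` blocks, dense width in [32, 512], dropout in
[0, 0.2], Adam at 1e-3, batches of 32, early stopping after 10 epochs
without validation improvement, best-validation weights returned. Inputs
are resized by bilinear interpolation ignoring aspect ratio. Default input
sides are **48 and 64 px** for the two ensemble constituents — chosen so a
full two-constituent training run on ~1500 images takes minutes on one
CPU; production-scale sides (764/1024) remain configurable. Augmentation
magnitudes are unstated upstream, so they are explicit configuration:
brightness ±10%, rotation ±5°, horizontal flip p = 0.5.

Ensembling averages constituent probability rows; by convexity of the
Brier score the ensemble is never worse than the constituents' mean, which
is also the mechanism behind its better calibration.

`tune_hyperband()` implements Hyperband: s_max = ⌊log_η R⌋ brackets;
bracket *s* starts ⌈(s_max+1)/(s+1)·η^s⌉ sampled configurations at R·η^−s
epochs and successively keeps the best 1/η. Each rung retrains from
scratch at the larger budget — at desk scale retraining is cheaper than
checkpoint plumbing, and it keeps every trial's validation loss comparable.

`grad_cam()` weights the final-conv feature maps by the spatial mean of
the target-logit gradient, rectifies the weighted sum and upsamples
bilinearly to the input. Because the synthetic generator records the true
tip coordinate, saliency can be scored objectively
(`tip_localization_rate()`): mean saliency inside a 15-px disc around the
tip versus outside.

## 2-D reduction

Two backends behind one interface. The `triplet` backend mirrors the
production reducer in spirit: anchors paired with one of their k = 15
exact nearest neighbours (positive) and a random non-neighbour (negative),
a small MLP trained with the margin triplet loss, giving a parametric map
with out-of-sample `transform_coords()`. The `linear` backend projects
onto the top-2 principal directions (SVD, sign-fixed) — it exists so the
attribution and drift modules can be tested against closed-form oracles
with no neural-network nondeterminism. Neighbour search is exact brute
force; desk-scale cohorts do not justify approximate search.

## Metadata attribution

`tag_r2()` regresses both embedding coordinates on a tag's numeric
encoding (numeric tags: one standardized column; categorical: reference
indicators, missing values as their own level) and reports pooled
R² = 1 − RSS/TSS. For a categorical tag this is exactly the pooled
group-means η², which the tests verify to 1e-10. Rank-deficient joint
encodings in `cumulative_r2()` are handled by the SVD pseudoinverse, so a
superset of tags never explains less than a subset. A constant tag yields
R² = 0 with a warning, never NaN. No significance testing is attached to
these R² values. Pooled R² is invariant under a common affine map of the
coordinates; per-axis rescaling changes the pooling weights, which is why
attribution is computed on the reducer's output coordinates as produced.

## Concept-drift monitoring

The detector is a classifier two-sample test: if a flexible classifier can
distinguish the reference embedding cloud from a candidate batch, the two
distributions differ. `score_batch()` trains a random forest (ranger,
500 trees) to discriminate reference from candidate on a random half of
each side, scores the *held-out* halves with the fitted forest, and
compares the two held-out score distributions with the two-sample
Kolmogorov–Smirnov test. The KS P value is computed by an exact
permutation dynamic programme (valid under ties) whenever
n_ref·n_cand ≤ 10 000, and by the asymptotic Kolmogorov distribution
otherwise.

Two design points deserve emphasis:

* **Held-out scoring, not in-sample OOB.** An appealing shortcut is to
  train one forest on all points and compare the two groups'
  *out-of-bag* probabilities. We measured that construction to be strongly
  anti-conservative: null rejection rates of 0.17–0.28 at α = 0.05
  across every regularization we tried (bootstrap vs stratified
  subsampling, leaf sizes 5–100, random splits, restricted mtry,
  tree-disjoint scoring), because in-sample scores carry self-exclusion
  artifacts and are mutually dependent, while the KS null assumes
  independent draws. With held-out scoring the scored points never entered
  training, so under no drift their scores are iid draws of the fitted
  function and the permutation-exact KS P value is valid; we measure a
  null rejection rate of 0.04 at α = 0.05 and P < 0.001 for 1-SD shifts
  at 200 points per side.
* **Duplicate cancellation.** Exact duplicate reference/candidate row
  pairs are cancelled before testing. A re-submitted batch of identical
  images carries no evidence of distributional change, but a flexible
  classifier memorizes training twins of scored points and would flag it;
  a candidate that is an exact copy of reference rows returns D = 0,
  p = 1 by construction.

`drift_monitor()` draws repeated batches from a candidate pool (without
replacement within a batch, with replacement across batches), scores each,
and flags drift when the median P value falls below α = 0.01. Defaults
(50 batches of 100) give stable box plots at desk scale. Drift statistics
are computed on the 2-D reduced coordinates by default — matching the
monitoring design that works on low-dimensional latent summaries — but any
coordinate matrix (including raw GAP space) is accepted.

## Evaluation statistics

* **Clopper–Pearson**: lower = B(α/2; x, n−x+1), upper =
  B(1−α/2; x+1, n−x); x = 0 pins the lower bound at 0 and x = n the upper
  at 1. Applied to accuracy, sensitivity and specificity; also applied to
  PPV with the method recorded in the output, since no alternative method
  is specified upstream and consistency beats guessing.
* **ROC/AUC**: rank (Mann–Whitney) definition with ties counted half,
  verified against a brute-force pairwise oracle; 95% CI from 2000 seeded
  case-resampling bootstrap replicates (percentile), single-class
  resamples redrawn.
* **Cohen κ** from the cross-table, κ = (p_o − p_e)/(1 − p_e); two
  constant, equal raters (p_e = 1) define κ = 1. `kappa_matrix()` reports
  the pairwise reader matrix with mean ± SD over the upper triangle (SD
  defined as 0 for a single pair).
* **Paired t** on per-reader κ differences, df = n − 1, two-tailed;
  zero-variance differences are flagged degenerate instead of returning
  NaN. A Welch two-sample variant sits behind `paired = FALSE`.
* **Calibration**: equal-width bins, frequency-weighted ECE, empty bins
  reported.
* **Feed score**: the satisfactory-class probability is the only monotone
  one-number mapping from the 3-class output to a feed / do-not-feed
  decision; the threshold (default 0.5) is configuration, not constant.
* **Rounding**: reported percentages round half away from zero
  (`round_half_up()`), raw proportions and their (x, n) counts are always
  retained alongside.

## Problem sizes and numerical choices

Test-suite problem sizes are chosen for single-CPU runs: the end-to-end
check trains both constituents on 1400 + 100 images and evaluates 300
held-out images (per-class one-vs-rest AUC ≥ 0.90 in at least 2 of 3
seeds); drift properties use 20 seeds per shift level at 200 points per
side; attribution uses n = 2000. The KS exact/asymptotic crossover at
n_a·n_b = 10 000 keeps the exact path for every batch size the monitor
uses by default. Ties in the exact DP are grouped by exact double
equality, matching how the D statistic itself is computed. Early stopping
compares losses strictly (an exactly flat epoch counts against patience);
max-pool gradient ties route to the first maximal entry; softmax is
computed with the row-max subtracted.

## Known limitations

* The synthetic task is far easier than radiograph interpretation; AUCs
  near 1.0 on it say nothing about clinical AUC.
* The CNN engine is CPU-bound and single-threaded beyond BLAS; it is not
  intended for production-resolution (764/1024 px) training, although the
  configuration admits it.
* PNG image export is 8-bit (the PNG writer's finest); 16-bit fidelity is
  available via TIFF. DICOM is not written.
* The drift monitor's batches are resampled from one pool, so monitor-level
  P values across batches are not independent; the drift flag uses their
  median, not a combined test.
* The triplet reducer is seeded-deterministic but, unlike the linear
  backend, makes no closed-form guarantee about out-of-sample consistency;
  its quality is asserted only through cluster-preservation checks.
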