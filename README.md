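# ngtmonitor

Lifecycle tooling for chest-radiograph nasogastric-tube (NGT) position
classifiers, in R. A misplaced NGT — in the esophagus or, dangerously, a
main bronchus — must be caught before feeding; a 3-class image classifier
(satisfactory / malpositioned / bronchial) can support that feed /
do-not-feed decision. But a deployed classifier is more than a model: the
cohort has to be curated from DICOM-style metadata and report text, ground
truth assembled by majority vote, the model trained, tuned, explained and
calibrated, and — once live — monitored for **concept drift**, the silent
performance decay caused by new radiography systems, departments, or
patient demographics.

`ngtmonitor` implements that whole lifecycle at desk scale, testable
end-to-end against a built-in synthetic radiograph generator:

* **Synthetic cohorts** (`synth_config`, `generate_manifest`,
  `render_image`, `synth_embeddings`, `apply_drift`): radiograph-like
  images with planted class geometry (tube tip in a class-specific
  region), metadata-dependent intensity effects, weak label–metadata
  association, and injectable drift scenarios.
* **Curation** (`qc_filter`, `keyword_filter`, `consensus_label`,
  `grouped_stratified_split`): resolution / body-part / view / age
  filters with an exclusion log, keyword retention on report text, 2-of-3
  majority voting, and patient-disjoint stratified 90/5/5 splitting.
* **Modeling** (`classifier_config`, `train_classifier`,
  `ensemble_proba`, `tune_hyperband`, `grad_cam`): a small configurable
  CNN with a global-average-pooling (GAP) head written on BLAS matrix
  operations (im2col convolutions, Adam, early stopping, train-time
  augmentation), a two-resolution probability-averaging ensemble,
  Hyperband tuning, and Grad-CAM saliency

  `L(θ) = −Σ_k y_k log p_k`, `CAM = ReLU(Σ_c α_c A_c)`, `α_c = mean ∂y/∂A_c`.
* **Reduction** (`fit_reducer`, `transform_coords`): parametric 2-D
  embedding with out-of-sample transform — a triplet-network backend and a
  deterministic linear (top-2 principal directions) backend.
* **Attribution** (`tag_r2`, `cumulative_r2`, `rank_tags`): fraction of
  embedding variance explained by each metadata tag,
  `R² = 1 − RSS/TSS` pooled over both coordinates (equal to pooled η²
  for categorical tags), singly and cumulatively.
* **Drift monitoring** (`score_batch`, `drift_monitor`, `ks_2sample`): a
  classifier two-sample test — a random forest trained to tell reference
  from candidate embeddings on half the data, held-out drift scores
  compared by the two-sample Kolmogorov–Smirnov statistic
  `D = sup_x |F̂_ref(x) − F̂_cand(x)|` with a permutation-exact small-sample
  P value, repeated over batches into an interpretable per-batch P-value
  distribution and a drift flag.
* **Evaluation** (`confusion_matrix`, `class_metrics`, `roc_auc`,
  `cohen_kappa`, `kappa_matrix`, `paired_kappa_test`,
  `calibration_curve`, `feed_score`): per-class metrics with exact
  Clopper–Pearson intervals `[B(α/2; x, n−x+1), B(1−α/2; x+1, n−x)]`,
  rank-based AUC with 2000-replicate bootstrap CIs, reader agreement
  `κ = (p_o − p_e)/(1 − p_e)`, paired reader tests, calibration curves
  and the feed-probability mapping.
* **Orchestration** (`run_config`, `run_pipeline`, `ensemble_experiment`,
  `inst/cli/ngtmonitor.R`): one-seed reproducible pipeline producing the
  full report bundle (CSV/JSON stamped with the configuration hash, plus
  figures), and a thin command-line interface.

## Worked example

```r
library(ngtmonitor)

# a small synthetic cohort, curated and split
cfg <- synth_config(n_images = 400, seed = 7)
man <- generate_manifest(cfg)
qc  <- qc_filter(man)
cohort <- keyword_filter(qc$cohort)
nrow(man); nrow(cohort)

# train the two-resolution ensemble and evaluate
exp <- ensemble_experiment(n_train = 700, n_val = 60, n_test = 150,
                           input_sides = c(32, 48), max_epochs = 6, seed = 7)
cm <- confusion_matrix(exp$test_labels, exp$probs)
print(cm)
print(class_metrics(cm, "bronchial")$sensitivity)

# drift: embed, reduce, monitor a shifted candidate pool
emb <- ensemble_embeddings(exp$models, exp$test_images)
red <- fit_reducer(emb, reducer_config(backend = "linear"))
co  <- transform_coords(red, emb)
es  <- structure(list(X = emb, labels = factor(exp$test_labels),
                      tags = data.frame(row.names = seq_len(nrow(emb)))),
                 class = "embedding_set")
shifted <- transform_coords(red, apply_drift(es, drift_spec("mean_shift", magnitude = 5))$X)
mon <- drift_monitor(co, shifted, drift_config(n_batches = 10, batch_size = 75,
                                               min_batch = 30, seed = 7))
mon$summary; mon$drift
```

Output (seed 7):

```
[1] 400
[1] 383
               predicted
truth           satisfactory malpositioned bronchial
  satisfactory            91             1         0
  malpositioned            0            44         0
  bronchial                0             6         8
57% (8 of 14; 95% CI: 29%, 82%)
     q1  median      q3
9.0e-15 9.0e-15 9.2e-15
[1] TRUE
```

Reading the output: 383 of 400 synthetic records survive curation (the
generator plants a pediatric tail, sub-resolution images and keyword-free
reports on purpose). The confusion matrix shows this deliberately small
6-epoch demo already separating satisfactory from malpositioned while
still under-fitting the rare bronchial class — whose sensitivity line,
57% (8 of 14; 95% CI: 29%, 82%), demonstrates that every reported
percentage carries its raw (x, n) counts and exact Clopper–Pearson
interval. At full desk scale (1500 training images, 10 epochs, 48/64-px
constituents — the run `scripts/acceptance.R` performs) per-class AUCs
exceed 0.99. The monitor's KS P values collapse under a planted 5-SD
embedding shift, so the drift flag raises; on an unshifted pool the
median P stays far above α.

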