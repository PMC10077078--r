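#' Pipeline run configuration
#'
#' One source of truth for an end-to-end run: the synthetic-cohort
#' configuration, the two ensemble resolutions, reducer and drift-monitor
#' settings, bootstrap size, and the global seed from which every stage's
#' sub-seed is derived. The serialized configuration (and its hash) is
#' embedded in every output bundle.
#'
#' @param out_dir output directory.
#' @param synth a [synth_config()] (its seed is overridden by `seed`).
#' @param fractions train/validation/test split fractions (sum to 1).
#' @param input_sides two input resolutions for the ensemble constituents.
#' @param dense_units,dropout_rate,max_epochs,patience classifier settings
#'   shared by both constituents.
#' @param reducer a [reducer_config()].
#' @param drift a [drift_config()].
#' @param drift_scenario `NULL` for no planted drift, or a [drift_spec()]
#'   applied to the candidate embeddings.
#' @param n_boot bootstrap replicates for AUC intervals.
#' @param seed global integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("ngtrun"),
                       synth = synth_config(n_images = 1500),
                       fractions = c(train = 0.90, validation = 0.05,
                                     test = 0.05),
                       input_sides = c(48, 64),
                       dense_units = 64, dropout_rate = 0.1,
                       max_epochs = 12, patience = 5,
                       reducer = reducer_config(backend = "linear"),
                       drift = drift_config(n_batches = 20),
                       drift_scenario = drift_spec("mean_shift", magnitude = 5),
                       n_boot = 500,
                       seed = 1) {
  synth$seed <- derive_seed(seed, "synth")
  reducer$seed <- derive_seed(seed, "reduce")
  drift$seed <- derive_seed(seed, "drift")
  structure(list(out_dir = out_dir, synth = synth, fractions = fractions,
                 input_sides = input_sides, dense_units = dense_units,
                 dropout_rate = dropout_rate, max_epochs = max_epochs,
                 patience = patience, reducer = reducer, drift = drift,
                 drift_scenario = drift_scenario, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# ngtmonitor config=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

log_stage <- function(verbose, seed, ...) {
  if (verbose) {
    message(format(Sys.time(), "%H:%M:%S"), " [seed ", seed, "] ", ...)
  }
}

#' Train and evaluate the two-resolution ensemble on a synthetic cohort
#'
#' Generates a fresh synthetic cohort (labels taken from the generator),
#' renders the images, trains one constituent per entry of `input_sides`,
#' and evaluates on a held-out test set. This is the controlled-experiment
#' path used for benchmarking the ensemble itself; [run_pipeline()] is the
#' full curation-to-report path.
#'
#' @param n_train,n_val,n_test cohort sizes.
#' @param input_sides constituent input resolutions.
#' @param max_epochs,patience training schedule shared by constituents.
#' @param image_size rendered image side.
#' @param seed integer seed (cohort, init, shuffling, augmentation).
#' @return list with `models`, `probs` (ensemble test probabilities),
#'   `constituent_probs`, `test_images`, `test_labels`.
#' @export
ensemble_experiment <- function(n_train = 1500, n_val = 100, n_test = 300,
                                input_sides = c(48, 64), max_epochs = 10,
                                patience = 10, image_size = 64, seed = 1) {
  n <- n_train + n_val + n_test
  scfg <- synth_config(n_images = n, image_size = image_size,
                       seed = derive_seed(seed, "exp_synth"))
  man <- generate_manifest(scfg)
  imgs <- render_cohort(man, scfg)
  ix_tr <- seq_len(n_train)
  ix_va <- n_train + seq_len(n_val)
  ix_te <- n_train + n_val + seq_len(n_test)
  models <- lapply(seq_along(input_sides), function(i) {
    cfg <- classifier_config(input_side = input_sides[i],
                             max_epochs = max_epochs, patience = patience,
                             seed = derive_seed(seed, paste0("exp_m", i)))
    train_classifier(imgs[ix_tr], man$label[ix_tr], imgs[ix_va],
                     man$label[ix_va], cfg)
  })
  cons <- lapply(models, predict_proba, images = imgs[ix_te])
  probs <- Reduce(`+`, cons) / length(cons)
  list(models = models, probs = probs, constituent_probs = cons,
       test_images = imgs[ix_te], test_labels = man$label[ix_te])
}

#' Run the full pipeline
#'
#' simulate -> curate (QC, keyword retention, rater consensus) -> split ->
#' train the two-resolution ensemble -> predict and embed the test set ->
#' reduce to 2-D -> attribute metadata tags -> monitor drift (null
#' candidate and, when configured, a planted drift scenario) -> evaluate
#' (confusion matrix, per-class metrics with exact intervals, bootstrap
#' AUC, calibration, rater agreement). All reports are written under
#' `config$out_dir`, each stamped with the configuration hash and seed;
#' reruns with one seed are byte-identical (figures exempt).
#'
#' @param config a [run_config()].
#' @param verbose log stage progress.
#' @return invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  seed <- config$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- "configure"
  res <- list(config = config, hash = hash)
  tryCatch({
    stage <- "simulate"
    log_stage(verbose, seed, "simulating cohort (n = ",
              config$synth$n_images, ")")
    manifest <- generate_manifest(config$synth)
    write_csv_prov(manifest, out("manifest.csv"), hash, seed)

    stage <- "curate"
    qc <- qc_filter(manifest)
    write_exclusion_log(qc$log, out("exclusions.jsonl"))
    cohort <- keyword_filter(qc$cohort)
    cons <- consensus_labels(cohort)
    keep <- cons != "no_consensus"
    cohort <- cohort[keep, , drop = FALSE]
    cohort$label <- cons[keep]
    log_stage(verbose, seed, nrow(cohort), " records after curation")
    if (nrow(cohort) < 60) stop2("curated cohort too small to split/train")

    stage <- "split"
    sa <- grouped_stratified_split(cohort, fractions = config$fractions,
                                   seed = derive_seed(seed, "split"))
    write_csv_prov(sa$assignment, out("split.csv"), hash, seed)
    ix <- split(seq_len(nrow(cohort)), sa$assignment$split)

    stage <- "render"
    log_stage(verbose, seed, "rendering ", nrow(cohort), " images")
    images <- render_cohort(cohort, config$synth)

    stage <- "train"
    models <- lapply(seq_along(config$input_sides), function(i) {
      side <- config$input_sides[i]
      log_stage(verbose, seed, "training constituent at ", side, " px")
      cfg <- classifier_config(input_side = side,
                               dense_units = config$dense_units,
                               dropout_rate = config$dropout_rate,
                               max_epochs = config$max_epochs,
                               patience = config$patience,
                               seed = derive_seed(seed, paste0("model", i)))
      fit <- train_classifier(images[ix$train], cohort$label[ix$train],
                              images[ix$validation],
                              cohort$label[ix$validation], cfg)
      write_csv_prov(fit$history, out(sprintf("history_%dpx.csv", side)),
                     hash, seed)
      fit
    })

    stage <- "predict"
    test_imgs <- images[ix$test]
    test_lab <- cohort$label[ix$test]
    probs <- ensemble_proba(models, test_imgs)
    pred_df <- data.frame(record_id = cohort$record_id[ix$test],
                          p_satisfactory = probs[, "satisfactory"],
                          p_malpositioned = probs[, "malpositioned"],
                          p_bronchial = probs[, "bronchial"])
    write_csv_prov(pred_df, out("predictions.csv"), hash, seed)

    stage <- "embed"
    emb <- ensemble_embeddings(models, test_imgs)
    rownames(emb) <- cohort$record_id[ix$test]

    stage <- "reduce"
    red <- fit_reducer(emb, config$reducer)
    coords <- transform_coords(red, emb)
    write_csv_prov(data.frame(record_id = rownames(coords), coords),
                   out("coords.csv"), hash, seed)

    stage <- "attribute"
    attr_res <- attribute_cohort(coords, cohort[ix$test, , drop = FALSE])
    write_csv_prov(attr_res$ranking, out("attribution.csv"), hash, seed)
    grDevices::png(out("fig_attribution.png"), 640, 480)
    plot_attribution(attr_res$ranking)
    grDevices::dev.off()

    stage <- "drift"
    log_stage(verbose, seed, "drift monitoring")
    drift_cfg <- config$drift
    drift_cfg$min_batch <- min(drift_cfg$min_batch, nrow(coords))
    drift_cfg$batch_size <- max(drift_cfg$min_batch,
                                min(drift_cfg$batch_size, nrow(coords)))
    null_mon <- drift_monitor(coords, coords, drift_cfg)
    monitors <- list(null = null_mon)
    if (!is.null(config$drift_scenario)) {
      es <- structure(list(X = emb, labels = factor(test_lab),
                           tags = data.frame(row.names = seq_len(nrow(emb)))),
                      class = "embedding_set")
      shifted <- apply_drift(es, config$drift_scenario)
      shifted_coords <- transform_coords(red, shifted$X)
      monitors$scenario <- drift_monitor(coords, shifted_coords, drift_cfg)
    }
    for (nm in names(monitors)) {
      write_drift_report(monitors[[nm]], out(paste0("drift_", nm, ".json")))
    }
    grDevices::png(out("fig_drift.png"), 640, 480)
    plot_drift(monitors)
    grDevices::dev.off()

    stage <- "evaluate"
    cm <- confusion_matrix(test_lab, probs)
    perf <- performance_table(cm)
    write_csv_prov(perf, out("performance.csv"), hash, seed)
    rocs <- lapply(ngt_classes(), function(cl) {
      roc_auc(probs[, cl], as.integer(test_lab == cl),
              n_boot = config$n_boot, seed = derive_seed(seed, cl))
    })
    names(rocs) <- ngt_classes()
    auc_df <- data.frame(class = names(rocs),
                         auc = vapply(rocs, `[[`, 0, "auc"),
                         ci_low = vapply(rocs, `[[`, 0, "ci_low"),
                         ci_high = vapply(rocs, `[[`, 0, "ci_high"))
    write_csv_prov(auc_df, out("auc.csv"), hash, seed)
    grDevices::png(out("fig_roc.png"), 960, 360)
    graphics::par(mfrow = c(1, 3))
    for (cl in names(rocs)) plot_roc(rocs[[cl]], main = cl)
    grDevices::dev.off()

    # calibration: ensemble vs constituents on the feed probability
    y_feed <- as.integer(test_lab == "satisfactory")
    cal_ens <- calibration_curve(probs[, "satisfactory"], y_feed)
    cal_con <- lapply(models, function(m) {
      calibration_curve(predict_proba(m, test_imgs)[, "satisfactory"],
                        y_feed)
    })
    ece_df <- data.frame(
      model = c("ensemble", sprintf("constituent_%dpx", config$input_sides)),
      ece = c(cal_ens$ece, vapply(cal_con, `[[`, 0, "ece")))
    write_csv_prov(ece_df, out("calibration.csv"), hash, seed)

    # rater agreement on feed decisions (test set)
    test_cohort <- cohort[ix$test, , drop = FALSE]
    to_feed <- function(x) ifelse(x == "satisfactory", "feed", "do_not_feed")
    km <- kappa_matrix(data.frame(rater1 = to_feed(test_cohort$rater1),
                                  rater2 = to_feed(test_cohort$rater2),
                                  rater3 = to_feed(test_cohort$rater3)))
    grDevices::png(out("fig_kappa.png"), 480, 480)
    plot_kappa_matrix(km)
    grDevices::dev.off()

    # model-vs-consensus feed ROC
    cons_feed <- to_feed(test_lab)
    fs <- feed_score(probs)
    roc_feed <- roc_auc(fs$score, as.integer(cons_feed == "feed"),
                        n_boot = config$n_boot,
                        seed = derive_seed(seed, "feed"))

    prov <- list(config_hash = hash, seed = seed,
                 config = unclass(config),
                 files = list.files(config$out_dir))
    writeLines(as.character(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                             digits = NA, force = TRUE)),
               out("provenance.json"))
    res <- c(res, list(manifest = manifest, cohort = cohort, split = sa,
                       models = models, probs = probs, truth = test_lab,
                       reducer = red, coords = coords,
                       attribution = attr_res, drift = monitors,
                       confusion = cm, performance = perf, rocs = rocs,
                       calibration = ece_df, kappa = km,
                       roc_feed = roc_feed))
    invisible(res)
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
}
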