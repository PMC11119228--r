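# --- published reference tables (inputs to reconstruction utilities) ----

#' Published patient counts of the four train/test versions
#'
#' The patient-level composition of the four evaluation versions
#' (training set shared by versions 2-4; test sets nested: version 2's
#' test = version 3's surgical test + version 4's endoscopic test).
#'
#' @return data.frame with `version`, `train_pos`, `train_neg`,
#'   `test_pos`, `test_neg` (patients).
#' @export
published_table2 <- function() {
  data.frame(
    version = 1:4,
    train_pos = c(80, 137, 137, 137),
    train_neg = c(624, 887, 887, 887),
    test_pos = c(21, 35, 21, 14),
    test_neg = c(156, 222, 156, 66)
  )
}

#' Published Youden operating points of the four versions
#'
#' Test-set sensitivity/specificity (percent) at the Youden-selected
#' cutoff for each version of the image model.
#'
#' @return data.frame with `version`, `sensitivity`, `specificity`.
#' @export
published_operating_points <- function() {
  data.frame(
    version = 1:4,
    sensitivity = c(71.4, 71.4, 76.2, 92.9),
    specificity = c(92.9, 84.2, 85.9, 57.6)
  )
}

#' Published cohort composition
#'
#' Study-population constants used by the cohort generator and the
#' reconstruction utilities: stratum sizes, stratum prevalences, the
#' per-stratum positive patient counts used by the split tables, and the
#' lymph-node yield.
#'
#' @return named list.
#' @export
published_cohort <- function() {
  list(
    n_endoscopic = 400, n_surgical = 881,
    prev_endo = 0.178, prev_surg = 0.066,
    endo_pos = 71, surg_pos = 101,          # split-table patient counts
    endo_neg = 329, surg_neg = 780,
    ln_positive = 273, ln_total = 22022
  )
}

# --- run configuration --------------------------------------------------

#' Assemble a run configuration
#'
#' A flat, serialisable list tying together generator, tiling, model and
#' evaluation settings; written as JSON next to every artifact so a run
#' can be regenerated from its output directory alone.
#'
#' @param seed master seed (all stage seeds are derived from it).
#' @param n_endoscopic,n_surgical cohort sizes.
#' @param prev_endo,prev_surg stratum prevalences.
#' @param slide_px,patch_size raster and patch sides in pixels.
#' @param evidence_frac planted evidence fraction of tissue area.
#' @param min_tissue_frac tiling retention threshold.
#' @param input_px encoder input resolution.
#' @param fe_epochs,mil_epochs,mil_lr training settings.
#' @param version evaluation version in 1..4.
#' @param out output directory (optional).
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_endoscopic = 100, n_surgical = 150,
                       prev_endo = 0.178, prev_surg = 0.066,
                       slide_px = 512, patch_size = 64,
                       evidence_frac = 0.05, min_tissue_frac = 0.5,
                       input_px = 32, fe_epochs = 8, mil_epochs = 40,
                       mil_lr = 5e-4, version = 2, out = NULL) {
  structure(
    list(seed = seed, n_endoscopic = n_endoscopic, n_surgical = n_surgical,
         prev_endo = prev_endo, prev_surg = prev_surg, slide_px = slide_px,
         patch_size = patch_size, evidence_frac = evidence_frac,
         min_tissue_frac = min_tissue_frac, input_px = input_px,
         fe_epochs = fe_epochs, mil_epochs = mil_epochs, mil_lr = mil_lr,
         version = version, out = out),
    class = "run_config"
  )
}

config_slide_params <- function(config) {
  slide_params(size = config$slide_px, patch_size = config$patch_size,
               evidence_frac = config$evidence_frac)
}

#' Simulate a cohort and write its slides to disk
#'
#' Stage driver: generates the cohort from the configuration, renders all
#' slides and evidence masks, writes cohort/manifest CSVs and the
#' configuration JSON.
#'
#' @param config a `run_config` with a non-NULL `out`.
#' @param force overwrite a non-empty output directory.
#' @return the manifest data.frame, invisibly.
#' @export
run_simulation <- function(config, force = FALSE) {
  assert_that(!is.null(config$out), "config$out must name an output directory")
  cohort <- generate_cohort(config$n_endoscopic, config$n_surgical,
                            config$prev_endo, config$prev_surg,
                            seed = derive_seed(config$seed, 1))
  manifest <- simulate_dataset(cohort, config$out,
                               params = config_slide_params(config),
                               seed = derive_seed(config$seed, 2),
                               force = force)
  jsonlite::write_json(unclass(config), file.path(config$out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Render, mask and tile every slide of a cohort into bags
#'
#' In-memory pipeline stage: for each slide of each patient, renders the
#' synthetic slide, detects tissue (Otsu on saturation, small objects below
#' one patch area removed), tiles it into patches, mean-pools the patches
#' to the encoder input resolution and drops the full-resolution pixels.
#'
#' @param cohort a `patient_cohort`.
#' @param config a `run_config`.
#' @return list of `wsi_bag`s (one per slide, empty bags dropped with a
#'   warning).
#' @export
build_bags <- function(cohort, config = run_config()) {
  params <- config_slide_params(config)
  bags <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    for (s in seq_len(rec$n_slides)) {
      sl <- render_slide(rec, params,
                         seed = derive_seed(config$seed, 1000 + i * 10 + s),
                         slide_index = s)
      mask <- detect_tissue(sl, min_area = config$patch_size^2)
      bag <- tile(sl, mask, patch_size = config$patch_size,
                  min_tissue_frac = config$min_tissue_frac)
      if (bag$n == 0) {
        warning(sprintf("slide %s produced an empty bag; skipped", sl$slide_id))
        next
      }
      bags[[length(bags) + 1]] <- prepare_bag(bag, input_px = config$input_px)
    }
  }
  bags
}

# --- full version experiment --------------------------------------------

#' Run one full evaluation version
#'
#' Executes the experiment for one train/test version on a simulated
#' cohort: tissue tiling, feature-extractor pretraining on the training
#' patients, stratified 5-fold cross-validation, ensemble prediction on
#' the held-out test set, Youden cutoff selection on the test predictions,
#' the clinical-utility panel against the all-positive guideline, the
#' McNemar comparison, and the random-forest clinicopathologic baseline.
#'
#' @param config a `run_config`.
#' @param cohort optional pre-generated `patient_cohort` (generated from
#'   the config when omitted).
#' @param bags optional pre-built bag list (built when omitted).
#' @return list of class `version_report`: split plan, per-fold AUCs, test
#'   AUC, cutoff, utility panel, RF baseline AUCs, and the config.
#' @export
run_version <- function(config = run_config(), cohort = NULL, bags = NULL) {
  cohort <- cohort %||% generate_cohort(
    config$n_endoscopic, config$n_surgical, config$prev_endo,
    config$prev_surg, seed = derive_seed(config$seed, 1)
  )
  bags <- bags %||% build_bags(cohort, config)
  pid <- vapply(bags, function(b) b$patient_id, "")
  # patients whose slides yielded no analysable patches are excluded,
  # mirroring the usual unclear-slide exclusion criterion
  dropped <- setdiff(cohort$patient_id, pid)
  if (length(dropped) > 0) {
    message(sprintf("excluding %d patient(s) with no analysable slides", length(dropped)))
    cohort <- cohort[cohort$patient_id %in% pid, ]
  }
  plan <- make_version_split(cohort, config$version,
                             seed = derive_seed(config$seed, 3))
  check_no_leakage(plan)
  train_bags <- bags[pid %in% plan$train_patient_ids]
  test_bags <- bags[pid %in% plan$test_patient_ids]
  fe <- pretrain_fe(train_bags, config = fe_config(input_px = config$input_px),
                    epochs = config$fe_epochs,
                    seed = derive_seed(config$seed, 4))
  cv <- run_cv(plan, train_bags, fe,
               trainer = list(epochs = config$mil_epochs, lr = config$mil_lr),
               seed = derive_seed(config$seed, 5))
  test_pred <- ensemble_predict(cv$models, test_bags, plan)
  test_auc <- roc_auc(test_pred$probability, test_pred$label)
  cut <- youden_cutoff(test_pred$probability, test_pred$label)
  panel <- utility_panel(test_pred$probability, test_pred$label, cut$threshold)
  rf <- rf_baseline(cohort_features(cohort), cohort$lnm_label, plan,
                    cohort$patient_id, seed = derive_seed(config$seed, 6))
  report <- structure(
    list(version = config$version, plan = plan,
         fold_auc = cv$fold_auc, mean_fold_auc = cv$mean_fold_auc,
         test_auc = test_auc, cutoff = cut, panel = panel,
         rf_fold_auc = rf$fold_auc, rf_test_auc = rf$test_auc,
         test_predictions = test_pred, models = cv$models, fe = fe,
         config = config),
    class = "version_report"
  )
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_version_report(report, file.path(config$out,
                                           sprintf("report_v%d.json", config$version)))
  }
  report
}

#' @export
print.version_report <- function(x, ...) {
  cat(sprintf("Version %d  (seed %s)\n", x$version, format(x$config$seed)))
  cat(sprintf("  fold AUCs: %s  (mean %.3f)\n",
              paste(sprintf("%.3f", x$fold_auc), collapse = " "),
              x$mean_fold_auc))
  cat(sprintf("  test AUC:  %.3f   RF test AUC: %.3f\n", x$test_auc, x$rf_test_auc))
  cat(sprintf("  Youden cutoff %.3f -> sens %.1f%%, spec %.1f%%\n",
              x$cutoff$threshold, 100 * x$cutoff$sensitivity,
              100 * x$cutoff$specificity))
  cat(sprintf("  unnecessary surgery: model %.1f%% vs guideline %.1f%% (reduction %.1f)\n",
              x$panel$model$unnecessary_surgery,
              x$panel$jsccr$unnecessary_surgery, x$panel$reduction))
  invisible(x)
}

#' Serialize a version report as JSON
#'
#' @param report a `version_report`.
#' @param path JSON path.
#' @export
write_version_report <- function(report, path) {
  jsonlite::write_json(
    list(
      version = report$version,
      seed = report$config$seed,
      fold_auc = report$fold_auc,
      mean_fold_auc = report$mean_fold_auc,
      test_auc = report$test_auc,
      cutoff = report$cutoff,
      model_utility = report$panel$model[c("sensitivity", "specificity", "ppv",
                                           "accuracy", "unnecessary_surgery",
                                           "missed_lnm")],
      jsccr_utility = report$panel$jsccr[c("sensitivity", "specificity", "ppv",
                                           "accuracy", "unnecessary_surgery",
                                           "missed_lnm")],
      reduction = report$panel$reduction,
      mcnemar_p = report$panel$mcnemar$p_value,
      rf_fold_auc = report$rf_fold_auc,
      rf_test_auc = report$rf_test_auc,
      config = unclass(report$config)
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

# --- synthetic benchmark ------------------------------------------------

#' End-to-end synthetic benchmark of the MIL pipeline
#'
#' The package's standing benchmark: a mixed cohort of ~250 slides at 15%
#' LNM prevalence, an 80/20 patient-level split, feature-extractor
#' pretraining and end-to-end MIL training on the training side, and three
#' read-outs on the held-out side: bag-level test AUC, a label-permutation
#' null AUC (attention and classifier retrained on permuted training
#' labels, evaluated against the true test labels), and attention
#' localization — the fraction of positive test bags whose evidence-bearing
#' patches receive a higher mean normalized attention score than their
#' normal patches.
#'
#' @param seed master seed.
#' @param n_endoscopic,n_surgical cohort sizes (defaults give ~250 slides).
#' @param prevalence LNM prevalence in both strata.
#' @param slide_px,patch_size raster/patch geometry.
#' @param fe_epochs,mil_epochs,mil_lr training settings.
#' @param run_null also compute the label-permutation null (default TRUE).
#' @param n_null number of label permutations averaged for the null AUC.
#' @return list with `test_auc`, `null_auc` (mean over permutations, with
#'   the individual `null_auc_draws`), `localization_frac`, `n_bags`,
#'   `n_train`, `n_test`, `patch_accuracy`, `evidence_patch_accuracy` and
#'   the trained model.
#' @export
synthetic_benchmark <- function(seed = 1, n_endoscopic = 113, n_surgical = 114,
                                prevalence = 0.15, slide_px = 512,
                                patch_size = 64, fe_epochs = 8,
                                mil_epochs = 40, mil_lr = 5e-4,
                                run_null = TRUE, n_null = 16) {
  config <- run_config(seed = seed, n_endoscopic = n_endoscopic,
                       n_surgical = n_surgical, prev_endo = prevalence,
                       prev_surg = prevalence, slide_px = slide_px,
                       patch_size = patch_size)
  cohort <- generate_cohort(n_endoscopic, n_surgical, prevalence, prevalence,
                            seed = derive_seed(seed, 1))
  bags <- build_bags(cohort, config)
  pid <- vapply(bags, function(b) b$patient_id, "")
  cohort <- cohort[cohort$patient_id %in% pid, ]
  plan <- make_version_split(cohort, 2, seed = derive_seed(seed, 3))
  train_bags <- bags[pid %in% plan$train_patient_ids]
  test_bags <- bags[pid %in% plan$test_patient_ids]
  fe <- pretrain_fe(train_bags, config = fe_config(input_px = config$input_px),
                    epochs = fe_epochs, seed = derive_seed(seed, 4))
  pacc <- patch_accuracy(fe, test_bags)
  ev_acc <- evidence_patch_accuracy(fe, test_bags)
  model <- train_end_to_end(train_bags, fe = fe, epochs = mil_epochs,
                            lr = mil_lr, seed = derive_seed(seed, 5))
  test_pred <- predict_bags(model, test_bags)
  test_auc <- roc_auc(test_pred$probability, test_pred$label)

  null_auc <- NA_real_
  null_auc_draws <- NULL
  if (run_null) {
    # permutation null: the standard label-permutation test. Bag labels
    # are permuted jointly across training and test bags (severing every
    # label-image association while preserving prevalence), the
    # attention/classifier head is retrained on the permuted training
    # labels, and the held-out AUC is computed against the permuted test
    # labels. The null AUC is the mean over `n_null` permutations;
    # features are encoded once and shared across them.
    y <- vapply(train_bags, function(b) as.integer(b$label), 1L)
    y_test <- vapply(test_bags, function(b) as.integer(b$label), 1L)
    train_feats <- lapply(train_bags, function(b) unclass(encode(fe, b)))
    test_feats <- lapply(test_bags, function(b) unclass(encode(fe, b)))
    n_tr <- length(y)
    null_auc_draws <- vapply(seq_len(n_null), function(r) {
      perm <- with_seed(derive_seed(seed, 600 + r), sample(c(y, y_test)))
      y_perm <- perm[seq_len(n_tr)]
      y_test_perm <- perm[n_tr + seq_along(y_test)]
      if (length(unique(y_perm)) < 2 || length(unique(y_test_perm)) < 2) {
        return(NA_real_)
      }
      null_model <- train_end_to_end(train_bags, labels = y_perm, fe = fe,
                                     epochs = mil_epochs, lr = mil_lr,
                                     seed = derive_seed(seed, 700 + r),
                                     features = train_feats)
      p <- vapply(test_feats, function(f) mil_forward(null_model, f)$probability, 1.0)
      roc_auc(p, y_test_perm)
    }, 1.0)
    null_auc <- mean(null_auc_draws, na.rm = TRUE)
  }

  # attention localization on positive held-out bags
  pos_bags <- Filter(function(b) b$label == 1L, test_bags)
  hits <- vapply(pos_bags, function(b) {
    res <- mil_forward(model, encode(model$fe, b))
    nv <- minmax_normalize(res$scores)
    ev <- b$evidence_frac > 0
    if (!any(ev) || all(ev)) return(NA)
    mean(nv[ev]) > mean(nv[!ev])
  }, TRUE)
  list(
    test_auc = test_auc,
    null_auc = null_auc,
    null_auc_draws = null_auc_draws,
    localization_frac = mean(hits, na.rm = TRUE),
    n_bags = length(bags),
    n_train = length(train_bags),
    n_test = length(test_bags),
    patch_accuracy = pacc,
    evidence_patch_accuracy = ev_acc,
    model = model,
    test_predictions = test_pred,
    plan = plan,
    config = config
  )
}
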