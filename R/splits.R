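# --- patient-level version splits ---------------------------------------

# Largest-remainder apportionment of per-class training counts across
# specimen strata: base = floor(0.8 * n_stratum); leftover seats (so the
# per-class total equals floor(0.8 * n_class)) go to the strata with the
# largest fractional remainders, ties broken toward the endoscopic stratum.
apportion_train <- function(n_by_stratum, frac = 0.8) {
  base <- floor(frac * n_by_stratum)
  total <- floor(frac * sum(n_by_stratum))
  # round remainders so exact ties (e.g. 0.8 vs 0.8) are not broken by
  # floating-point noise before the endoscopic-first tie rule applies
  rem <- round(frac * n_by_stratum - base, 9)
  extra <- total - sum(base)
  if (extra > 0) {
    pref <- order(-rem, names(n_by_stratum) != "endoscopic")
    base[pref[seq_len(extra)]] <- base[pref[seq_len(extra)]] + 1
  }
  base
}

#' Build the patient-level train/test split for one evaluation version
#'
#' One global 80/20 split, stratified by class x specimen type, is drawn
#' from the seed; the four versions are nested views of it:
#' \describe{
#'   \item{Version 1}{train and test restricted to surgical patients,}
#'   \item{Version 2}{the global split as-is (both specimen types on both
#'     sides),}
#'   \item{Version 3}{full training set, test restricted to surgical
#'     patients,}
#'   \item{Version 4}{full training set, test restricted to endoscopic
#'     patients.}
#' }
#' Training patients are then dealt into 5 folds, stratified by class x
#' specimen so each fold preserves the class proportion to within one
#' patient. All slides of a patient stay on one side.
#'
#' @param cohort a `patient_cohort`.
#' @param version integer in 1..4.
#' @param seed integer seed shared across versions (shared randomization is
#'   the default; pass different seeds for independent draws).
#' @param train_frac training fraction of the global split (default 0.8).
#' @return object of class `split_plan`: list with `version`,
#'   `train_patient_ids`, `test_patient_ids`, `fold_assignment` (named
#'   integer vector over training patients), `seed`.
#' @export
make_version_split <- function(cohort, version, seed = 1, train_frac = 0.8) {
  assert_that(version %in% 1:4, "version must be one of 1, 2, 3, 4")
  if (version %in% 2:4) {
    assert_that(all(c("endoscopic", "surgical") %in% cohort$specimen_type),
                "versions 2-4 need both specimen types in the cohort")
  }
  ids <- split(cohort$patient_id,
               list(class = cohort$lnm_label, spec = cohort$specimen_type),
               drop = FALSE)
  train_ids <- character(0)
  with_seed(derive_seed(seed, 31), {
    for (cls in unique(cohort$lnm_label)) {
      n_by_stratum <- vapply(c("endoscopic", "surgical"), function(sp) {
        length(ids[[paste(cls, sp, sep = ".")]] %||% character(0))
      }, 1L)
      take <- apportion_train(n_by_stratum, train_frac)
      for (sp in names(take)) {
        pool <- ids[[paste(cls, sp, sep = ".")]] %||% character(0)
        if (length(pool) > 0 && take[[sp]] > 0) {
          train_ids <- c(train_ids,
                         pool[sample.int(length(pool), take[[sp]])])
        }
      }
    }
  })
  test_ids <- setdiff(cohort$patient_id, train_ids)
  spec_of <- stats::setNames(cohort$specimen_type, cohort$patient_id)
  cls_of <- stats::setNames(cohort$lnm_label, cohort$patient_id)
  if (version == 1) {
    train_ids <- train_ids[spec_of[train_ids] == "surgical"]
    test_ids <- test_ids[spec_of[test_ids] == "surgical"]
  } else if (version == 3) {
    test_ids <- test_ids[spec_of[test_ids] == "surgical"]
  } else if (version == 4) {
    test_ids <- test_ids[spec_of[test_ids] == "endoscopic"]
  }
  # stratified 5-fold assignment: shuffle within class x specimen, deal
  # round-robin with a rotating start so remainders spread across folds
  folds <- integer(length(train_ids))
  names(folds) <- train_ids
  with_seed(derive_seed(seed, 47 + version), {
    offset <- 0L
    for (key in unique(paste(cls_of[train_ids], spec_of[train_ids]))) {
      members <- train_ids[paste(cls_of[train_ids], spec_of[train_ids]) == key]
      members <- members[sample.int(length(members))]
      folds[members] <- ((seq_along(members) - 1L + offset) %% 5L) + 1L
      offset <- (offset + length(members)) %% 5L
    }
  })
  structure(
    list(version = as.integer(version),
         train_patient_ids = sort(train_ids),
         test_patient_ids = sort(test_ids),
         fold_assignment = folds[sort(train_ids)],
         seed = seed),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan version %d: %d train / %d test patients, 5 folds, seed %s>\n",
              x$version, length(x$train_patient_ids),
              length(x$test_patient_ids), format(x$seed)))
  invisible(x)
}

#' Tabulate a split plan against a cohort
#'
#' @param plan a `split_plan`.
#' @param cohort the cohort it was drawn from.
#' @return data.frame of patient counts by side and class.
#' @export
split_counts <- function(plan, cohort) {
  cls_of <- stats::setNames(cohort$lnm_label, cohort$patient_id)
  data.frame(
    side = c("train", "train", "test", "test"),
    lnm = c(1, 0, 1, 0),
    patients = c(sum(cls_of[plan$train_patient_ids] == 1),
                 sum(cls_of[plan$train_patient_ids] == 0),
                 sum(cls_of[plan$test_patient_ids] == 1),
                 sum(cls_of[plan$test_patient_ids] == 0))
  )
}

#' Check a split plan for patient leakage
#'
#' @param plan a `split_plan`.
#' @return `TRUE` invisibly; errors if any patient sits on both sides or a
#'   training patient lacks a fold.
#' @export
check_no_leakage <- function(plan) {
  leak <- intersect(plan$train_patient_ids, plan$test_patient_ids)
  assert_that(length(leak) == 0, "patients on both sides of the split: %s",
              paste(utils::head(leak, 5), collapse = ", "))
  assert_that(setequal(names(plan$fold_assignment), plan$train_patient_ids),
              "fold assignment does not cover the training patients")
  assert_that(all(plan$fold_assignment %in% 1:5), "folds must be in 1..5")
  invisible(TRUE)
}

#' Serialize / restore a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path JSON file path.
#' @export
write_split_json <- function(plan, path) {
  jsonlite::write_json(
    list(version = plan$version, seed = plan$seed,
         train_patient_ids = plan$train_patient_ids,
         test_patient_ids = plan$test_patient_ids,
         fold_assignment = as.list(plan$fold_assignment)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(version = as.integer(x$version),
         train_patient_ids = as.character(x$train_patient_ids),
         test_patient_ids = as.character(x$test_patient_ids),
         fold_assignment = unlist(x$fold_assignment),
         seed = x$seed),
    class = "split_plan"
  )
}

# --- cross-validation and ensembling ------------------------------------

#' Run stratified 5-fold cross-validation on a split plan's training set
#'
#' Trains one MIL model per fold (on the other four folds), records the
#' validation AUC on the held-out fold, and returns the five models for
#' test-set ensembling.
#'
#' @param plan a `split_plan`.
#' @param bags list of `wsi_bag`s covering at least the plan's training
#'   patients.
#' @param fe pretrained `fe_model`.
#' @param trainer list of arguments forwarded to [train_end_to_end()]
#'   (epochs, lr, config, freeze_fe, bag_cap).
#' @param seed integer seed (per-fold child seeds are derived).
#' @return list with `models` (5 `mil_model`s) and `fold_auc` (length 5).
#' @export
run_cv <- function(plan, bags, fe, trainer = list(), seed = 1) {
  check_no_leakage(plan)
  pid <- vapply(bags, function(b) b$patient_id, "")
  lab <- vapply(bags, function(b) as.integer(b$label), 1L)
  models <- vector("list", 5)
  fold_auc <- numeric(5)
  for (k in 1:5) {
    tr_pat <- names(plan$fold_assignment)[plan$fold_assignment != k]
    va_pat <- names(plan$fold_assignment)[plan$fold_assignment == k]
    tr_bags <- bags[pid %in% tr_pat]
    va_bags <- bags[pid %in% va_pat]
    tr_lab <- lab[pid %in% tr_pat]
    va_lab <- lab[pid %in% va_pat]
    assert_that(length(unique(tr_lab)) == 2 && length(unique(va_lab)) == 2,
                "fold %d has a single class; enlarge the cohort", k)
    args <- c(list(bags = tr_bags, fe = fe, seed = derive_seed(seed, 100 + k)),
              trainer)
    model <- do.call(train_end_to_end, args)
    va_pred <- predict_bags(model, va_bags)
    # validation AUC at patient level (mean over a patient's slides)
    va_patient <- aggregate_patient(va_pred)
    fold_auc[k] <- roc_auc(va_patient$probability, va_patient$label)
    models[[k]] <- model
  }
  list(models = models, fold_auc = fold_auc, mean_fold_auc = mean(fold_auc))
}

# slide-level predictions -> one row per patient (mean probability)
aggregate_patient <- function(pred) {
  agg <- stats::aggregate(probability ~ patient_id, data = pred, FUN = mean)
  lab <- stats::aggregate(label ~ patient_id, data = pred, FUN = function(l) l[1])
  merge(agg, lab, by = "patient_id")
}

#' Ensemble fold models on the held-out test set
#'
#' Per slide, the probability is the mean over the five fold models; per
#' patient, the mean over the patient's slides.
#'
#' @param models list of 5 trained `mil_model`s (from [run_cv()]).
#' @param bags list of `wsi_bag`s of exactly the plan's test patients.
#' @param plan the `split_plan` (used to verify coverage).
#' @return data.frame with one row per patient: `patient_id`,
#'   `probability`, `label`.
#' @export
ensemble_predict <- function(models, bags, plan = NULL) {
  pid <- vapply(bags, function(b) b$patient_id, "")
  if (!is.null(plan)) {
    missing <- setdiff(plan$test_patient_ids, pid)
    assert_that(length(missing) == 0, "missing slides for test patients: %s",
                paste(utils::head(missing, 5), collapse = ", "))
    keep <- pid %in% plan$test_patient_ids
    bags <- bags[keep]
  }
  preds <- lapply(models, function(m) predict_bags(m, bags)$probability)
  slide_prob <- Reduce(`+`, preds) / length(preds)
  pred <- data.frame(
    patient_id = vapply(bags, function(b) b$patient_id, ""),
    slide_id = vapply(bags, function(b) b$slide_id, ""),
    label = vapply(bags, function(b) as.integer(b$label), 1L),
    probability = slide_prob,
    stringsAsFactors = FALSE
  )
  aggregate_patient(pred)
}
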