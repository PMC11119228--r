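#' Rank-based area under the ROC curve
#'
#' Computes the concordance (Mann-Whitney) form of the AUC with midrank
#' handling of ties, which equals the trapezoidal integral of the empirical
#' ROC curve.
#'
#' @param scores numeric vector of predicted scores (higher = more positive).
#' @param labels binary vector (0/1 or logical) of true classes, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(length(scores) == length(labels), "scores and labels differ in length")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  assert_that(all(is.finite(scores)), "scores must be finite")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  assert_that(n_pos > 0 && n_neg > 0, "both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal operating threshold
#'
#' Scans every candidate threshold (midpoints between adjacent distinct
#' scores, plus -Inf and +Inf) and picks the one maximizing the Youden
#' index J = sensitivity + specificity - 1, with a prediction rule
#' "positive iff score > threshold". Ties on J are broken toward higher
#' sensitivity, then toward the lower threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `sensitivity`, `specificity` (fractions in
#'   \[0, 1\]) and `j` (the Youden index at the chosen threshold).
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(length(scores) == length(labels), "scores and labels differ in length")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  assert_that(n_pos > 0 && n_neg > 0, "both classes must be present to pick a cutoff")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    j <- sens + spec - 1
    if (is.null(best) ||
        j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sensitivity + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(sens - best$sensitivity) <= 1e-12 &&
         t < best$threshold)) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec, j = j)
    }
  }
  best
}

#' Confusion counts from scores, labels and a threshold
#'
#' @inheritParams roc_auc
#' @param threshold predictions are positive iff `score > threshold`.
#' @return object of class `confusion_counts`: list with integers
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores > threshold
  structure(
    list(
      tp = sum(pred & labels == 1L), fp = sum(pred & labels == 0L),
      tn = sum(!pred & labels == 0L), fn = sum(!pred & labels == 1L)
    ),
    class = "confusion_counts"
  )
}

new_confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  assert_that(all(counts >= 0), "confusion counts must be non-negative")
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(counts, class = "confusion_counts")
}

#' Reconstruct confusion counts from printed sensitivity/specificity
#'
#' Bridges a published percent sensitivity/specificity and the test-set
#' class sizes back to integer counts by nearest-integer rounding of
#' rate x n.
#'
#' @param sens_pct,spec_pct sensitivity and specificity in percent.
#' @param n_pos,n_neg numbers of truly positive / negative patients.
#' @return `confusion_counts`.
#' @examples
#' confusion_from_rates(92.9, 57.6, 14, 66) # tp 13, fp 28, tn 38, fn 1
#' @export
confusion_from_rates <- function(sens_pct, spec_pct, n_pos, n_neg) {
  assert_that(sens_pct >= 0 && sens_pct <= 100 && spec_pct >= 0 && spec_pct <= 100,
              "rates must be percentages in [0, 100]")
  assert_that(n_pos >= 0 && n_neg >= 0, "class sizes must be non-negative")
  tp <- round_half_up(sens_pct / 100 * n_pos, 0)
  tn <- round_half_up(spec_pct / 100 * n_neg, 0)
  new_confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Clinical-utility panel from confusion counts
#'
#' Computes the metric panel used to compare a predictive strategy against
#' surgery-for-everyone: sensitivity, specificity, PPV, accuracy, the
#' unnecessary-additional-surgery rate (share of strategy-positive patients
#' who are truly LNM-negative, = 100 - PPV) and the missed-LNM rate
#' (= 100 - sensitivity). All values are percentages rounded half-up to one
#' decimal.
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `utility_report`: named list of percentages
#'   (`sensitivity`, `specificity`, `ppv`, `accuracy`, `unnecessary_surgery`,
#'   `missed_lnm`). `ppv` and `unnecessary_surgery` are `NA` when no patient
#'   is predicted positive.
#' @export
clinical_utility <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  assert_that(tp + fn > 0, "no positive patients: sensitivity undefined")
  assert_that(tn + fp > 0, "no negative patients: specificity undefined")
  pred_pos <- tp + fp
  r1 <- function(x) round_half_up(x, 1)
  structure(
    list(
      sensitivity = r1(100 * tp / (tp + fn)),
      specificity = r1(100 * tn / (tn + fp)),
      ppv = if (pred_pos > 0) r1(100 * tp / pred_pos) else NA_real_,
      accuracy = r1(100 * (tp + tn) / (tp + fp + tn + fn)),
      unnecessary_surgery = if (pred_pos > 0) r1(100 * fp / pred_pos) else NA_real_,
      missed_lnm = r1(100 * fn / (tp + fn)),
      counts = counts
    ),
    class = "utility_report"
  )
}

#' @export
print.utility_report <- function(x, ...) {
  cat(sprintf(
    paste0("Sensitivity (%%)          %5.1f\nSpecificity (%%)          %5.1f\n",
           "PPV (%%)                  %5.1f\nAccuracy (%%)             %5.1f\n",
           "Unnecessary surgery (%%)  %5.1f\nMissed LNM (%%)           %5.1f\n"),
    x$sensitivity, x$specificity, x$ppv, x$accuracy,
    x$unnecessary_surgery, x$missed_lnm
  ))
  invisible(x)
}

#' All-positive (operate-on-everyone) guideline baseline
#'
#' The JSCCR-style strategy sends every high-risk patient to additional
#' surgery, i.e. predicts positive for everyone: sensitivity 100%,
#' specificity 0%, PPV = prevalence.
#'
#' @param labels binary vector of true LNM labels.
#' @return list with `counts` (`confusion_counts`) and `report`
#'   (`utility_report`).
#' @export
jsccr_baseline <- function(labels) {
  labels <- as.integer(labels)
  assert_that(length(labels) > 0, "labels must be nonempty")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  counts <- new_confusion_counts(
    tp = sum(labels == 1L), fp = sum(labels == 0L), tn = 0L, fn = 0L
  )
  prev <- 100 * counts$tp / (counts$tp + counts$fp)
  # sensitivity/specificity are definitional for the all-positive rule
  # (100 / 0), so the report stays well-defined even for one-class input
  report <- structure(
    list(
      sensitivity = 100, specificity = 0,
      ppv = round_half_up(prev, 1),
      accuracy = round_half_up(prev, 1),
      unnecessary_surgery = round_half_up(100 - prev, 1),
      missed_lnm = 0,
      counts = counts
    ),
    class = "utility_report"
  )
  list(counts = counts, report = report)
}

#' Reduction in unnecessary additional surgery versus a guideline
#'
#' Difference of the two printed (already rounded) unnecessary-surgery
#' percentages, guideline minus model, matching the arithmetic used when
#' tabulating published panels.
#'
#' @param model,guideline `utility_report` objects on the same patients.
#' @return percentage points, one decimal.
#' @export
reduction_vs_guideline <- function(model, guideline) {
  stopifnot(inherits(model, "utility_report"), inherits(guideline, "utility_report"))
  round_half_up(guideline$unnecessary_surgery - model$unnecessary_surgery, 1)
}

#' McNemar paired comparison of two strategies
#'
#' Takes per-patient correctness indicators of two paired strategies and
#' tests the symmetry of their discordant counts: `b` = A correct & B wrong,
#' `c` = A wrong & B correct. Uses the exact two-sided binomial test when
#' b + c < 25, otherwise the continuity-corrected chi-square statistic
#' (|b - c| - 1)^2 / (b + c) on 1 df.
#'
#' @param correct_a,correct_b binary/logical vectors, paired by patient.
#' @return list with `b`, `c`, `method` ("exact" or "chisq"), `statistic`
#'   (`NA` for exact) and `p_value`.
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  a <- as.logical(correct_a); b_ <- as.logical(correct_b)
  assert_that(length(a) == length(b_), "paired vectors differ in length")
  assert_that(!anyNA(a) && !anyNA(b_), "correctness indicators must not be NA")
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  n <- b + cc
  if (n == 0) {
    return(list(b = b, c = cc, method = "exact", statistic = NA_real_,
                p_value = 1.0, note = "no discordant pairs"))
  }
  if (n < 25) {
    k <- min(b, cc)
    p <- min(1, 2 * stats::pbinom(k, n, 0.5))
    list(b = b, c = cc, method = "exact", statistic = NA_real_, p_value = p)
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    list(b = b, c = cc, method = "chisq", statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
}

#' Full model-vs-guideline utility panel
#'
#' Convenience wrapper producing the published-style panel for one test set:
#' model utility at a threshold, the all-positive guideline utility, their
#' unnecessary-surgery reduction, and the McNemar comparison of per-patient
#' correctness.
#'
#' @param scores model probabilities per patient.
#' @param labels true LNM labels per patient.
#' @param threshold operating threshold (predict positive iff score >
#'   threshold), e.g. from [youden_cutoff()].
#' @return list with `model` and `jsccr` utility reports, `reduction`, and
#'   `mcnemar`.
#' @export
utility_panel <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  counts <- confusion_counts(scores, labels, threshold)
  model <- clinical_utility(counts)
  guideline <- jsccr_baseline(labels)
  correct_model <- (scores > threshold) == (labels == 1L)
  correct_jsccr <- labels == 1L
  list(
    model = model,
    jsccr = guideline$report,
    reduction = reduction_vs_guideline(model, guideline$report),
    mcnemar = mcnemar_paired(correct_model, correct_jsccr)
  )
}

#' Published-style utility panel from printed operating rates
#'
#' Reconstructs the test confusion matrix from printed sensitivity /
#' specificity percentages and class sizes, then derives every panel cell
#' for both the model and the all-positive guideline.
#'
#' @inheritParams confusion_from_rates
#' @return list with `counts`, `model`, `jsccr`, `reduction`.
#' @examples
#' table4_panel(92.9, 57.6, 14, 66)$model$ppv # 31.7
#' @export
table4_panel <- function(sens_pct, spec_pct, n_pos, n_neg) {
  counts <- confusion_from_rates(sens_pct, spec_pct, n_pos, n_neg)
  model <- clinical_utility(counts)
  guideline <- jsccr_baseline(rep(c(1L, 0L), c(n_pos, n_neg)))
  list(
    counts = counts,
    model = model,
    jsccr = guideline$report,
    reduction = reduction_vs_guideline(model, guideline$report)
  )
}

#' Random-forest clinicopathologic baseline
#'
#' Fits the tabular comparison model: a 500-tree random forest on encoded
#' clinicopathologic covariates, with the same patient-level fold protocol
#' and test-set ensembling as the image model (per-fold forests, validation
#' AUC per fold, mean of fold-forest probabilities on the test set).
#'
#' @param features data.frame of covariates, one row per patient; factors
#'   and numerics allowed, any other type is rejected.
#' @param labels binary LNM labels aligned with `features` rows.
#' @param plan a `split_plan` (see [make_version_split()]); row names or the
#'   `patient_id` column of `features` must cover its patients.
#' @param patient_ids character vector aligning `features`/`labels` rows to
#'   plan patient ids.
#' @param n_trees number of trees per forest (default 500).
#' @param seed integer seed.
#' @return list with `fold_auc` (length 5), `mean_fold_auc`, `test_auc`,
#'   `test_scores` (named per-patient ensemble probabilities).
#' @export
rf_baseline <- function(features, labels, plan, patient_ids,
                        n_trees = 500, seed = 1) {
  stopifnot(inherits(plan, "split_plan"))
  ok_type <- vapply(features, function(col) is.numeric(col) || is.factor(col), TRUE)
  if (!all(ok_type)) {
    stopf("non-numeric, non-factor feature columns: %s",
          paste(names(features)[!ok_type], collapse = ", "))
  }
  labels <- factor(as.integer(labels), levels = c(0L, 1L))
  idx <- stats::setNames(seq_along(patient_ids), patient_ids)
  train_idx <- idx[plan$train_patient_ids]
  test_idx <- idx[plan$test_patient_ids]
  assert_that(!anyNA(train_idx) && !anyNA(test_idx),
              "features must cover every patient in the split plan")
  folds <- plan$fold_assignment[plan$train_patient_ids]
  fold_auc <- numeric(5)
  test_prob <- matrix(0, length(test_idx), 5)
  forests <- vector("list", 5)
  for (k in 1:5) {
    tr <- train_idx[folds != k]
    va <- train_idx[folds == k]
    fit <- with_seed(derive_seed(seed, 700 + k), randomForest::randomForest(
      x = features[tr, , drop = FALSE], y = labels[tr], ntree = n_trees
    ))
    p_va <- stats::predict(fit, features[va, , drop = FALSE], type = "prob")[, "1"]
    fold_auc[k] <- roc_auc(p_va, as.integer(as.character(labels[va])))
    test_prob[, k] <- stats::predict(fit, features[test_idx, , drop = FALSE],
                                     type = "prob")[, "1"]
    forests[[k]] <- fit
  }
  test_scores <- rowMeans(test_prob)
  names(test_scores) <- plan$test_patient_ids
  list(
    fold_auc = fold_auc,
    mean_fold_auc = mean(fold_auc),
    test_auc = roc_auc(test_scores, as.integer(as.character(labels[test_idx]))),
    test_scores = test_scores,
    forests = forests,
    n_trees = n_trees
  )
}
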