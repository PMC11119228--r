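test_that("version splits reproduce the published composition exactly", {
  cohort <- table2_cohort()
  want <- published_table2()
  for (v in 1:4) {
    plan <- make_version_split(cohort, v, seed = 11)
    check_no_leakage(plan)
    got <- split_counts(plan, cohort)
    expect_equal(got$patients[got$side == "train" & got$lnm == 1],
                 want$train_pos[v], info = paste("version", v))
    expect_equal(got$patients[got$side == "train" & got$lnm == 0],
                 want$train_neg[v])
    expect_equal(got$patients[got$side == "test" & got$lnm == 1],
                 want$test_pos[v])
    expect_equal(got$patients[got$side == "test" & got$lnm == 0],
                 want$test_neg[v])
  }
})

test_that("test sets of versions 3 and 4 partition version 2's test set", {
  cohort <- table2_cohort()
  p2 <- make_version_split(cohort, 2, seed = 11)
  p3 <- make_version_split(cohort, 3, seed = 11)
  p4 <- make_version_split(cohort, 4, seed = 11)
  expect_setequal(c(p3$test_patient_ids, p4$test_patient_ids),
                  p2$test_patient_ids)
  expect_length(intersect(p3$test_patient_ids, p4$test_patient_ids), 0)
  # versions 2-4 share the training set
  expect_setequal(p3$train_patient_ids, p2$train_patient_ids)
  expect_setequal(p4$train_patient_ids, p2$train_patient_ids)
})

test_that("specimen restrictions of versions 1 and 4 hold", {
  cohort <- table2_cohort()
  spec <- setNames(cohort$specimen_type, cohort$patient_id)
  p1 <- make_version_split(cohort, 1, seed = 11)
  expect_true(all(spec[p1$train_patient_ids] == "surgical"))
  expect_true(all(spec[p1$test_patient_ids] == "surgical"))
  p4 <- make_version_split(cohort, 4, seed = 11)
  expect_true(all(spec[p4$test_patient_ids] == "endoscopic"))
})

test_that("folds are stratified and cover the training set exactly once", {
  cohort <- table2_cohort()
  cls <- setNames(cohort$lnm_label, cohort$patient_id)
  for (v in c(1, 2)) {
    plan <- make_version_split(cohort, v, seed = 11)
    folds <- plan$fold_assignment
    expect_setequal(names(folds), plan$train_patient_ids)
    expect_true(all(folds %in% 1:5))
    n_pos <- sum(cls[names(folds)] == 1)
    for (k in 1:5) {
      in_fold <- names(folds)[folds == k]
      # class count per fold within one patient of the proportional share
      expect_lte(abs(sum(cls[in_fold] == 1) - n_pos / 5), 1)
    }
  }
})

test_that("split determinism, errors and JSON round trip", {
  cohort <- table2_cohort()
  a <- make_version_split(cohort, 2, seed = 3)
  b <- make_version_split(cohort, 2, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, make_version_split(cohort, 2, seed = 4)))
  expect_error(make_version_split(cohort, 5, seed = 1), "version")
  surg_only <- cohort[cohort$specimen_type == "surgical", ]
  expect_error(make_version_split(surg_only, 2, seed = 1), "both specimen")
  path <- withr::local_tempfile(fileext = ".json")
  write_split_json(a, path)
  back <- read_split_json(path)
  expect_equal(back$train_patient_ids, a$train_patient_ids)
  expect_equal(back$test_patient_ids, a$test_patient_ids)
  expect_equal(unname(back$fold_assignment[a$train_patient_ids]),
               unname(a$fold_assignment[a$train_patient_ids]))
})

test_that("cross-validation trains five reusable fold models", {
  fx <- small_fixture()
  plan <- make_version_split(fx$cohort, 2, seed = 500)
  pid <- vapply(fx$bags, `[[`, "", "patient_id")
  train_bags <- fx$bags[pid %in% plan$train_patient_ids]
  cv <- run_cv(plan, train_bags, fx$fe,
               trainer = list(epochs = 6), seed = 501)
  expect_length(cv$models, 5)
  expect_length(cv$fold_auc, 5)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  # models are self-contained (reusable for prediction)
  p <- predict_bags(cv$models[[3]], train_bags[1:2])
  expect_true(all(p$probability > 0 & p$probability < 1))
})

test_that("ensembling averages over models, then over a patient's slides", {
  fx <- small_fixture()
  plan <- make_version_split(fx$cohort, 2, seed = 500)
  pid <- vapply(fx$bags, `[[`, "", "patient_id")
  test_bags <- fx$bags[pid %in% plan$test_patient_ids]
  # five identical models ensemble to the single-model output
  same <- rep(list(fx$model), 5)
  ens <- ensemble_predict(same, test_bags, plan)
  single <- predict_bags(fx$model, test_bags)
  single_pat <- aggregate_patient(single)
  m <- merge(ens, single_pat, by = "patient_id")
  expect_equal(m$probability.x, m$probability.y, tolerance = 1e-12)
  # mean-over-slides rule: a two-slide patient averages its slides
  multi <- single$patient_id[duplicated(single$patient_id)]
  if (length(multi) > 0) {
    pid1 <- multi[1]
    expect_equal(ens$probability[ens$patient_id == pid1],
                 mean(single$probability[single$patient_id == pid1]),
                 tolerance = 1e-12)
  }
  # missing slides are named
  expect_error(ensemble_predict(same, test_bags[-1], plan), "missing slides")
})
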