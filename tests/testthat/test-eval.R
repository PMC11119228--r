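test_that("roc_auc matches hand-computable cases", {
  expect_equal(roc_auc(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  # perfect separation and all-ties
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("roc_auc equals the pairwise-concordance oracle on random inputs", {
  withr::with_seed(101, {
    for (rep in 1:30) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
      expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
    }
  })
})

test_that("roc_auc agrees with pROC on a tied example", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    labels <- sample(0:1, 40, replace = TRUE)
    labels[1:2] <- 0:1
    scores <- round(runif(40), 1)
    expect_equal(
      roc_auc(scores, labels),
      as.numeric(suppressMessages(pROC::auc(labels, scores))),
      tolerance = 1e-12
    )
  })
})

test_that("youden_cutoff maximizes J with the documented tie rules", {
  # perfect separation
  yc <- youden_cutoff(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(yc$j, 1)
  expect_equal(yc$sensitivity, 1)
  expect_equal(yc$specificity, 1)
  # tie between two J = 0.5 thresholds resolves toward higher sensitivity
  yc <- youden_cutoff(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(yc$j, 0.5)
  expect_equal(yc$sensitivity, 1)
  expect_equal(yc$specificity, 0.5)
  expect_lt(yc$threshold, 0.3)
  # shift invariance
  yc2 <- youden_cutoff(c(0.9, 0.3, 0.6, 0.1) + 5, c(1, 1, 0, 0))
  expect_equal(yc2$threshold, yc$threshold + 5)
  expect_equal(yc2$j, yc$j)
})

test_that("youden_cutoff equals the exhaustive-scan oracle on random inputs", {
  withr::with_seed(202, {
    for (rep in 1:25) {
      n <- sample(5:40, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(1:2, 1))
      got <- youden_cutoff(scores, labels)
      want <- brute_youden(scores, labels)
      expect_equal(got$j, want$j)
      expect_equal(got$sensitivity, want$sensitivity)
      expect_equal(got$threshold, want$threshold)
    }
  })
})

test_that("clinical_utility reproduces the published version panels", {
  # version 4 test set: 14 positive / 66 negative patients
  r <- clinical_utility(new_confusion_counts(tp = 13, fp = 28, tn = 38, fn = 1))
  expect_equal(r$ppv, 31.7)
  expect_equal(r$accuracy, 63.8)
  expect_equal(r$unnecessary_surgery, 68.3)
  expect_equal(r$missed_lnm, 7.1)
  # version 3 test set: 21 / 156
  r3 <- clinical_utility(new_confusion_counts(tp = 16, fp = 22, tn = 134, fn = 5))
  expect_equal(r3$ppv, 42.1)
  expect_equal(r3$unnecessary_surgery, 57.9)
  # degenerate perfect classifier
  rp <- clinical_utility(new_confusion_counts(1, 0, 1, 0))
  expect_equal(rp$sensitivity, 100)
  expect_equal(rp$specificity, 100)
  expect_equal(rp$unnecessary_surgery, 0)
  expect_equal(rp$missed_lnm, 0)
})

test_that("utility identities hold before rounding on random counts", {
  withr::with_seed(303, {
    for (rep in 1:20) {
      tp <- sample(1:50, 1); fp <- sample(0:50, 1)
      tn <- sample(1:50, 1); fn <- sample(0:50, 1)
      unnec <- 100 * fp / (tp + fp)
      ppv <- 100 * tp / (tp + fp)
      expect_equal(unnec, 100 - ppv, tolerance = 1e-9)
      sens <- 100 * tp / (tp + fn)
      missed <- 100 * fn / (tp + fn)
      expect_equal(missed, 100 - sens, tolerance = 1e-9)
      r <- clinical_utility(new_confusion_counts(tp, fp, tn, fn))
      expect_equal(r$unnecessary_surgery, round_half_up(unnec, 1))
      expect_equal(r$missed_lnm, round_half_up(missed, 1))
    }
  })
})

test_that("the all-positive guideline baseline is degenerate by construction", {
  r <- jsccr_baseline(rep(c(1, 0), c(14, 66)))$report
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 0)
  expect_equal(r$ppv, 17.5)
  expect_equal(r$unnecessary_surgery, 82.5)
  r1 <- jsccr_baseline(rep(c(1, 0), c(21, 156)))$report
  expect_equal(r1$unnecessary_surgery, 88.1)
  # all-positive labels: every surgery is necessary
  rall <- jsccr_baseline(rep(1, 10))$report
  expect_equal(rall$ppv, 100)
  expect_equal(rall$unnecessary_surgery, 0)
  # invariant on random labels
  withr::with_seed(11, {
    for (rep in 1:10) {
      lab <- sample(0:1, sample(2:30, 1), replace = TRUE)
      rr <- jsccr_baseline(lab)$report
      expect_identical(rr$sensitivity, 100)
      expect_identical(rr$specificity, 0)
    }
  })
})

test_that("reduction vs guideline matches the published arithmetic", {
  v4 <- table4_panel(92.9, 57.6, 14, 66)
  expect_equal(v4$reduction, 14.2)
  v1 <- table4_panel(71.4, 92.9, 21, 156)
  expect_equal(v1$reduction, 45.8)
  expect_equal(reduction_vs_guideline(v1$model, v1$model), 0.0)
})

test_that("mcnemar_paired: exact branch, chi-square branch and edge cases", {
  # symmetric discordance
  a <- rep(c(TRUE, FALSE, TRUE), c(5, 5, 10))
  b <- rep(c(FALSE, TRUE, TRUE), c(5, 5, 10))
  expect_equal(mcnemar_paired(a, b)$p_value, 1.0)
  # one-sided discordance b = 10, c = 0 -> 2 * (1/2)^10
  expect_equal(mcnemar_paired(rep(TRUE, 10), rep(FALSE, 10))$p_value,
               2 * 0.5^10)
  # chi-square branch with continuity correction
  a <- rep(c(TRUE, FALSE), c(30, 10))
  b <- rep(c(FALSE, TRUE), c(30, 10))
  m <- mcnemar_paired(a, b)
  expect_equal(m$method, "chisq")
  expect_equal(m$statistic, (abs(30 - 10) - 1)^2 / 40)
  # matches stats::mcnemar.test on the 2x2 discordance table
  tab <- matrix(c(0, 10, 30, 0), 2)
  expect_equal(m$p_value, stats::mcnemar.test(tab)$p.value)
  # no discordance
  expect_equal(mcnemar_paired(c(TRUE, FALSE), c(TRUE, FALSE))$p_value, 1.0)
})

test_that("exact mcnemar p equals the binomial oracle across counts", {
  for (b in 0:8) for (cc in 0:8) {
    if (b + cc == 0) next
    a_vec <- rep(c(TRUE, FALSE), c(b, cc))
    b_vec <- rep(c(FALSE, TRUE), c(b, cc))
    p <- mcnemar_paired(a_vec, b_vec)$p_value
    oracle <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
    expect_equal(p, oracle)
  }
})

test_that("confusion_from_rates reconstructs published counts", {
  c4 <- confusion_from_rates(92.9, 57.6, 14, 66)
  expect_equal(unlist(c4[c("tp", "fp", "tn", "fn")]),
               c(tp = 13, fp = 28, tn = 38, fn = 1))
  expect_error(confusion_from_rates(101, 50, 10, 10), "percentages")
})

test_that("random forest baseline separates a planted signal and not noise", {
  withr::with_seed(55, {
    cohort <- generate_cohort(60, 60, prev_endo = 0.35, prev_surg = 0.35,
                              seed = 56)
    plan <- make_version_split(cohort, 2, seed = 57)
    # perfectly separable feature
    feats <- data.frame(signal = cohort$lnm_label + rnorm(nrow(cohort), 0, 1e-3),
                        noise = rnorm(nrow(cohort)))
    rownames(feats) <- cohort$patient_id
    rf <- rf_baseline(feats, cohort$lnm_label, plan, cohort$patient_id,
                      seed = 58)
    expect_gte(rf$test_auc, 0.99)
    expect_equal(rf$forests[[1]]$ntree, 500)
    # permuted labels: no signal
    perm <- sample(cohort$lnm_label)
    rf0 <- rf_baseline(data.frame(noise = rnorm(nrow(cohort)),
                                  noise2 = rnorm(nrow(cohort)),
                                  row.names = cohort$patient_id),
                       perm, plan, cohort$patient_id, seed = 59)
    expect_gte(rf0$test_auc, 0.3)
    expect_lte(rf0$test_auc, 0.7)
  })
})

test_that("round_half_up rounds .5 away from zero", {
  expect_equal(round_half_up(63.75, 1), 63.8)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(1.24499, 2), 1.24)
})
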