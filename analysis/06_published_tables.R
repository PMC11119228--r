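#!/usr/bin/env Rscript
# 06 — arithmetic reconstruction of the published tables.
#
# No training involved: verifies that the package's split apportionment
# reproduces the published train/test composition from the cohort sizes,
# and that the clinical-utility panel derived from the printed operating
# rates reproduces every published cell (PPV, accuracy, unnecessary
# surgery, missed LNM, guideline columns, reduction).

suppressPackageStartupMessages(library(lnmil))
dir.create("results", showWarnings = FALSE)

pc <- published_cohort()

# split composition from the published stratum sizes
cohort <- generate_cohort(pc$n_endoscopic, pc$n_surgical,
                          prev_endo = pc$endo_pos / pc$n_endoscopic,
                          prev_surg = pc$surg_pos / pc$n_surgical, seed = 1)
splits <- do.call(rbind, lapply(1:4, function(v) {
  cnt <- split_counts(make_version_split(cohort, v, seed = 1), cohort)
  data.frame(version = v,
             train_pos = cnt$patients[cnt$side == "train" & cnt$lnm == 1],
             train_neg = cnt$patients[cnt$side == "train" & cnt$lnm == 0],
             test_pos = cnt$patients[cnt$side == "test" & cnt$lnm == 1],
             test_neg = cnt$patients[cnt$side == "test" & cnt$lnm == 0])
}))
write.csv(splits, "results/split_composition.csv", row.names = FALSE)
stopifnot(all(as.matrix(splits[, -1]) == as.matrix(published_table2()[, -1])))
cat("split composition matches the published table for all four versions\n")

# utility panels from the printed operating rates
ops <- published_operating_points()
t2 <- published_table2()
panels <- do.call(rbind, lapply(1:4, function(v) {
  p <- table4_panel(ops$sensitivity[v], ops$specificity[v],
                    t2$test_pos[v], t2$test_neg[v])
  data.frame(version = v,
             sensitivity = p$model$sensitivity,
             specificity = p$model$specificity,
             ppv = p$model$ppv, accuracy = p$model$accuracy,
             unnecessary_surgery = p$model$unnecessary_surgery,
             missed_lnm = p$model$missed_lnm,
             jsccr_ppv = p$jsccr$ppv,
             jsccr_unnecessary_surgery = p$jsccr$unnecessary_surgery,
             reduction = p$reduction)
}))
write.csv(panels, "results/utility_reconstruction.csv", row.names = FALSE)
print(panels)

# cohort arithmetic
study <- generate_cohort(pc$n_endoscopic, pc$n_surgical,
                         pc$prev_endo, pc$prev_surg, seed = 1)
s <- cohort_summary(study, ln_positive = pc$ln_positive, ln_total = pc$ln_total)
cat(sprintf("overall prevalence %.1f%% | LN ratio %.2f%%\n",
            s$overall_prevalence_pct, s$ln_ratio_pct))
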