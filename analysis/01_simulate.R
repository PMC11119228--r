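#!/usr/bin/env Rscript
# 01 — simulate the study cohort and slides.
#
# Generates a desk-scale synthetic cohort mirroring the study's structure:
# 100 endoscopic-resection patients (17.8% LNM) and 150 surgical patients
# (6.6% LNM), clinicopathologic covariates drawn from the published
# stratum distributions, ~10% of patients contributing two slides. Writes
# the cohort table, a stratum summary, and a small gallery of rendered
# slides with their ground-truth evidence masks.

suppressPackageStartupMessages(library(lnmil))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

config <- run_config(seed = 2026, n_endoscopic = 100, n_surgical = 150,
                     slide_px = 512, patch_size = 64)
saveRDS(config, "scratch/config.rds")

cohort <- generate_cohort(config$n_endoscopic, config$n_surgical,
                          config$prev_endo, config$prev_surg,
                          seed = config$seed)
write_cohort_csv(cohort, "results/cohort.csv")

s <- cohort_summary(cohort)
cat(sprintf("cohort: %d patients, %d slides\n", s$n_patients, s$n_slides))
cat(sprintf("  endoscopic: %d patients, prevalence %.1f%%\n",
            s$endoscopic["n"], s$endoscopic["prevalence_pct"]))
cat(sprintf("  surgical:   %d patients, prevalence %.1f%%\n",
            s$surgical["n"], s$surgical["prevalence_pct"]))
cat(sprintf("  overall prevalence: %.1f%%\n", s$overall_prevalence_pct))

summary_df <- data.frame(
  stratum = c("endoscopic", "surgical", "overall"),
  patients = c(s$endoscopic["n"], s$surgical["n"], s$n_patients),
  positives = c(s$endoscopic["positives"], s$surgical["positives"],
                s$endoscopic["positives"] + s$surgical["positives"]),
  prevalence_pct = c(s$endoscopic["prevalence_pct"],
                     s$surgical["prevalence_pct"],
                     s$overall_prevalence_pct)
)
write.csv(summary_df, "results/cohort_summary.csv", row.names = FALSE)

# gallery: two positive and two negative patients, slides + evidence masks
gallery <- cohort[c(which(cohort$lnm_label == 1)[1:2],
                    which(cohort$lnm_label == 0)[1:2]), ]
gallery$n_slides <- 1L
simulate_dataset(gallery, "results/slide_gallery",
                 params = slide_params(size = config$slide_px,
                                       patch_size = config$patch_size),
                 seed = config$seed, force = TRUE)
cat("wrote results/cohort.csv, results/cohort_summary.csv and a 4-slide gallery\n")
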