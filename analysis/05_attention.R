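#!/usr/bin/env Rscript
# 05 — attention heatmaps and high-attention patch export.
#
# For positive test slides of the version-2 model: renders the min-max
# normalized attention heatmap over the slide, exports the top-3 patches
# by attention score, and quantifies localization (mean normalized
# attention on evidence-bearing vs normal patches).

suppressPackageStartupMessages(library(lnmil))

config <- readRDS("scratch/config.rds")
cohort <- read_cohort_csv("results/cohort.csv")
report <- readRDS("scratch/report_v2.rds")
bags <- readRDS("scratch/bags.rds")
model <- report$models[[1]]
dir.create("results/attention", showWarnings = FALSE, recursive = TRUE)

pid <- vapply(bags, `[[`, "", "patient_id")
lab <- vapply(bags, `[[`, 1L, "label")
test_pos <- bags[pid %in% report$plan$test_patient_ids & lab == 1]

rows <- list()
for (bag in test_pos) {
  res <- mil_forward(model, encode(model$fe, bag))
  nv <- minmax_normalize(res$scores)
  ev <- bag$evidence_frac > 0
  # re-render the slide for the gallery overlays
  rec <- cohort[cohort$patient_id == bag$patient_id, ]
  slide_index <- as.integer(sub(".*_S", "", bag$slide_id))
  i <- match(bag$patient_id, cohort$patient_id)
  sl <- render_slide(rec, slide_params(size = config$slide_px,
                                       patch_size = config$patch_size),
                     seed = lnmil:::derive_seed(config$seed, 1000 + i * 10 + slide_index),
                     slide_index = slide_index)
  png::writePNG(sl$pixels,
                file.path("results/attention", paste0(bag$slide_id, "_slide.png")))
  render_heatmap(bag, res, slide_dim = c(config$slide_px, config$slide_px),
                 path = file.path("results/attention",
                                  paste0(bag$slide_id, "_heatmap.png")))
  write_attention_csv(bag, res,
                      file.path("results/attention",
                                paste0(bag$slide_id, "_scores.csv")))
  full_bag <- tile(sl, detect_tissue(sl, min_area = config$patch_size^2),
                   patch_size = config$patch_size)
  top_patches(full_bag, res, k = min(3, bag$n),
              dir = file.path("results/attention", paste0(bag$slide_id, "_top")))
  rows[[bag$slide_id]] <- data.frame(
    slide_id = bag$slide_id,
    probability = res$probability,
    mean_as_evidence = if (any(ev)) mean(nv[ev]) else NA,
    mean_as_normal = if (any(!ev)) mean(nv[!ev]) else NA,
    localized = if (any(ev) && any(!ev)) mean(nv[ev]) > mean(nv[!ev]) else NA
  )
}
loc <- do.call(rbind, rows)
write.csv(loc, "results/attention_localization.csv", row.names = FALSE)
cat(sprintf("attention localized on evidence in %d / %d positive test slides\n",
            sum(loc$localized, na.rm = TRUE), sum(!is.na(loc$localized))))
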