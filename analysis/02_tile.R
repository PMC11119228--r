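#!/usr/bin/env Rscript
# 02 — tissue detection and patch tiling.
#
# Renders every slide of the simulated cohort, detects tissue (Otsu on the
# saturation channel, components smaller than one patch dropped), tiles
# each slide into non-overlapping 64 px patches keeping cells with >= 50%
# tissue, and mean-pools patches to the 32 px encoder input. Bags are the
# unit of all downstream modelling.

suppressPackageStartupMessages(library(lnmil))

config <- readRDS("scratch/config.rds")
cohort <- read_cohort_csv("results/cohort.csv")

t0 <- Sys.time()
bags <- build_bags(cohort, config)
cat(sprintf("tiled %d slides in %.1f min\n", length(bags),
            as.numeric(Sys.time() - t0, units = "mins")))
saveRDS(bags, "scratch/bags.rds")

sizes <- data.frame(
  slide_id = vapply(bags, `[[`, "", "slide_id"),
  patient_id = vapply(bags, `[[`, "", "patient_id"),
  label = vapply(bags, `[[`, 1L, "label"),
  specimen = cohort$specimen_type[match(vapply(bags, `[[`, "", "patient_id"),
                                        cohort$patient_id)],
  n_patches = vapply(bags, `[[`, 1L, "n"),
  evidence_patches = vapply(bags, function(b) sum(b$evidence_frac > 0), 1L)
)
write.csv(sizes, "results/bag_sizes.csv", row.names = FALSE)

cat(sprintf("patches per bag: median %d (endoscopic %d, surgical %d)\n",
            median(sizes$n_patches),
            median(sizes$n_patches[sizes$specimen == "endoscopic"]),
            median(sizes$n_patches[sizes$specimen == "surgical"])))
cat(sprintf("positive bags with >=1 evidence patch: %d / %d\n",
            sum(sizes$evidence_patches > 0 & sizes$label == 1),
            sum(sizes$label == 1)))
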