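#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic crowdsourced TMA study.
#
# Produces, under results/data/:
#   detection ground truth + 50-rater lay crowd + 3-expert panel (10 images,
#   6x6 grid), an IHC study (30 images, 45 lay raters scoring 10 images
#   each, 3 experts), and the four disjoint crowds of the 2x2 tutorial
#   factorial (50 raters per cell).

suppressPackageStartupMessages(library(crowdtma))

SEED <- 20161213L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# --- detection study -------------------------------------------------------
truth <- generate_ground_truth(n_images = 10, rows = 6, cols = 6,
                               p_cancer = 0.4, p_no_tissue = 0.15,
                               seed = SEED)
crowd <- simulate_crowd(truth, 50, lay_profile_sampler(), seed = SEED + 1)
experts <- simulate_expert_panel(truth, k = 3, seed = SEED + 2)

truth_tbl <- truth$grid
truth_tbl$rater_id <- "__truth__"
truth_tbl$rater_type <- "expert"
write_detection_table(truth_tbl, file.path(out, "detection_truth.csv"))
write_detection_table(crowd$annotations, file.path(out, "detection_lay.csv"))
write_detection_table(experts$detection, file.path(out, "detection_expert.csv"))

cat(sprintf("detection: %d squares (%d no-tissue in truth), %d lay raters, %d experts\n",
            nrow(truth$grid), sum(truth$grid$label == "no_tissue"),
            length(crowd$profiles), 3))

# --- IHC study -------------------------------------------------------------
ihc_truth <- generate_ground_truth(n_images = 30, seed = SEED + 3)
ihc_crowd <- simulate_ihc_crowd(ihc_truth, 45, lay_profile_sampler(),
                                images_per_rater = 10, seed = SEED + 4)
ihc_experts <- simulate_expert_panel(ihc_truth, k = 3, seed = SEED + 5)

write_ihc_table(ihc_crowd$ratings, file.path(out, "ihc_lay.csv"))
write_ihc_table(ihc_experts$ihc, file.path(out, "ihc_expert.csv"))
readr::write_csv(ihc_truth$ihc, file.path(out, "ihc_truth.csv"))

cat(sprintf("ihc: %d images, %d lay ratings (%d raters x 10 images), %d expert ratings\n",
            nrow(ihc_truth$ihc), nrow(ihc_crowd$ratings), 45,
            nrow(ihc_experts$ihc)))

# --- factorial tutorial study ----------------------------------------------
cells <- simulate_factorial_study(truth, n_per_cell = 50, seed = SEED + 6)
for (cl in c("none", "annotated", "feedback", "both")) {
  write_detection_table(cells[[cl]],
                        file.path(out, sprintf("factorial_%s.csv", cl)))
}
readr::write_csv(cells$design, file.path(out, "factorial_design.csv"))
cat("factorial: 4 cells x 50 raters; cell means:\n")
print(as.data.frame(cells$design), row.names = FALSE)
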