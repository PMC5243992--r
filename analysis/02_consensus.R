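#!/usr/bin/env Rscript
# Stage 2: consensus scores and the no-tissue mask.
#
# Reads the stage-1 CSVs, forms the expert majority-vote reference and
# unanimous no-tissue mask, the lay per-square majority consensus, the
# median expert IHC score per image, and the aggregate lay H-score with a
# bootstrapped 95th-percentile CI of the median.

suppressPackageStartupMessages(library(crowdtma))

SEED <- 20161213L
dat <- "results/data"
out <- "results"
if (!file.exists(file.path(dat, "detection_lay.csv"))) {
  stop("run analysis/01_simulate.R first")
}

lay <- read_detection_table(file.path(dat, "detection_lay.csv"))
experts <- read_detection_table(file.path(dat, "detection_expert.csv"))
cons <- expert_detection_consensus(experts, mask_rule = "unanimous")

scores <- majority_consensus(lay)
scores$masked <- paste(scores$image_id, scores$row, scores$col) %in%
  paste(cons$mask$image_id, cons$mask$row, cons$mask$col)
readr::write_csv(scores, file.path(out, "square_scores.csv"))
readr::write_csv(cons$reference, file.path(out, "expert_reference.csv"))
readr::write_csv(cons$mask, file.path(out, "no_tissue_mask.csv"))

cat(sprintf("expert consensus: %d squares, %d masked as unanimous no-tissue (%.1f%%)\n",
            nrow(cons$reference), nrow(cons$mask),
            100 * nrow(cons$mask) / nrow(cons$reference)))
cat(sprintf("lay consensus: %d squares positive of %d unmasked\n",
            sum(scores$consensus & !scores$masked), sum(!scores$masked)))

ihc_lay <- read_ihc_table(file.path(dat, "ihc_lay.csv"))
ihc_experts <- read_ihc_table(file.path(dat, "ihc_expert.csv"))
ihc_ref <- expert_ihc_consensus(ihc_experts)
readr::write_csv(ihc_ref, file.path(out, "ihc_expert_reference.csv"))

hs <- aggregate_h_score(ihc_lay, n_boot = 10000, seed = SEED + 7)
readr::write_csv(hs, file.path(out, "image_hscores.csv"))
cat(sprintf("aggregate H-scores: %d images, median CI width %.0f (median over images)\n",
            nrow(hs), median(hs$ci_high - hs$ci_low)))
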