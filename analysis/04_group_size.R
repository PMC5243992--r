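#!/usr/bin/env Rscript
# Stage 4: accuracy as a function of crowd size.
#
# Detection: bootstrap AUC over group sizes 3..40, 500 resamples per size.
# IHC: bootstrap Spearman r over a coarser size grid (each size costs one
# correlation per resample), plus the full-population correlation with a
# 10,000-resample percentile CI.

suppressPackageStartupMessages(library(crowdtma))

SEED <- 20161213L
dat <- "results/data"
out <- "results"
if (!file.exists(file.path(out, "expert_reference.csv"))) {
  stop("run analysis/02_consensus.R first")
}

lay <- read_detection_table(file.path(dat, "detection_lay.csv"))
reference <- readr::read_csv(file.path(out, "expert_reference.csv"),
                             show_col_types = FALSE)
mask <- readr::read_csv(file.path(out, "no_tissue_mask.csv"),
                        show_col_types = FALSE)

auc_curve <- bootstrap_group_auc(lay, reference, mask, sizes = 3:40,
                                 n_boot = 500, seed = SEED + 8)
readr::write_csv(auc_curve, file.path(out, "auc_curve.csv"))
cat(sprintf("AUC curve: size 3 mean %.3f -> size 40 mean %.3f (plateau above 0.90: %s)\n",
            auc_curve$point[auc_curve$size == 3],
            auc_curve$point[auc_curve$size == 40],
            auc_curve$point[auc_curve$size == 40] > 0.90))

ihc_lay <- read_ihc_table(file.path(dat, "ihc_lay.csv"))
ihc_ref <- readr::read_csv(file.path(out, "ihc_expert_reference.csv"),
                           show_col_types = FALSE)

sp_curve <- bootstrap_spearman(ihc_lay, ihc_ref,
                               sizes = c(3, 5, 10, 20, 40),
                               n_boot = 2000, seed = SEED + 9)
readr::write_csv(sp_curve, file.path(out, "spearman_curve.csv"))
cat("Spearman curve (median over resamples):\n")
print(as.data.frame(sp_curve), row.names = FALSE)

full <- spearman_vs_experts(ihc_lay, ihc_ref, n_boot = 10000,
                            seed = SEED + 10)
jsonlite::write_json(full, file.path(out, "spearman_full.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("full population (n=%d raters): r %.3f, 95%% CI (%.3f, %.3f)\n",
            full$n_raters, full$r, full$ci_low, full$ci_high))
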