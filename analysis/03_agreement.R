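#!/usr/bin/env Rscript
# Stage 3: agreement metrics.
#
# Per-rater sensitivity/specificity/F1/kappa against the expert reference
# over unmasked squares; consensus-vs-reference kappa; pairwise expert
# kappas and their mean; the full-crowd vote-fraction AUC.

suppressPackageStartupMessages(library(crowdtma))
suppressPackageStartupMessages(library(dplyr))

dat <- "results/data"
out <- "results"
if (!file.exists(file.path(out, "expert_reference.csv"))) {
  stop("run analysis/02_consensus.R first")
}

lay <- read_detection_table(file.path(dat, "detection_lay.csv"))
experts <- read_detection_table(file.path(dat, "detection_expert.csv"))
reference <- readr::read_csv(file.path(out, "expert_reference.csv"),
                             show_col_types = FALSE)
mask <- readr::read_csv(file.path(out, "no_tissue_mask.csv"),
                        show_col_types = FALSE)
scores <- readr::read_csv(file.path(out, "square_scores.csv"),
                          show_col_types = FALSE)

perf <- rater_performance(lay, reference, mask)
readr::write_csv(perf, file.path(out, "rater_performance.csv"))
cat(sprintf("individual raters (n=%d): mean sens %.3f, spec %.3f, F1 %.3f, kappa %.3f\n",
            nrow(perf), mean(perf$sensitivity), mean(perf$specificity),
            mean(perf$f1), mean(perf$kappa)))

unmask <- function(d) anti_join(d, mask, by = c("image_id", "row", "col")) |>
  arrange(image_id, row, col)
cons_grid <- unmask(transmute(scores, image_id, row, col,
                              positive = consensus))
ref_grid <- unmask(reference)
cons_kappa <- cohens_kappa(cons_grid$positive, ref_grid$positive)

pk <- expert_pairwise_kappa(experts, mask)
frac <- unmask(scores)
auc <- roc_auc(frac$vote_fraction, ref_grid$positive)

cat(sprintf("consensus vs reference kappa: %.3f (mean individual %.3f)\n",
            cons_kappa, mean(perf$kappa)))
cat(sprintf("expert pairwise kappas: %s; mean %.3f\n",
            paste(sprintf("%.3f", pk$pairs$kappa), collapse = ", "), pk$mean))
cat(sprintf("full-crowd vote-fraction AUC: %.3f over %d unmasked squares\n",
            as.numeric(auc), nrow(ref_grid)))

jsonlite::write_json(
  list(consensus_kappa = cons_kappa,
       mean_individual_kappa = mean(perf$kappa),
       expert_pairwise_kappa_mean = pk$mean,
       crowd_auc = as.numeric(auc),
       n_unmasked_squares = nrow(ref_grid)),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
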