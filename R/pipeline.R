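#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end synthetic study in one
#' validated list. Analysis defaults encode the study constants: group
#' sizes 3 to 40 with 500 detection resamples, 10000 IHC resamples, 95%
#' percentile intervals.
#'
#' @param seed Master seed for every stage.
#' @param n_images,rows,cols Detection ground-truth dimensions.
#' @param p_cancer,p_no_tissue Per-square truth probabilities.
#' @param n_raters Lay detection crowd size.
#' @param n_experts Expert panel size.
#' @param n_ihc_images,n_ihc_raters,images_per_rater IHC study dimensions.
#' @param sizes Group sizes for the detection AUC curve.
#' @param spearman_sizes Group sizes for the IHC curve (a coarser grid, as
#'   each size costs `n_boot_spearman` correlations).
#' @param n_boot_auc,n_boot_spearman Bootstrap resamples.
#' @param ci_level Confidence level in percent.
#' @param tie_rule Majority tie rule (`"negative"` or `"positive"`).
#' @param mask_rule No-tissue mask rule (`"unanimous"` or `"majority"`).
#' @param run_factorial Whether to run the tutorial-effect stage.
#' @param n_per_cell Raters per factorial cell.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1, n_images = 10, rows = 6, cols = 6,
                       p_cancer = 0.4, p_no_tissue = 0.15,
                       n_raters = 50, n_experts = 3,
                       n_ihc_images = 30, n_ihc_raters = 45,
                       images_per_rater = 10,
                       sizes = 3:40, spearman_sizes = c(3, 5, 10, 20, 40),
                       n_boot_auc = 500, n_boot_spearman = 10000,
                       ci_level = 95,
                       tie_rule = c("negative", "positive"),
                       mask_rule = c("unanimous", "majority"),
                       run_factorial = TRUE, n_per_cell = 50) {
  tie_rule <- match.arg(tie_rule)
  mask_rule <- match.arg(mask_rule)
  stopifnot(n_raters >= 1, n_experts >= 1, n_ihc_raters >= 1,
            images_per_rater >= 1, images_per_rater <= n_ihc_images,
            n_boot_auc >= 1, n_boot_spearman >= 1,
            ci_level > 0, ci_level <= 100, all(sizes >= 1),
            all(spearman_sizes >= 1), n_per_cell >= 1)
  spearman_sizes <- pmin(spearman_sizes, n_ihc_raters)
  structure(
    list(seed = seed, n_images = n_images, rows = rows, cols = cols,
         p_cancer = p_cancer, p_no_tissue = p_no_tissue,
         n_raters = n_raters, n_experts = n_experts,
         n_ihc_images = n_ihc_images, n_ihc_raters = n_ihc_raters,
         images_per_rater = images_per_rater,
         sizes = sizes, spearman_sizes = unique(spearman_sizes),
         n_boot_auc = n_boot_auc, n_boot_spearman = n_boot_spearman,
         ci_level = ci_level, tie_rule = tie_rule, mask_rule = mask_rule,
         run_factorial = run_factorial, n_per_cell = n_per_cell),
    class = "run_config"
  )
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, consensus, metrics, curves and (optionally) the
#' factorial stage, writing every intermediate and result as a plain file
#' under `out_dir`. Reruns with the same config are bit-identical. The
#' config (and the seed) is echoed into `run_metadata.json`.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  path <- function(...) file.path(out_dir, ...)

  # --- simulate ------------------------------------------------------------
  truth <- generate_ground_truth(
    n_images = config$n_images, rows = config$rows, cols = config$cols,
    p_cancer = config$p_cancer, p_no_tissue = config$p_no_tissue,
    seed = child_seed(config$seed, 100L))
  crowd <- simulate_crowd(truth, config$n_raters,
                          seed = child_seed(config$seed, 101L))
  experts <- simulate_expert_panel(truth, k = config$n_experts,
                                   seed = child_seed(config$seed, 102L))
  ihc_truth <- generate_ground_truth(
    n_images = config$n_ihc_images, rows = config$rows, cols = config$cols,
    p_cancer = config$p_cancer, p_no_tissue = config$p_no_tissue,
    seed = child_seed(config$seed, 103L))
  ihc_crowd <- simulate_ihc_crowd(ihc_truth, config$n_ihc_raters,
                                  images_per_rater = config$images_per_rater,
                                  seed = child_seed(config$seed, 104L))
  ihc_experts <- simulate_expert_panel(ihc_truth, k = config$n_experts,
                                       seed = child_seed(config$seed, 105L))
  write_detection_table(crowd$annotations, path("detection_lay.csv"))
  write_detection_table(experts$detection, path("detection_expert.csv"))
  write_ihc_table(ihc_crowd$ratings, path("ihc_lay.csv"))
  write_ihc_table(ihc_experts$ihc, path("ihc_expert.csv"))
  truth_tbl <- truth$grid
  truth_tbl$rater_id <- "__truth__"
  truth_tbl$rater_type <- "expert"
  write_detection_table(truth_tbl, path("truth.csv"))
  say("simulate: ", config$n_raters, " lay raters, ", config$n_experts,
      " experts, ", nrow(truth$grid), " squares; IHC ", config$n_ihc_raters,
      " raters over ", config$n_ihc_images, " images")

  # --- consensus -----------------------------------------------------------
  expert_cons <- expert_detection_consensus(experts$detection,
                                            mask_rule = config$mask_rule)
  scores <- majority_consensus(crowd$annotations, tie = config$tie_rule)
  scores$masked <- paste(scores$image_id, scores$row, scores$col) %in%
    paste(expert_cons$mask$image_id, expert_cons$mask$row,
          expert_cons$mask$col)
  readr::write_csv(scores, path("square_scores.csv"))
  ihc_ref <- expert_ihc_consensus(ihc_experts$ihc)
  hscores <- aggregate_h_score(ihc_crowd$ratings,
                               n_boot = config$n_boot_spearman,
                               level = config$ci_level,
                               seed = child_seed(config$seed, 106L))
  readr::write_csv(hscores, path("image_hscores.csv"))
  say("consensus: ", nrow(expert_cons$mask), " masked squares (rule: ",
      config$mask_rule, ")")

  # --- metrics -------------------------------------------------------------
  perf <- rater_performance(crowd$annotations, expert_cons$reference,
                            expert_cons$mask)
  readr::write_csv(perf, path("rater_performance.csv"))
  cons_grid <- dplyr::transmute(scores, .data$image_id, .data$row, .data$col,
                                positive = .data$consensus)
  cons_kappa <- {
    a <- dplyr::arrange(apply_mask(cons_grid, expert_cons$mask),
                        .data$image_id, .data$row, .data$col)
    b <- dplyr::arrange(apply_mask(expert_cons$reference, expert_cons$mask),
                        .data$image_id, .data$row, .data$col)
    cohens_kappa(a$positive, b$positive)
  }
  pk <- expert_pairwise_kappa(experts$detection, expert_cons$mask)
  frac <- dplyr::arrange(apply_mask(scores, expert_cons$mask),
                         .data$image_id, .data$row, .data$col)
  refm <- dplyr::arrange(apply_mask(expert_cons$reference, expert_cons$mask),
                         .data$image_id, .data$row, .data$col)
  crowd_auc <- roc_auc(frac$vote_fraction, refm$positive)
  summary_list <- list(
    consensus_kappa = cons_kappa,
    mean_individual_kappa = mean(perf$kappa),
    expert_pairwise_kappa_mean = pk$mean,
    crowd_auc = as.numeric(crowd_auc),
    n_masked_squares = nrow(expert_cons$mask),
    n_unmasked_squares = nrow(refm)
  )
  jsonlite::write_json(summary_list, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("metrics: consensus kappa ", round(cons_kappa, 3),
      ", expert pairwise mean ", round(pk$mean, 3))

  # --- curves --------------------------------------------------------------
  auc_curve <- bootstrap_group_auc(
    crowd$annotations, expert_cons$reference, expert_cons$mask,
    sizes = config$sizes, n_boot = config$n_boot_auc,
    seed = child_seed(config$seed, 107L), level = config$ci_level)
  readr::write_csv(auc_curve, path("auc_curve.csv"))
  sp_curve <- bootstrap_spearman(
    ihc_crowd$ratings, ihc_ref, sizes = config$spearman_sizes,
    n_boot = config$n_boot_spearman,
    seed = child_seed(config$seed, 108L), level = config$ci_level)
  readr::write_csv(sp_curve, path("spearman_curve.csv"))
  sp_full <- spearman_vs_experts(ihc_crowd$ratings, ihc_ref,
                                 n_boot = config$n_boot_spearman,
                                 seed = child_seed(config$seed, 109L),
                                 level = config$ci_level)
  jsonlite::write_json(sp_full, path("spearman_full.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("curves: AUC over ", length(config$sizes), " sizes, Spearman over ",
      length(config$spearman_sizes), " sizes (full-population r ",
      round(sp_full$r, 3), ")")

  # --- factorial -----------------------------------------------------------
  glm_results <- NULL
  if (isTRUE(config$run_factorial)) {
    cells <- simulate_factorial_study(truth, n_per_cell = config$n_per_cell,
                                      seed = child_seed(config$seed, 110L))
    records <- build_factorial_records(cells[c("none", "annotated",
                                               "feedback", "both")],
                                       expert_cons$reference,
                                       expert_cons$mask)
    readr::write_csv(records, path("factorial_records.csv"))
    glm_results <- fit_factorial_all(records)
    readr::write_csv(glm_results, path("glm_results.csv"))
    say("factorial: ", nrow(records), " raters across 4 cells")
  }

  meta <- config
  class(meta) <- NULL
  jsonlite::write_json(list(config = meta,
                            n_masked_squares = nrow(expert_cons$mask)),
                       path("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(truth = truth, crowd = crowd, experts = experts,
                 expert_consensus = expert_cons, square_scores = scores,
                 rater_performance = perf, summary = summary_list,
                 auc_curve = auc_curve, ihc_truth = ihc_truth,
                 ihc_crowd = ihc_crowd, ihc_reference = ihc_ref,
                 image_hscores = hscores, spearman_curve = sp_curve,
                 spearman_full = sp_full, glm_results = glm_results))
}
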