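#' Build per-rater records for the 2x2 factorial analysis
#'
#' Takes the four disjoint rater cells of the factorial design crossing
#' annotated example images with feedback-based training, computes each
#' rater's performance against the expert reference over the unmasked
#' squares, and attaches the cell indicators.
#'
#' @param cells Named list of four detection tibbles with names `none`
#'   (neither factor), `annotated` (annotated images only), `feedback`
#'   (feedback training only) and `both`. Rater ids must be disjoint across
#'   cells (no participant takes part twice).
#' @param reference Binary reference grid.
#' @param mask Optional no-tissue mask.
#' @return Tibble `rater_id, annotated_images, feedback_training,
#'   sensitivity, specificity, f1` (indicators 0/1).
#' @export
build_factorial_records <- function(cells, reference, mask = NULL) {
  design <- tibble::tibble(
    cell = c("none", "annotated", "feedback", "both"),
    annotated_images = c(0L, 1L, 0L, 1L),
    feedback_training = c(0L, 0L, 1L, 1L)
  )
  missing_cells <- setdiff(design$cell, names(cells))
  if (length(missing_cells) > 0) {
    stop("missing factorial cell(s): ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  }
  ids <- unlist(lapply(design$cell, function(cl) unique(cells[[cl]]$rater_id)))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("rater '", dup[1], "' appears in more than one factorial cell",
         call. = FALSE)
  }
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    perf <- rater_performance(cells[[design$cell[i]]], reference, mask)
    out[[i]] <- tibble::tibble(
      rater_id = perf$rater_id,
      annotated_images = design$annotated_images[i],
      feedback_training = design$feedback_training[i],
      sensitivity = perf$sensitivity,
      specificity = perf$specificity,
      f1 = perf$f1
    )
  }
  dplyr::bind_rows(out)
}

#' Fit the 2x2 factorial linear model for one outcome
#'
#' Ordinary least squares of the outcome on the two tutorial indicators and
#' their interaction, with treatment (0/1) coding: the intercept is the
#' double-control mean and each coefficient is the estimated change in
#' performance when adding the factor. Coefficients and Wald 95% confidence
#' bounds are reported multiplied by 100 (percentage points); two-sided
#' p-values come from the t distribution. P-values are uncorrected for
#' multiple comparisons by default; `bonferroni = TRUE` multiplies the
#' three effect p-values by 3 (capped at 1).
#'
#' @param records Tibble from [build_factorial_records()].
#' @param outcome One of `"f1"`, `"sensitivity"`, `"specificity"`.
#' @param conf_level Confidence level for the coefficient intervals.
#' @param bonferroni Apply a Bonferroni correction to the effect p-values.
#' @return Tibble `term, estimate, ci_low, ci_high, p_value, outcome` with
#'   terms `intercept`, `annotated_images`, `feedback_training`,
#'   `interaction`; `estimate`, `ci_low`, `ci_high` are x100.
#' @export
fit_factorial_glm <- function(records, outcome = c("f1", "sensitivity",
                                                   "specificity"),
                              conf_level = 0.95, bonferroni = FALSE) {
  outcome <- match.arg(outcome)
  needed <- c("annotated_images", "feedback_training", outcome)
  stopifnot(all(needed %in% names(records)))
  cell_counts <- dplyr::count(records, .data$annotated_images,
                              .data$feedback_training)
  full <- tidyr::expand_grid(annotated_images = 0:1, feedback_training = 0:1)
  empty <- dplyr::anti_join(full, cell_counts,
                            by = c("annotated_images", "feedback_training"))
  if (nrow(empty) > 0) {
    stop("empty design cell (annotated_images = ", empty$annotated_images[1],
         ", feedback_training = ", empty$feedback_training[1],
         "): interaction is inestimable", call. = FALSE)
  }
  d <- data.frame(y = records[[outcome]],
                  annotated_images = records$annotated_images,
                  feedback_training = records$feedback_training)
  if (anyNA(d$y)) {
    stop("outcome '", outcome, "' is undefined for ", sum(is.na(d$y)),
         " rater(s); resolve before fitting", call. = FALSE)
  }
  fit <- stats::lm(y ~ annotated_images * feedback_training, data = d)
  est <- stats::coef(fit) * 100
  ci <- suppressWarnings(stats::confint(fit, level = conf_level) * 100)
  p <- suppressWarnings(summary(fit))$coefficients[, "Pr(>|t|)"]
  term_map <- c("(Intercept)" = "intercept",
                "annotated_images" = "annotated_images",
                "feedback_training" = "feedback_training",
                "annotated_images:feedback_training" = "interaction")
  terms <- term_map[names(est)]
  if (bonferroni) {
    eff <- terms != "intercept"
    p[eff] <- pmin(1, p[eff] * sum(eff))
  }
  tibble::tibble(term = unname(terms), estimate = unname(est),
                 ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                 p_value = unname(p), outcome = outcome)
}

#' Fit the factorial model for all three outcomes
#'
#' Convenience wrapper fitting [fit_factorial_glm()] separately for F1,
#' specificity and sensitivity, returning one stacked table shaped like a
#' factor-by-outcome grid.
#'
#' @inheritParams fit_factorial_glm
#' @return Tibble of the three per-outcome fits stacked.
#' @export
fit_factorial_all <- function(records, conf_level = 0.95, bonferroni = FALSE) {
  dplyr::bind_rows(lapply(c("f1", "specificity", "sensitivity"),
                          function(o) fit_factorial_glm(records, o,
                                                        conf_level = conf_level,
                                                        bonferroni = bonferroni)))
}
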