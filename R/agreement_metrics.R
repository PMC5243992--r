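#' Confusion counts of a binary rating against a reference
#'
#' Tallies true/false positives and negatives over the unmasked squares
#' shared by a rating grid and a reference grid. Both inputs are per-square
#' tibbles with columns `image_id, row, col, positive` (logical); masked
#' squares contribute to no count.
#'
#' @param rating,reference Binary grids covering the same squares.
#' @param mask Optional tibble `image_id, row, col` of excluded squares.
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(rating, reference, mask = NULL) {
  rating <- apply_mask(rating, mask)
  reference <- apply_mask(reference, mask)
  j <- dplyr::inner_join(rating, reference, by = c("image_id", "row", "col"),
                         suffix = c("_rating", "_reference"))
  if (nrow(j) != nrow(rating) || nrow(j) != nrow(reference)) {
    stop("rating and reference do not cover the same set of squares",
         call. = FALSE)
  }
  a <- j$positive_rating
  b <- j$positive_reference
  structure(list(tp = sum(a & b), tn = sum(!a & !b),
                 fp = sum(a & !b), fn = sum(!a & b)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, TN %d, FP %d, FN %d (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Sensitivity, specificity and F1 from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1-score
#' `2*TP/(2*TP+FP+FN)`. A statistic whose denominator is zero is reported as
#' undefined (`NA`) with a reason, never silently as 0.
#'
#' @param counts A [confusion_counts()] object (or list with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return An object of class `performance_summary`: list with
#'   `sensitivity`, `specificity`, `f1`, `counts` and `undefined` (named
#'   character vector of reasons for any `NA` statistic).
#' @export
performance <- function(counts) {
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  undefined <- character(0)
  sens <- if (counts$tp + counts$fn > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else {
    undefined["sensitivity"] <- "no reference-positive squares (TP + FN = 0)"
    NA_real_
  }
  spec <- if (counts$tn + counts$fp > 0) {
    counts$tn / (counts$tn + counts$fp)
  } else {
    undefined["specificity"] <- "no reference-negative squares (TN + FP = 0)"
    NA_real_
  }
  f1_den <- 2 * counts$tp + counts$fp + counts$fn
  f1 <- if (f1_den > 0) {
    2 * counts$tp / f1_den
  } else {
    undefined["f1"] <- "no positive squares in rating or reference (2TP + FP + FN = 0)"
    NA_real_
  }
  structure(list(sensitivity = sens, specificity = spec, f1 = f1,
                 counts = counts, undefined = undefined),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("<performance_summary> sensitivity %s, specificity %s, F1 %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$f1)))
  invisible(x)
}

#' Cohen's kappa for two binary ratings
#'
#' Unweighted, two-category kappa: `(p_o - p_e) / (1 - p_e)` where `p_o` is
#' the observed agreement and `p_e` the chance agreement from the marginal
#' rates. When both raters are constant on the same category (`p_e == 1`,
#' which forces `p_o == 1`) kappa is 1 by convention.
#'
#' @param a,b Logical vectors of equal length (paired over the same
#'   unmasked squares).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("ratings have different lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  if (length(a) == 0L || anyNA(a) || anyNA(b)) {
    stop("ratings must be non-empty with no missing values", call. = FALSE)
  }
  po <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe == 1) {
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Pairwise kappa between experts
#'
#' Computes Cohen's kappa for every unordered pair of experts on their
#' binarized labels over the unmasked squares, and the arithmetic mean of
#' those pairwise values.
#'
#' @param expert_annotations Detection tibble with at least two raters.
#' @param mask Optional no-tissue mask.
#' @return A list with `pairs` (tibble `rater_a, rater_b, kappa`) and
#'   `mean` (the average pairwise kappa).
#' @export
expert_pairwise_kappa <- function(expert_annotations, mask = NULL) {
  raters <- sort(unique(expert_annotations$rater_id))
  if (length(raters) < 2) {
    stop("pairwise kappa needs at least 2 experts", call. = FALSE)
  }
  grids <- lapply(raters, function(r) {
    g <- binary_grid(expert_annotations[expert_annotations$rater_id == r, ])
    g <- apply_mask(g, mask)
    dplyr::arrange(g, .data$image_id, .data$row, .data$col)
  })
  names(grids) <- raters
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    ga <- grids[[p[1]]]
    gb <- grids[[p[2]]]
    if (nrow(ga) != nrow(gb) ||
        !all(ga$image_id == gb$image_id & ga$row == gb$row & ga$col == gb$col)) {
      stop("experts '", p[1], "' and '", p[2],
           "' do not cover the same squares", call. = FALSE)
    }
    tibble::tibble(rater_a = p[1], rater_b = p[2],
                   kappa = cohens_kappa(ga$positive, gb$positive))
  })
  pairs_tbl <- dplyr::bind_rows(res)
  list(pairs = pairs_tbl, mean = mean(pairs_tbl$kappa))
}

#' Per-rater performance against a reference
#'
#' For each rater in a detection table: confusion counts, sensitivity,
#' specificity, F1 and Cohen's kappa against the reference grid, over the
#' unmasked squares.
#'
#' @param annotations Detection tibble (one or more raters).
#' @param reference Binary reference grid (`image_id, row, col, positive`).
#' @param mask Optional no-tissue mask.
#' @return Tibble with one row per rater.
#' @export
rater_performance <- function(annotations, reference, mask = NULL) {
  ref <- dplyr::arrange(apply_mask(reference, mask),
                        .data$image_id, .data$row, .data$col)
  raters <- unique(annotations[, c("rater_id", "rater_type")])
  out <- vector("list", nrow(raters))
  for (i in seq_len(nrow(raters))) {
    g <- binary_grid(annotations[annotations$rater_id == raters$rater_id[i], ])
    g <- dplyr::arrange(apply_mask(g, mask),
                        .data$image_id, .data$row, .data$col)
    cc <- confusion_counts(g, ref)
    perf <- performance(cc)
    out[[i]] <- tibble::tibble(
      rater_id = raters$rater_id[i], rater_type = raters$rater_type[i],
      tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
      sensitivity = perf$sensitivity, specificity = perf$specificity,
      f1 = perf$f1, kappa = cohens_kappa(g$positive, ref$positive))
  }
  dplyr::bind_rows(out)
}

#' ROC AUC from per-square scores
#'
#' The area under the ROC curve equals the Mann-Whitney probability that a
#' randomly chosen reference-positive square scores higher than a randomly
#' chosen reference-negative square, with half credit for ties. Computed in
#' rank form. The natural score for a crowd is the per-square vote fraction.
#'
#' @param scores Numeric scores, one per unmasked square.
#' @param positive Logical reference, aligned with `scores`.
#' @return The AUC in `[0, 1]`, or `NA` with a `"reason"` attribute when the
#'   reference contains a single class.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive)) {
    stop("scores and reference have different lengths", call. = FALSE)
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "reference contains a single class"
    return(out)
  }
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), as used to
#' compare aggregate crowd H-scores with the expert reference per image.
#'
#' @param x,y Paired numeric vectors of length >= 3.
#' @return Spearman's r, or `NA` with a `"reason"` attribute when either
#'   vector is constant.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y have different lengths", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("spearman_r() needs at least 3 paired values", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("x and y must not contain missing values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant vector"
    return(out)
  }
  stats::cor(x, y, method = "spearman")
}
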