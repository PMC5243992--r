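#' Binarize a three-way square label
#'
#' Detection analysis treats each square rating as binary: `cancer` is
#' positive; `no_cancer` and `no_tissue` (blank) are both negative, since a
#' blank is equivalent to "no cancer seen here".
#'
#' @param label Character vector of labels in
#'   `{cancer, no_cancer, no_tissue}`.
#' @return Logical vector, `TRUE` for cancer-positive.
#' @export
binarize_label <- function(label) {
  bad <- !(label %in% SQUARE_LABELS)
  if (any(bad)) {
    stop("unknown label '", label[which(bad)[1]], "'", call. = FALSE)
  }
  label == "cancer"
}

# Per-rater binary grid from a detection annotation table.
binary_grid <- function(annotations) {
  tibble::tibble(image_id = annotations$image_id, row = annotations$row,
                 col = annotations$col,
                 positive = binarize_label(annotations$label))
}

#' Majority-vote consensus per grid square
#'
#' Aggregates all raters' binarized labels per square. A square's consensus
#' is positive iff strictly more than half of the votes are positive; exact
#' ties resolve negative (the conservative rule: lay crowds tend to
#' over-call cancer, so ties are not promoted to positives).
#'
#' @param annotations Detection tibble covering one or more images; every
#'   rater present is counted on every square it labelled.
#' @param tie `"negative"` (default) or `"positive"`: how a vote fraction of
#'   exactly 0.5 is resolved.
#' @return Tibble with one row per square: `image_id, row, col,
#'   positive_votes, total_votes, vote_fraction, consensus` (logical).
#' @export
majority_consensus <- function(annotations, tie = c("negative", "positive")) {
  tie <- match.arg(tie)
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop("majority_consensus() needs at least one annotation", call. = FALSE)
  }
  out <- annotations |>
    dplyr::group_by(.data$image_id, .data$row, .data$col) |>
    dplyr::summarise(positive_votes = sum(binarize_label(.data$label)),
                     total_votes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(vote_fraction = .data$positive_votes / .data$total_votes,
                  consensus = .data$vote_fraction > 0.5 |
                    (tie == "positive" & .data$vote_fraction == 0.5)) |>
    dplyr::arrange(.data$image_id, .data$row, .data$col)
  out
}

#' Expert consensus reference and no-tissue mask
#'
#' The reference grid is the majority vote over the binarized expert labels
#' (ties negative). The no-tissue mask collects squares that contained no
#' tissue whatsoever and are excluded from all detection metrics; by default
#' a square is masked only when *every* expert labelled it `no_tissue`
#' (`mask_rule = "unanimous"`); `"majority"` masks squares where more than
#' half did.
#'
#' @param expert_annotations Detection tibble of the expert panel; every
#'   expert must cover every image.
#' @param mask_rule `"unanimous"` (default) or `"majority"`.
#' @return A list with `reference` (tibble `image_id, row, col, positive`),
#'   `mask` (tibble `image_id, row, col`) and `mask_rule`.
#' @export
expert_detection_consensus <- function(expert_annotations,
                                       mask_rule = c("unanimous", "majority")) {
  mask_rule <- match.arg(mask_rule)
  if (is.null(expert_annotations) || nrow(expert_annotations) == 0L) {
    stop("expert_detection_consensus() needs at least one expert annotation",
         call. = FALSE)
  }
  n_experts <- dplyr::n_distinct(expert_annotations$rater_id)
  cover <- expert_annotations |>
    dplyr::distinct(.data$image_id, .data$rater_id) |>
    dplyr::count(.data$image_id)
  if (any(cover$n != n_experts)) {
    bad <- cover$image_id[cover$n != n_experts][1]
    stop("image '", bad, "' is not covered by all ", n_experts, " experts",
         call. = FALSE)
  }
  sq <- expert_annotations |>
    dplyr::group_by(.data$image_id, .data$row, .data$col) |>
    dplyr::summarise(positive_votes = sum(.data$label == "cancer"),
                     no_tissue_votes = sum(.data$label == "no_tissue"),
                     total_votes = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$image_id, .data$row, .data$col)
  reference <- dplyr::transmute(
    sq, .data$image_id, .data$row, .data$col,
    positive = .data$positive_votes / .data$total_votes > 0.5)
  masked <- if (mask_rule == "unanimous") {
    sq$no_tissue_votes == sq$total_votes
  } else {
    sq$no_tissue_votes / sq$total_votes > 0.5
  }
  mask <- dplyr::select(sq[masked, ], "image_id", "row", "col")
  list(reference = reference, mask = mask, mask_rule = mask_rule)
}

#' Expert consensus IHC score per image
#'
#' The reference proportion is the median of the expert proportions; the
#' reference intensity is the median intensity over experts who reported a
#' positive proportion (absent when the median proportion is 0); the
#' reference H-score is the product of the two medians. Even-count medians
#' are the midpoint of the two central values and may be non-integer;
#' downstream treats them as real-valued.
#'
#' @param expert_ratings IHC rating tibble of the expert panel.
#' @return Tibble with one row per image: `image_id, proportion, intensity,
#'   h_score` (numeric).
#' @export
expert_ihc_consensus <- function(expert_ratings) {
  if (is.null(expert_ratings) || nrow(expert_ratings) == 0L) {
    stop("expert_ihc_consensus() needs at least one expert rating",
         call. = FALSE)
  }
  expert_ratings |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      med_prop = stats::median(.data$proportion),
      med_int = {
        pos <- .data$proportion > 0
        if (any(pos)) stats::median(.data$intensity[pos]) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::transmute(
      .data$image_id,
      proportion = .data$med_prop,
      intensity = ifelse(.data$med_prop > 0, .data$med_int, NA_real_),
      h_score = ifelse(.data$med_prop == 0, 0, .data$med_prop * .data$med_int)
    ) |>
    dplyr::arrange(.data$image_id)
}

#' Aggregate crowd H-score per image
#'
#' The aggregate H-score of an image is the median over the H-scores of all
#' raters who scored it, with a bootstrapped percentile confidence interval
#' of the median (raters resampled with replacement within the image).
#'
#' @param ratings IHC rating tibble (lay raters).
#' @param n_boot Bootstrap resamples per image (default 10000).
#' @param level Confidence level in percent (default 95).
#' @param seed Integer seed.
#' @return Tibble `image_id, n_raters, h_score, ci_low, ci_high`.
#' @export
aggregate_h_score <- function(ratings, n_boot = 10000, level = 95, seed = 1) {
  if (is.null(ratings) || nrow(ratings) == 0L) {
    stop("aggregate_h_score() needs at least one rating", call. = FALSE)
  }
  images <- sort(unique(ratings$image_id))
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    v <- ratings$h_score[ratings$image_id == images[i]]
    med <- stats::median(v)
    if (length(unique(v)) == 1L) {
      ci <- c(v[1], v[1])
    } else {
      set.seed(child_seed(seed, 8L, i))
      boots <- vapply(seq_len(n_boot), function(b) {
        stats::median(v[sample.int(length(v), length(v), replace = TRUE)])
      }, numeric(1))
      ci <- percentile_ci(boots, level = level)
    }
    out[[i]] <- tibble::tibble(image_id = images[i], n_raters = length(v),
                               h_score = med, ci_low = ci[1], ci_high = ci[2])
  }
  dplyr::bind_rows(out)
}
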