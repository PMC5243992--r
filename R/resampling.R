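#' Percentile bootstrap confidence interval
#'
#' Empirical percentiles at `(100 - level)/2` and `100 - (100 - level)/2`
#' with linear interpolation (quantile type 7). `level = 100` returns the
#' sample range.
#'
#' @param samples Numeric vector of bootstrap statistics (length >= 1).
#' @param level Confidence level in percent, in `(0, 100]`.
#' @return Numeric vector `c(low, high)`.
#' @export
percentile_ci <- function(samples, level = 95) {
  if (length(samples) == 0L) {
    stop("percentile_ci() needs at least one sample", call. = FALSE)
  }
  if (!is.finite(level) || level <= 0 || level > 100) {
    stop("level must lie in (0, 100]", call. = FALSE)
  }
  alpha <- (100 - level) / 200
  unname(stats::quantile(samples, probs = c(alpha, 1 - alpha), names = FALSE,
                         type = 7))
}

# Squares x raters matrix of binary cancer votes, aligned with the unmasked
# reference. Every rater must cover every unmasked reference square.
vote_matrix <- function(annotations, reference, mask = NULL) {
  ref <- dplyr::arrange(apply_mask(reference, mask),
                        .data$image_id, .data$row, .data$col)
  key <- paste(ref$image_id, ref$row, ref$col, sep = "\r")
  raters <- sort(unique(annotations$rater_id))
  ann <- apply_mask(annotations, mask)
  ri <- match(paste(ann$image_id, ann$row, ann$col, sep = "\r"), key)
  ci <- match(ann$rater_id, raters)
  keep <- !is.na(ri)
  V <- matrix(NA_integer_, nrow = length(key), ncol = length(raters),
              dimnames = list(NULL, raters))
  V[cbind(ri[keep], ci[keep])] <- as.integer(ann$label[keep] == "cancer")
  if (anyNA(V)) {
    miss <- which(is.na(V), arr.ind = TRUE)[1, ]
    stop("rater '", raters[miss[2]], "' does not cover reference square ",
         key[miss[1]], call. = FALSE)
  }
  list(votes = V, positive = ref$positive)
}

#' Bootstrap AUC as a function of crowd size
#'
#' For each group size `n`, draws `n` rater ids from the population with
#' replacement (`n_boot` times; duplicated raters contribute duplicate
#' votes), forms the per-square vote fraction of the drawn multiset,
#' computes the ROC AUC against the reference, and summarises resamples by
#' their mean and a percentile confidence interval. A resample whose AUC is
#' undefined is redrawn, with a counter reported.
#'
#' @param annotations Lay detection tibble; every rater must cover every
#'   unmasked reference square.
#' @param reference Binary reference grid.
#' @param mask Optional no-tissue mask.
#' @param sizes Group sizes (default 3 to 40).
#' @param n_boot Resamples per size (default 500).
#' @param seed Integer seed; each size uses an independent child seed.
#' @param level Confidence level in percent.
#' @param max_redraws Safety cap on redraws per size.
#' @return Tibble `size, point, ci_low, ci_high, n_redrawn` with attributes
#'   `statistic = "auc"`, `n_boot`, `seed` and `level`. `point` is the mean
#'   AUC over resamples.
#' @export
bootstrap_group_auc <- function(annotations, reference, mask = NULL,
                                sizes = 3:40, n_boot = 500, seed = 1,
                                level = 95, max_redraws = 1000) {
  stopifnot(all(sizes >= 1), n_boot >= 1)
  vm <- vote_matrix(annotations, reference, mask)
  if (all(vm$positive) || !any(vm$positive)) {
    stop("reference contains a single class over the unmasked squares; ",
         "AUC is undefined", call. = FALSE)
  }
  n_raters <- ncol(vm$votes)
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    set.seed(child_seed(seed, 10L, si))
    vals <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n_raters, n, replace = TRUE)
        frac <- rowMeans(vm$votes[, idx, drop = FALSE])
        a <- roc_auc(frac, vm$positive)
        if (!is.na(a)) break
        redrawn <- redrawn + 1L
        if (redrawn > max_redraws) {
          stop("more than ", max_redraws, " undefined-AUC redraws at size ",
               n, call. = FALSE)
        }
      }
      vals[b] <- a
    }
    ci <- percentile_ci(vals, level = level)
    rows[[si]] <- tibble::tibble(size = n, point = mean(vals),
                                 ci_low = ci[1], ci_high = ci[2],
                                 n_redrawn = redrawn)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "statistic") <- "auc"
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  out
}

# Images x raters matrix of H-scores (NA where a rater did not score an
# image), aligned with the per-image reference H-scores.
hscore_matrix <- function(ratings, reference) {
  stopifnot(all(c("image_id", "h_score") %in% names(reference)))
  images <- reference$image_id
  raters <- sort(unique(ratings$rater_id))
  H <- matrix(NA_real_, nrow = length(images), ncol = length(raters),
              dimnames = list(images, raters))
  ri <- match(ratings$image_id, images)
  ci <- match(ratings$rater_id, raters)
  keep <- !is.na(ri)
  H[cbind(ri[keep], ci[keep])] <- ratings$h_score[keep]
  rated <- rowSums(!is.na(H)) > 0
  if (!all(rated)) {
    warning(sum(!rated), " reference image(s) have no ratings and are ",
            "excluded from the correlation", call. = FALSE)
    H <- H[rated, , drop = FALSE]
  }
  list(h = H, reference = reference$h_score[rated])
}

#' Bootstrap Spearman correlation as a function of crowd size
#'
#' For each group size `n` and each resample: draw `n` raters with
#' replacement, take per image the median H-score over the drawn raters who
#' scored it (images with no drawn rater are dropped from that resample's
#' correlation), and compute Spearman's r against the reference H-scores.
#' Resamples covering fewer than 3 images, or with a constant aggregate, are
#' redrawn with a counter. The per-size point estimate is the median over
#' resamples, with a percentile confidence interval.
#'
#' @param ratings Lay IHC rating tibble.
#' @param reference Per-image reference, tibble `image_id, h_score` (e.g.
#'   from [expert_ihc_consensus()]).
#' @param sizes Group sizes.
#' @param n_boot Resamples per size (default 10000).
#' @param seed Integer seed; each size uses an independent child seed.
#' @param level Confidence level in percent.
#' @param max_redraws Safety cap on redraws per size.
#' @return Tibble `size, point, ci_low, ci_high, n_redrawn` with attributes
#'   `statistic = "spearman_r"`, `n_boot`, `seed` and `level`.
#' @export
bootstrap_spearman <- function(ratings, reference, sizes, n_boot = 10000,
                               seed = 1, level = 95, max_redraws = 10000) {
  stopifnot(all(sizes >= 1), n_boot >= 1)
  hm <- hscore_matrix(ratings, reference)
  n_raters <- ncol(hm$h)
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    set.seed(child_seed(seed, 11L, si))
    vals <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n_raters, n, replace = TRUE)
        med <- apply(hm$h[, idx, drop = FALSE], 1, stats::median, na.rm = TRUE)
        keep <- !is.na(med)
        r <- NA_real_
        if (sum(keep) >= 3) {
          r <- spearman_r(med[keep], hm$reference[keep])
        }
        if (!is.na(r)) break
        redrawn <- redrawn + 1L
        if (redrawn > max_redraws) {
          stop("more than ", max_redraws, " degenerate-resample redraws at ",
               "size ", n, call. = FALSE)
        }
      }
      vals[b] <- r
    }
    ci <- percentile_ci(vals, level = level)
    rows[[si]] <- tibble::tibble(size = n, point = stats::median(vals),
                                 ci_low = ci[1], ci_high = ci[2],
                                 n_redrawn = redrawn)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "statistic") <- "spearman_r"
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  out
}

#' Full-population Spearman correlation with bootstrap CI
#'
#' The observed Spearman correlation between the aggregate (median) crowd
#' H-score and the reference H-score per image, with a percentile bootstrap
#' confidence interval from resampling the full rater population with
#' replacement.
#'
#' @inheritParams bootstrap_spearman
#' @return A list with `r` (observed correlation), `ci_low`, `ci_high`,
#'   `n_raters`, `n_images`, `n_boot` and `n_redrawn`.
#' @export
spearman_vs_experts <- function(ratings, reference, n_boot = 10000, seed = 1,
                                level = 95) {
  hm <- hscore_matrix(ratings, reference)
  med <- apply(hm$h, 1, stats::median, na.rm = TRUE)
  observed <- spearman_r(med, hm$reference)
  curve <- bootstrap_spearman(ratings, reference, sizes = ncol(hm$h),
                              n_boot = n_boot, seed = seed, level = level)
  list(r = as.numeric(observed), ci_low = curve$ci_low[1],
       ci_high = curve$ci_high[1], n_raters = ncol(hm$h),
       n_images = nrow(hm$h), n_boot = n_boot,
       n_redrawn = curve$n_redrawn[1])
}
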