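# Shared fixtures and independent oracles for the test suite.

# Detection tibble for one image from a named list of per-rater label
# vectors (row-major over a rows x cols grid).
make_detection <- function(labels_by_rater, image_id = "img001",
                           rows = 2, cols = 2, rater_type = "lay") {
  stopifnot(all(vapply(labels_by_rater, length, 1L) == rows * cols))
  dplyr::bind_rows(lapply(names(labels_by_rater), function(r) {
    tibble::tibble(
      image_id = image_id, rater_id = r, rater_type = rater_type,
      row = rep(0:(rows - 1), each = cols), col = rep(0:(cols - 1), rows),
      label = labels_by_rater[[r]]
    )
  }))
}

# Hand-built ground truth with controlled grid labels and IHC values.
make_truth <- function(labels, n_images = 1, rows = 2, cols = 2,
                       proportion = 50L, intensity = 2L) {
  image_id <- sprintf("img%03d", seq_len(n_images))
  grid <- tidyr::expand_grid(image_id = image_id,
                             row = 0:(rows - 1), col = 0:(cols - 1))
  grid$label <- rep_len(labels, nrow(grid))
  proportion <- as.integer(rep_len(proportion, n_images))
  intensity <- as.integer(rep_len(intensity, n_images))
  intensity[proportion == 0L] <- NA_integer_
  ihc <- tibble::tibble(image_id = image_id, proportion = proportion,
                        intensity = intensity,
                        h_score = derive_h_score(proportion, intensity))
  structure(list(grid = grid, ihc = ihc,
                 params = list(n_images = n_images, rows = rows, cols = cols,
                               p_cancer = NA, p_no_tissue = NA, seed = NA)),
            class = "tma_truth")
}

noiseless_profile <- function() {
  rater_profile(1, 1, 1, proportion_sd = 0, intensity_confusion = diag(3))
}

# Independent AUC oracle: exhaustive positive-negative pair enumeration
# with half credit for ties.
auc_brute <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Independent kappa oracle: direct observed/chance agreement tally from the
# 2x2 table.
kappa_tally <- function(a, b) {
  n <- length(a)
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Independent Spearman oracle: mid-rank then Pearson.
spearman_brute <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact binomial 99% acceptance interval for an observed count.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
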