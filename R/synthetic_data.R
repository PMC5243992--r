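#' Construct a rater profile
#'
#' A rater profile holds the generative parameters of one synthetic rater:
#' detection error rates and IHC scoring noise.
#'
#' @param sensitivity Probability of marking CANCER given the square truly
#'   contains cancer.
#' @param specificity Probability of marking NO_CANCER given the square is
#'   truly cancer-free tissue.
#' @param tissue_recognition Probability of marking NO_TISSUE given the
#'   square is truly empty; misrecognition splits uniformly between the two
#'   tissue labels.
#' @param proportion_sd Standard deviation (percentage points) of the
#'   Gaussian noise on the reported IHC proportion before rounding to the
#'   nearest multiple of 5 and clipping to `[0, 100]`.
#' @param intensity_confusion 3x3 row-stochastic matrix; row `i` is the
#'   distribution of the reported intensity given true intensity `i`.
#' @return An object of class `rater_profile`.
#' @export
rater_profile <- function(sensitivity, specificity, tissue_recognition,
                          proportion_sd = 0, intensity_confusion = diag(3)) {
  probs <- c(sensitivity = sensitivity, specificity = specificity,
             tissue_recognition = tissue_recognition)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("sensitivity, specificity and tissue_recognition must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.finite(proportion_sd) || proportion_sd < 0) {
    stop("proportion_sd must be non-negative", call. = FALSE)
  }
  m <- as.matrix(intensity_confusion)
  if (!all(dim(m) == c(3, 3)) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("intensity_confusion must be a 3x3 row-stochastic matrix", call. = FALSE)
  }
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         tissue_recognition = tissue_recognition,
         proportion_sd = proportion_sd, intensity_confusion = m),
    class = "rater_profile"
  )
}

#' @export
print.rater_profile <- function(x, ...) {
  cat(sprintf(
    "<rater_profile> sens %.3f, spec %.3f, tissue %.3f, prop sd %.1f\n",
    x$sensitivity, x$specificity, x$tissue_recognition, x$proportion_sd))
  invisible(x)
}

# Beta shape parameters from a mean and standard deviation.
beta_shapes <- function(mean, sd) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("sd too large for a Beta distribution with mean ", mean, call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Default intensity confusion matrix for lay raters
#'
#' Rows (true intensity 1..3) to columns (reported 1..3). Adjacent grades are
#' confused far more often than opposite ones, reflecting that weak/moderate
#' and moderate/strong boundaries are the hard calls.
#' @return A 3x3 row-stochastic matrix.
#' @export
default_intensity_confusion <- function() {
  matrix(c(0.80, 0.18, 0.02,
           0.10, 0.80, 0.10,
           0.02, 0.18, 0.80), nrow = 3, byrow = TRUE)
}

#' Profile samplers for lay and expert populations
#'
#' `lay_profile_sampler()` returns a closure drawing heterogeneous lay-rater
#' profiles: sensitivity and specificity are Beta-distributed with the stated
#' means and standard deviations (defaults centred on the observed lay rates
#' of 0.74 and 0.66). `constant_profile_sampler()` wraps a fixed profile.
#'
#' @param mean_sensitivity,mean_specificity Population means.
#' @param sd_sensitivity,sd_specificity Population standard deviations.
#' @param tissue_recognition,proportion_sd,intensity_confusion Passed through
#'   to every drawn [rater_profile()].
#' @return A function of no arguments returning a `rater_profile`, drawing
#'   from the current RNG stream.
#' @export
lay_profile_sampler <- function(mean_sensitivity = 0.74,
                                mean_specificity = 0.66,
                                sd_sensitivity = 0.14,
                                sd_specificity = 0.14,
                                tissue_recognition = 0.85,
                                proportion_sd = 10,
                                intensity_confusion = default_intensity_confusion()) {
  se <- beta_shapes(mean_sensitivity, sd_sensitivity)
  sp <- beta_shapes(mean_specificity, sd_specificity)
  function() {
    rater_profile(
      sensitivity = stats::rbeta(1, se[1], se[2]),
      specificity = stats::rbeta(1, sp[1], sp[2]),
      tissue_recognition = tissue_recognition,
      proportion_sd = proportion_sd,
      intensity_confusion = intensity_confusion
    )
  }
}

#' @rdname lay_profile_sampler
#' @param profile A fixed [rater_profile()] returned on every draw.
#' @export
constant_profile_sampler <- function(profile) {
  force(profile)
  function() profile
}

#' Default expert profile
#'
#' Experts are modelled as high-accuracy raters: detection rates 0.95,
#' proportion noise SD 5 percentage points, 0.90-diagonal intensity
#' confusion.
#' @return A `rater_profile`.
#' @export
default_expert_profile <- function() {
  rater_profile(
    sensitivity = 0.95, specificity = 0.95, tissue_recognition = 0.95,
    proportion_sd = 5,
    intensity_confusion = matrix(c(0.90, 0.09, 0.01,
                                   0.05, 0.90, 0.05,
                                   0.01, 0.09, 0.90), nrow = 3, byrow = TRUE)
  )
}

#' Generate per-square and per-image ground truth
#'
#' Each grid square is drawn i.i.d. over `{cancer, no_cancer, no_tissue}`
#' with the stated probabilities. Each image also receives an IHC truth
#' drawn uniformly over the 61 valid (proportion, intensity) pairs:
#' `(0, NA)` and `{5, 10, ..., 100} x {1, 2, 3}`.
#'
#' @param n_images Number of TMA images.
#' @param rows,cols Grid dimensions (default 6 x 6).
#' @param p_cancer,p_no_tissue Per-square probabilities of cancer and empty
#'   squares; their sum must not exceed 1.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return An object of class `tma_truth`: a list with `grid` (tibble
#'   `image_id, row, col, label`), `ihc` (tibble `image_id, proportion,
#'   intensity, h_score`) and `params`.
#' @export
generate_ground_truth <- function(n_images = 10, rows = 6, cols = 6,
                                  p_cancer = 0.4, p_no_tissue = 0.15,
                                  seed = 1) {
  if (n_images < 1 || rows < 1 || cols < 1) {
    stop("n_images, rows and cols must be at least 1", call. = FALSE)
  }
  probs <- c(p_cancer, p_no_tissue)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1) ||
      sum(probs) > 1) {
    stop("p_cancer and p_no_tissue must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  set.seed(seed)
  image_id <- sprintf("img%03d", seq_len(n_images))
  grid <- tidyr::expand_grid(image_id = image_id,
                             row = 0:(rows - 1), col = 0:(cols - 1))
  grid$label <- sample(SQUARE_LABELS, nrow(grid), replace = TRUE,
                       prob = c(p_cancer, 1 - p_cancer - p_no_tissue,
                                p_no_tissue))
  # IHC truth: uniform over the 61 valid (proportion, intensity) pairs.
  pair <- sample.int(61L, n_images, replace = TRUE) - 1L
  proportion <- ifelse(pair == 0L, 0L, ((pair - 1L) %/% 3L + 1L) * 5L)
  intensity <- ifelse(pair == 0L, NA_integer_, (pair - 1L) %% 3L + 1L)
  ihc <- tibble::tibble(
    image_id = image_id,
    proportion = as.integer(proportion),
    intensity = as.integer(intensity),
    h_score = derive_h_score(as.integer(proportion), as.integer(intensity))
  )
  structure(
    list(grid = grid, ihc = ihc,
         params = list(n_images = n_images, rows = rows, cols = cols,
                       p_cancer = p_cancer, p_no_tissue = p_no_tissue,
                       seed = seed)),
    class = "tma_truth"
  )
}

#' @export
print.tma_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("<tma_truth> %d images, %dx%d grid (%d squares), p_cancer %.2f, p_no_tissue %.2f\n",
              p$n_images, p$rows, p$cols, nrow(x$grid), p$p_cancer,
              p$p_no_tissue))
  invisible(x)
}

#' Simulate one rater's detection annotations
#'
#' Per square, independently: a true cancer square is marked `cancer` with
#' probability `sensitivity`, else `no_cancer`; a true tissue square without
#' cancer is marked `no_cancer` with probability `specificity`, else
#' `cancer`; a truly empty square is marked `no_tissue` with probability
#' `tissue_recognition`, else one of the two tissue labels uniformly.
#'
#' @param truth A `tma_truth` object.
#' @param profile A [rater_profile()].
#' @param seed Integer seed.
#' @param rater_id,rater_type Identifier columns for the output.
#' @return A detection tibble (one row per square).
#' @export
simulate_detection_rater <- function(truth, profile, seed,
                                     rater_id = "rater1", rater_type = "lay") {
  stopifnot(inherits(truth, "tma_truth"), inherits(profile, "rater_profile"))
  g <- truth$grid
  n <- nrow(g)
  set.seed(seed)
  u <- stats::runif(n)
  alt <- stats::runif(n)
  lab <- character(n)
  ca <- g$label == "cancer"
  nc <- g$label == "no_cancer"
  nt <- g$label == "no_tissue"
  lab[ca] <- ifelse(u[ca] < profile$sensitivity, "cancer", "no_cancer")
  lab[nc] <- ifelse(u[nc] < profile$specificity, "no_cancer", "cancer")
  lab[nt] <- ifelse(u[nt] < profile$tissue_recognition, "no_tissue",
                    ifelse(alt[nt] < 0.5, "cancer", "no_cancer"))
  tibble::tibble(image_id = g$image_id, rater_id = rater_id,
                 rater_type = rater_type, row = g$row, col = g$col,
                 label = lab)
}

#' Simulate a crowd of detection raters
#'
#' Draws `n_raters` independent profiles from `profile_sampler` and has each
#' rater annotate every image. Profile draws and annotations use per-rater
#' child seeds, so the first `k` raters of an `n > k` crowd are identical to
#' a crowd of size `k` under the same seed.
#'
#' @param truth A `tma_truth` object.
#' @param n_raters Number of raters (>= 1).
#' @param profile_sampler Function of no arguments returning a
#'   [rater_profile()] (see [lay_profile_sampler()]).
#' @param seed Integer seed.
#' @param rater_prefix Prefix for generated rater ids.
#' @param rater_type Rater type tag for the output.
#' @return A list with `annotations` (one detection tibble) and `profiles`
#'   (named list of the drawn profiles).
#' @export
simulate_crowd <- function(truth, n_raters,
                           profile_sampler = lay_profile_sampler(), seed = 1,
                           rater_prefix = "lay", rater_type = "lay") {
  stopifnot(n_raters >= 1)
  ids <- sprintf("%s%03d", rater_prefix, seq_len(n_raters))
  profiles <- vector("list", n_raters)
  ann <- vector("list", n_raters)
  for (i in seq_len(n_raters)) {
    set.seed(child_seed(seed, 1L, i))
    p <- profile_sampler()
    if (!inherits(p, "rater_profile")) {
      stop("profile_sampler must return a rater_profile", call. = FALSE)
    }
    profiles[[i]] <- p
    ann[[i]] <- simulate_detection_rater(truth, p,
                                         seed = child_seed(seed, 2L, i),
                                         rater_id = ids[i],
                                         rater_type = rater_type)
  }
  list(annotations = dplyr::bind_rows(ann),
       profiles = stats::setNames(profiles, ids))
}

#' Simulate one rater's IHC ratings
#'
#' The rater is assigned a uniform random subset of `images_per_rater`
#' images. The reported proportion is the true proportion plus Gaussian
#' noise (SD `profile$proportion_sd`), rounded to the nearest multiple of 5
#' and clipped to `[0, 100]`. When the reported proportion is positive the
#' reported intensity is drawn from the `intensity_confusion` row of the
#' true intensity (uniform over 1..3 if the true proportion was 0, so no
#' true intensity exists); a reported proportion of 0 has absent intensity.
#'
#' @param truth A `tma_truth` object.
#' @param profile A [rater_profile()].
#' @param images_per_rater Number of images this rater scores.
#' @param seed Integer seed.
#' @param rater_id,rater_type Identifier columns for the output.
#' @return An IHC rating tibble with derived `h_score`.
#' @export
simulate_ihc_rater <- function(truth, profile, images_per_rater, seed,
                               rater_id = "rater1", rater_type = "lay") {
  stopifnot(inherits(truth, "tma_truth"), inherits(profile, "rater_profile"))
  n_images <- nrow(truth$ihc)
  if (images_per_rater < 1 || images_per_rater > n_images) {
    stop("images_per_rater must be between 1 and the number of images (",
         n_images, ")", call. = FALSE)
  }
  set.seed(seed)
  pick <- sort(sample.int(n_images, images_per_rater))
  tr <- truth$ihc[pick, ]
  noise <- stats::rnorm(images_per_rater, 0, profile$proportion_sd)
  prop <- pmin(100, pmax(0, round((tr$proportion + noise) / 5) * 5))
  inten <- rep(NA_integer_, images_per_rater)
  for (j in seq_len(images_per_rater)) {
    if (prop[j] > 0) {
      if (is.na(tr$intensity[j])) {
        inten[j] <- sample.int(3L, 1L)
      } else {
        inten[j] <- sample(1:3, 1,
                           prob = profile$intensity_confusion[tr$intensity[j], ])
      }
    }
  }
  tibble::tibble(image_id = tr$image_id, rater_id = rater_id,
                 rater_type = rater_type, proportion = as.integer(prop),
                 intensity = inten,
                 h_score = derive_h_score(as.integer(prop), inten))
}

#' Simulate a crowd of IHC raters
#'
#' Draws `n_raters` profiles and gives each a random subset of
#' `images_per_rater` images, mirroring a protocol where each participant
#' scores a random set of images. Uses per-rater child seeds.
#'
#' @inheritParams simulate_crowd
#' @param images_per_rater Images assigned to each rater.
#' @return A list with `ratings` (one IHC tibble) and `profiles`.
#' @export
simulate_ihc_crowd <- function(truth, n_raters,
                               profile_sampler = lay_profile_sampler(),
                               images_per_rater = 10, seed = 1,
                               rater_prefix = "lay", rater_type = "lay") {
  stopifnot(n_raters >= 1)
  ids <- sprintf("%s%03d", rater_prefix, seq_len(n_raters))
  profiles <- vector("list", n_raters)
  ratings <- vector("list", n_raters)
  for (i in seq_len(n_raters)) {
    set.seed(child_seed(seed, 3L, i))
    p <- profile_sampler()
    profiles[[i]] <- p
    ratings[[i]] <- simulate_ihc_rater(truth, p, images_per_rater,
                                       seed = child_seed(seed, 4L, i),
                                       rater_id = ids[i],
                                       rater_type = rater_type)
  }
  list(ratings = dplyr::bind_rows(ratings),
       profiles = stats::setNames(profiles, ids))
}

#' Simulate an expert panel
#'
#' `k` high-accuracy raters annotate every image, for both the detection
#' grid and the IHC score, tagged `expert`. Panel sizes of 3 (most sample
#' types) or 5 are typical.
#'
#' @param truth A `tma_truth` object.
#' @param k Panel size (>= 1).
#' @param expert_profile Profile shared by all experts.
#' @param seed Integer seed.
#' @return A list with `detection` (tibble), `ihc` (tibble) and `profiles`.
#' @export
simulate_expert_panel <- function(truth, k = 3,
                                  expert_profile = default_expert_profile(),
                                  seed = 1) {
  stopifnot(k >= 1)
  ids <- sprintf("expert%d", seq_len(k))
  det <- vector("list", k)
  ihc <- vector("list", k)
  for (i in seq_len(k)) {
    det[[i]] <- simulate_detection_rater(truth, expert_profile,
                                         seed = child_seed(seed, 5L, i),
                                         rater_id = ids[i],
                                         rater_type = "expert")
    ihc[[i]] <- simulate_ihc_rater(truth, expert_profile,
                                   images_per_rater = nrow(truth$ihc),
                                   seed = child_seed(seed, 6L, i),
                                   rater_id = ids[i], rater_type = "expert")
  }
  list(detection = dplyr::bind_rows(det), ihc = dplyr::bind_rows(ihc),
       profiles = stats::setNames(rep(list(expert_profile), k), ids))
}

#' Simulate the 2x2 factorial tutorial study
#'
#' Four disjoint crowds, one per cell of the factorial design crossing
#' annotated example images with feedback-based training. Each cell's rater
#' population has Beta-distributed sensitivity and specificity whose means
#' are the baseline rates shifted by the corresponding main effects (and
#' interaction, default none).
#'
#' @param truth A `tma_truth` object.
#' @param n_per_cell Raters per cell.
#' @param base_sensitivity,base_specificity Mean rates of the
#'   double-control cell.
#' @param annotated_effect,feedback_effect,interaction_effect Named numeric
#'   vectors `c(sens = ..., spec = ...)` added to the cell means.
#' @param sd_sensitivity,sd_specificity Between-rater SDs within each cell.
#' @param tissue_recognition Tissue-recognition rate for all raters.
#' @param seed Integer seed.
#' @return Named list of four detection tibbles (`none`, `annotated`,
#'   `feedback`, `both`) plus a `design` tibble of the cell means.
#' @export
simulate_factorial_study <- function(truth, n_per_cell = 50,
                                     base_sensitivity = 0.74,
                                     base_specificity = 0.66,
                                     annotated_effect = c(sens = 0.0269, spec = 0.0118),
                                     feedback_effect = c(sens = 0.0877, spec = -0.0759),
                                     interaction_effect = c(sens = 0, spec = 0),
                                     sd_sensitivity = 0.10,
                                     sd_specificity = 0.10,
                                     tissue_recognition = 0.85,
                                     seed = 1) {
  cells <- tibble::tibble(
    cell = c("none", "annotated", "feedback", "both"),
    annotated_images = c(0, 1, 0, 1),
    feedback_training = c(0, 0, 1, 1)
  )
  clamp <- function(x) pmin(0.99, pmax(0.01, x))
  out <- list()
  design <- cells
  design$mean_sensitivity <- NA_real_
  design$mean_specificity <- NA_real_
  for (i in seq_len(nrow(cells))) {
    a <- cells$annotated_images[i]
    f <- cells$feedback_training[i]
    m_se <- clamp(base_sensitivity + a * annotated_effect[["sens"]] +
                    f * feedback_effect[["sens"]] +
                    a * f * interaction_effect[["sens"]])
    m_sp <- clamp(base_specificity + a * annotated_effect[["spec"]] +
                    f * feedback_effect[["spec"]] +
                    a * f * interaction_effect[["spec"]])
    design$mean_sensitivity[i] <- m_se
    design$mean_specificity[i] <- m_sp
    sampler <- lay_profile_sampler(
      mean_sensitivity = m_se, mean_specificity = m_sp,
      sd_sensitivity = sd_sensitivity, sd_specificity = sd_specificity,
      tissue_recognition = tissue_recognition
    )
    sim <- simulate_crowd(truth, n_per_cell, sampler,
                          seed = child_seed(seed, 7L, i),
                          rater_prefix = paste0(cells$cell[i], "_"))
    out[[cells$cell[i]]] <- sim$annotations
  }
  out$design <- design
  out
}
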