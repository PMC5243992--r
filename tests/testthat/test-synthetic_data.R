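test_that("ground truth has the right shape and degenerate limits", {
  truth <- generate_ground_truth(n_images = 10, seed = 1)
  expect_equal(nrow(truth$grid), 360)
  expect_equal(dplyr::n_distinct(truth$grid$image_id), 10)

  all_cancer <- generate_ground_truth(n_images = 3, p_cancer = 1,
                                      p_no_tissue = 0, seed = 2)
  expect_true(all(all_cancer$grid$label == "cancer"))
  expect_error(generate_ground_truth(p_cancer = 0.7, p_no_tissue = 0.5),
               "sum to at most 1")
})

test_that("no-tissue frequency matches the generating probability", {
  truth <- generate_ground_truth(n_images = 100, p_cancer = 0.4,
                                 p_no_tissue = 0.15, seed = 3)
  n <- nrow(truth$grid)
  bounds <- binom99(n, 0.15)
  observed <- sum(truth$grid$label == "no_tissue")
  expect_gte(observed, bounds[1])
  expect_lte(observed, bounds[2])
})

test_that("IHC truth obeys the rating invariants", {
  truth <- generate_ground_truth(n_images = 200, seed = 4)
  expect_true(all(truth$ihc$proportion %% 5 == 0))
  expect_true(all(is.na(truth$ihc$intensity) == (truth$ihc$proportion == 0)))
  expect_identical(truth$ihc$h_score,
                   derive_h_score(truth$ihc$proportion, truth$ihc$intensity))
})

test_that("a noiseless rater reproduces the truth exactly", {
  truth <- generate_ground_truth(n_images = 5, seed = 5)
  ann <- simulate_detection_rater(truth, noiseless_profile(), seed = 6)
  expect_identical(ann$label, truth$grid$label)
})

test_that("a zero-sensitivity rater produces no true positives", {
  truth <- generate_ground_truth(n_images = 5, p_cancer = 0.5,
                                 p_no_tissue = 0, seed = 7)
  ann <- simulate_detection_rater(truth, rater_profile(0, 1, 1), seed = 8)
  expect_equal(sum(ann$label == "cancer" & truth$grid$label == "cancer"), 0)
})

test_that("empirical error rates recover the profile at large n", {
  # ~10,800 tissue squares, all tissue
  truth <- generate_ground_truth(n_images = 300, p_cancer = 0.5,
                                 p_no_tissue = 0, seed = 9)
  profile <- rater_profile(0.74, 0.66, 0.9)
  ann <- simulate_detection_rater(truth, profile, seed = 10)
  cancer <- truth$grid$label == "cancer"
  hit <- ann$label == "cancer"

  n_pos <- sum(cancer)
  sens_bounds <- binom99(n_pos, 0.74)
  expect_gte(sum(hit & cancer), sens_bounds[1])
  expect_lte(sum(hit & cancer), sens_bounds[2])

  n_neg <- sum(!cancer)
  spec_bounds <- binom99(n_neg, 0.66)
  expect_gte(sum(!hit & !cancer), spec_bounds[1])
  expect_lte(sum(!hit & !cancer), spec_bounds[2])
})

test_that("misrecognised empty squares split between the tissue labels", {
  truth <- generate_ground_truth(n_images = 200, p_cancer = 0,
                                 p_no_tissue = 1, seed = 11)
  ann <- simulate_detection_rater(truth, rater_profile(1, 1, 0.5), seed = 12)
  n <- nrow(truth$grid)
  nt_bounds <- binom99(n, 0.5)
  expect_gte(sum(ann$label == "no_tissue"), nt_bounds[1])
  expect_lte(sum(ann$label == "no_tissue"), nt_bounds[2])
  wrong <- ann$label != "no_tissue"
  ca_bounds <- binom99(sum(wrong), 0.5)
  expect_gte(sum(ann$label[wrong] == "cancer"), ca_bounds[1])
  expect_lte(sum(ann$label[wrong] == "cancer"), ca_bounds[2])
})

test_that("crowds are reproducible and stable under extension", {
  truth <- generate_ground_truth(n_images = 3, seed = 13)
  a <- simulate_crowd(truth, 4, seed = 14)
  b <- simulate_crowd(truth, 4, seed = 14)
  expect_identical(a$annotations, b$annotations)
  expect_equal(a$profiles, b$profiles)

  big <- simulate_crowd(truth, 7, seed = 14)
  first4 <- big$annotations[big$annotations$rater_id %in%
                              unique(a$annotations$rater_id), ]
  expect_identical(as.data.frame(first4), as.data.frame(a$annotations))
})

test_that("a deterministic sampler yields one annotation set per rater", {
  truth <- generate_ground_truth(n_images = 2, seed = 15)
  crowd <- simulate_crowd(truth, 3,
                          constant_profile_sampler(noiseless_profile()),
                          seed = 16)
  expect_equal(dplyr::n_distinct(crowd$annotations$rater_id), 3)
  expect_equal(nrow(crowd$annotations), 3 * nrow(truth$grid))
})

test_that("drawn profile sensitivities centre on the sampler mean", {
  truth <- generate_ground_truth(n_images = 1, seed = 17)
  crowd <- simulate_crowd(truth, 50, lay_profile_sampler(), seed = 18)
  sens <- vapply(crowd$profiles, function(p) p$sensitivity, numeric(1))
  # analytic 99% CI of the mean of 50 Beta(mean .74, sd .14) draws
  half <- 2.5758 * 0.14 / sqrt(50)
  expect_gt(mean(sens), 0.74 - half)
  expect_lt(mean(sens), 0.74 + half)
})

test_that("noiseless IHC raters reproduce the truth on assigned images", {
  truth <- generate_ground_truth(n_images = 20, seed = 19)
  rating <- simulate_ihc_rater(truth, noiseless_profile(),
                               images_per_rater = 10, seed = 20)
  expect_equal(nrow(rating), 10)
  merged <- dplyr::inner_join(rating, truth$ihc, by = "image_id",
                              suffix = c("", "_true"))
  expect_identical(merged$proportion, merged$proportion_true)
  expect_identical(merged$intensity, merged$intensity_true)
  expect_identical(merged$h_score, merged$h_score_true)
})

test_that("symmetric proportion noise keeps the median on the truth", {
  truth <- make_truth(labels = c("cancer", "no_cancer", "cancer", "no_cancer"),
                      n_images = 1, proportion = 50L, intensity = 2L)
  profile <- rater_profile(1, 1, 1, proportion_sd = 10,
                           intensity_confusion = diag(3))
  crowd <- simulate_ihc_crowd(truth, 200,
                              constant_profile_sampler(profile),
                              images_per_rater = 1, seed = 21)
  expect_lte(abs(median(crowd$ratings$proportion) - 50), 5)
})

test_that("zero true proportion with zero noise is always reported 0", {
  truth <- make_truth(labels = "no_cancer", n_images = 3, proportion = 0L)
  crowd <- simulate_ihc_crowd(truth, 5,
                              constant_profile_sampler(noiseless_profile()),
                              images_per_rater = 3, seed = 22)
  expect_true(all(crowd$ratings$proportion == 0))
  expect_true(all(is.na(crowd$ratings$intensity)))
  expect_true(all(crowd$ratings$h_score == 0))
})

test_that("a noiseless expert panel is unanimous with the truth", {
  truth <- generate_ground_truth(n_images = 4, seed = 23)
  panel <- simulate_expert_panel(truth, k = 3,
                                 expert_profile = noiseless_profile(),
                                 seed = 24)
  expect_equal(dplyr::n_distinct(panel$detection$rater_id), 3)
  expect_true(all(panel$detection$rater_type == "expert"))
  for (id in unique(panel$detection$rater_id)) {
    one <- panel$detection[panel$detection$rater_id == id, ]
    expect_identical(one$label, truth$grid$label)
  }
  cons <- expert_detection_consensus(panel$detection)
  expect_identical(cons$reference$positive, truth$grid$label == "cancer")
})
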