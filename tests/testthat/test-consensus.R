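test_that("binarization maps cancer to positive and the rest to negative", {
  expect_true(binarize_label("cancer"))
  expect_false(binarize_label("no_cancer"))
  expect_false(binarize_label("no_tissue"))
  expect_equal(binarize_label(c("cancer", "no_tissue")), c(TRUE, FALSE))
  expect_error(binarize_label("blank"), "unknown label")
})

test_that("majority consensus follows the vote fraction with ties negative", {
  ann <- make_detection(list(
    r1 = c("cancer", "cancer", "no_cancer", "no_cancer"),
    r2 = c("cancer", "no_cancer", "no_cancer", "no_cancer"),
    r3 = c("no_cancer", "no_cancer", "no_cancer", "cancer")
  ))
  out <- majority_consensus(ann)
  # square (0,0): votes C,C,N -> positive 2/3
  expect_true(out$consensus[1])
  expect_equal(out$vote_fraction[1], 2 / 3)
  # square (1,1): votes N,N,C -> negative 1/3
  expect_false(out$consensus[4])
  expect_error(majority_consensus(ann[0, ]), "at least one")
})

test_that("two-rater ties resolve negative, exhaustively", {
  labels <- c("cancer", "no_cancer", "no_tissue")
  for (l1 in labels) {
    for (l2 in labels) {
      ann <- make_detection(list(r1 = rep(l1, 4), r2 = rep(l2, 4)))
      out <- majority_consensus(ann)
      # with 2 raters, only unanimity on cancer exceeds 0.5
      expected <- l1 == "cancer" && l2 == "cancer"
      expect_equal(unique(out$consensus), expected,
                   info = paste(l1, l2))
    }
  }
  # the positive tie rule flips exact ties only
  ann <- make_detection(list(r1 = rep("cancer", 4), r2 = rep("no_cancer", 4)))
  expect_true(all(majority_consensus(ann, tie = "positive")$consensus))
})

test_that("a 1/4 minority vote stays negative", {
  ann <- make_detection(list(r1 = rep("no_cancer", 4), r2 = rep("no_cancer", 4),
                             r3 = rep("no_cancer", 4), r4 = rep("cancer", 4)))
  out <- majority_consensus(ann)
  expect_true(all(!out$consensus))
  expect_true(all(out$vote_fraction == 0.25))
})

test_that("majority consensus is order- and duplication-invariant", {
  truth <- generate_ground_truth(n_images = 2, seed = 31)
  crowd <- simulate_crowd(truth, 5, seed = 32)
  base <- majority_consensus(crowd$annotations)
  shuffled <- crowd$annotations[sample(nrow(crowd$annotations)), ]
  expect_equal(majority_consensus(shuffled), base)
  doubled <- dplyr::bind_rows(
    crowd$annotations,
    dplyr::mutate(crowd$annotations, rater_id = paste0(rater_id, "_dup")))
  expect_equal(majority_consensus(doubled)$consensus, base$consensus)
  expect_equal(majority_consensus(doubled)$vote_fraction, base$vote_fraction)
})

test_that("expert consensus rules match enumeration over all 3-expert triples", {
  labels <- c("cancer", "no_cancer", "no_tissue")
  triples <- expand.grid(e1 = labels, e2 = labels, e3 = labels,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(triples))) {
    tr <- unlist(triples[i, ])
    ann <- make_detection(list(e1 = rep(tr[1], 4), e2 = rep(tr[2], 4),
                               e3 = rep(tr[3], 4)), rater_type = "expert")
    cons <- expert_detection_consensus(ann)
    expect_equal(unique(cons$reference$positive), sum(tr == "cancer") >= 2,
                 info = paste(tr, collapse = "/"))
    expect_equal(nrow(cons$mask), if (all(tr == "no_tissue")) 4 else 0,
                 info = paste(tr, collapse = "/"))
  }
  # the (no_tissue, no_tissue, no_cancer) square is kept and negative
  ann <- make_detection(list(e1 = rep("no_tissue", 4), e2 = rep("no_tissue", 4),
                             e3 = rep("no_cancer", 4)), rater_type = "expert")
  cons <- expert_detection_consensus(ann)
  expect_equal(nrow(cons$mask), 0)
  expect_true(all(!cons$reference$positive))
  # under the majority mask rule the same square is masked
  cons_maj <- expert_detection_consensus(ann, mask_rule = "majority")
  expect_equal(nrow(cons_maj$mask), 4)
})

test_that("noiseless experts recover truth and the true no-tissue mask", {
  truth <- generate_ground_truth(n_images = 5, p_no_tissue = 0.3, seed = 33)
  panel <- simulate_expert_panel(truth, k = 3,
                                 expert_profile = noiseless_profile(),
                                 seed = 34)
  cons <- expert_detection_consensus(panel$detection)
  expect_identical(cons$reference$positive, truth$grid$label == "cancer")
  true_nt <- truth$grid[truth$grid$label == "no_tissue",
                        c("image_id", "row", "col")]
  expect_equal(as.data.frame(cons$mask), as.data.frame(true_nt))
})

test_that("expert coverage of every image is required", {
  truth <- generate_ground_truth(n_images = 2, seed = 35)
  panel <- simulate_expert_panel(truth, k = 2,
                                 expert_profile = noiseless_profile(),
                                 seed = 36)
  partial <- panel$detection[!(panel$detection$rater_id == "expert2" &
                                 panel$detection$image_id == "img002"), ]
  expect_error(expert_detection_consensus(partial), "not covered by all")
})

test_that("expert IHC consensus is the median of proportions and intensities", {
  ratings <- tibble::tibble(
    image_id = "img001", rater_id = c("e1", "e2", "e3"),
    rater_type = "expert", proportion = c(40L, 50L, 80L),
    intensity = c(2L, 2L, 3L))
  ratings$h_score <- derive_h_score(ratings$proportion, ratings$intensity)
  cons <- expert_ihc_consensus(ratings)
  expect_equal(cons$proportion, 50)
  expect_equal(cons$intensity, 2)
  expect_equal(cons$h_score, 100)
})

test_that("even-count medians take the midpoint; zero median drops intensity", {
  two <- tibble::tibble(image_id = "img001", rater_id = c("e1", "e2"),
                        rater_type = "expert", proportion = c(50L, 50L),
                        intensity = c(1L, 3L))
  two$h_score <- derive_h_score(two$proportion, two$intensity)
  cons <- expert_ihc_consensus(two)
  expect_equal(cons$intensity, 2) # midpoint of (1, 3)

  zero <- tibble::tibble(image_id = "img001",
                         rater_id = c("e1", "e2", "e3"),
                         rater_type = "expert", proportion = c(0L, 0L, 20L),
                         intensity = c(NA, NA, 3L))
  zero$h_score <- derive_h_score(zero$proportion, zero$intensity)
  cons0 <- expert_ihc_consensus(zero)
  expect_equal(cons0$proportion, 0)
  expect_true(is.na(cons0$intensity))
  expect_equal(cons0$h_score, 0)

  single <- zero[3, ]
  cons1 <- expert_ihc_consensus(single)
  expect_equal(cons1$h_score, 60)
})

test_that("aggregate H-score is the within-image median with a percentile CI", {
  ratings <- tibble::tibble(
    image_id = "img001", rater_id = c("r1", "r2", "r3"), rater_type = "lay",
    proportion = c(0L, 50L, 100L), intensity = c(NA, 2L, 3L))
  ratings$h_score <- derive_h_score(ratings$proportion, ratings$intensity)
  agg <- aggregate_h_score(ratings, n_boot = 200, seed = 1)
  expect_equal(agg$h_score, 100)
  expect_equal(agg$n_raters, 3)

  same <- dplyr::mutate(ratings, proportion = 50L, intensity = 2L,
                        h_score = 100L)
  agg2 <- aggregate_h_score(same, n_boot = 200, seed = 1)
  expect_equal(c(agg2$ci_low, agg2$ci_high), c(100, 100))
})

test_that("15 noiseless raters recover the true aggregate H-score", {
  truth <- make_truth(labels = "cancer", n_images = 4,
                      proportion = c(50L, 75L, 100L, 25L),
                      intensity = c(3L, 2L, 1L, 2L))
  crowd <- simulate_ihc_crowd(truth, 15,
                              constant_profile_sampler(noiseless_profile()),
                              images_per_rater = 4, seed = 37)
  agg <- aggregate_h_score(crowd$ratings, n_boot = 100, seed = 2)
  expect_equal(agg$h_score, truth$ihc$h_score[match(agg$image_id,
                                                    truth$ihc$image_id)])
  expect_equal(agg$ci_low, agg$h_score)
  expect_equal(agg$ci_high, agg$h_score)
})

test_that("masked squares contribute to no downstream metric", {
  truth <- generate_ground_truth(n_images = 4, p_no_tissue = 0.25, seed = 38)
  crowd <- simulate_crowd(truth, 7, seed = 39)
  panel <- simulate_expert_panel(truth, k = 3,
                                 expert_profile = noiseless_profile(),
                                 seed = 40)
  cons <- expert_detection_consensus(panel$detection)
  with_mask <- rater_performance(crowd$annotations, cons$reference, cons$mask)

  # physically remove the masked squares from every input instead
  key <- function(d) paste(d$image_id, d$row, d$col)
  mk <- key(cons$mask)
  ann2 <- crowd$annotations[!(key(crowd$annotations) %in% mk), ]
  ref2 <- cons$reference[!(key(cons$reference) %in% mk), ]
  removed <- rater_performance(ann2, ref2, mask = NULL)
  expect_equal(as.data.frame(with_mask), as.data.frame(removed))
})
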