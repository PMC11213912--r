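test_that("Dice has its boundary identities and symmetry", {
  a <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_equal(dice_per_class(a, a, 1), 1)
  b <- matrix(c(2, 2, 1, 1), 2, 2)
  expect_equal(dice_per_class(a, b, 1), 0)

  # prediction covers half of the truth at equal total size
  gt <- matrix(0L, 4, 4); gt[1:2, ] <- 1L; gt[3:4, ] <- 2L
  pr <- matrix(2L, 4, 4); pr[1, ] <- 1L; pr[3, ] <- 9L
  # |P|=4, |G|=8, |P n G|=4 for class 1? no: pr row1 only -> 4 px overlap 4
  expect_equal(dice_per_class(pr, gt, 1), 2 * 4 / (4 + 8))

  # symmetry on random masks (both arguments annotated everywhere)
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(sample(1:3, 36, TRUE), 6, 6)
    y <- matrix(sample(1:3, 36, TRUE), 6, 6)
    expect_equal(dice_per_class(x, y, 2), dice_per_class(y, x, 2))
  }

  # absent class is undefined, ignore pixels are ignored
  expect_true(is.na(dice_per_class(a, a, 5)))
  gt0 <- gt; gt0[1, ] <- 0L          # ignore the first row
  pr3 <- matrix(2L, 4, 4); pr3[2:3, ] <- 1L
  expect_equal(dice_per_class(pr3, gt0, 1), 2 * 4 / (8 + 4))

  # grouped Dice merges epithelium correctly
  g1 <- matrix(1L, 4, 4); g2 <- matrix(2L, 4, 4)
  expect_equal(unname(dice_grouped(g1, g2)["epithelium"]), 1)
})

test_that("instance matching is greedy centroid-in-annotation", {
  pred <- tibble::tibble(instance_id = 1:2, x = c(5, 50), y = c(5, 50))
  gt <- tibble::tibble(instance_id = 10, x = 5, y = 5,
                       xmin = 2, xmax = 8, ymin = 2, ymax = 8)
  m <- match_instances(pred, gt)
  expect_equal(m$matches$pred_id, 1)
  expect_equal(m$matches$gt_id, 10)
  expect_equal(m$unmatched_pred, 2)
  expect_length(m$unmatched_gt, 0)

  # dense non-overlapping truth: greedy equals the optimal assignment
  r <- generate_roi(synth_params(roi_size_px = 160L, seed = 17))
  probs <- tilquant:::oracle_probs_from_truth(r)
  inst <- extract_instances(probs, min_size_px = 10)
  m2 <- match_instances(inst, r$nucleus_classes)
  # optimal assignment on non-overlapping truth matches every instance
  expect_equal(nrow(m2$matches), nrow(r$nucleus_classes))
  expect_length(m2$unmatched_gt, 0)
})

test_that("AUROC equals exhaustive pair counting", {
  # perfectly separating probabilities
  probs <- cbind(a = c(.9, .8, .1, .2), b = c(.1, .2, .9, .8))
  mets <- nucleus_metrics(probs, c("a", "a", "b", "b"))
  expect_equal(mets$auroc[mets$class == "a"], 1)
  expect_equal(mets$f1[mets$class == "a"], 1)
  expect_equal(mets$mcc[mets$class == "macro"], 1)

  # label-independent probabilities approach 0.5 at large n
  set.seed(4)
  n <- 4000
  p <- runif(n)
  probs2 <- cbind(a = p, b = 1 - p)
  mets2 <- nucleus_metrics(probs2, sample(c("a", "b"), n, TRUE))
  expect_equal(mets2$auroc[mets2$class == "a"], 0.5, tolerance = 0.05)

  # exact agreement with the brute-force oracle on small fixtures,
  # including ties
  set.seed(9)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, 0.1), n, TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_identical(tilquant:::auroc_rank(scores, labels),
                     auroc_bruteforce(scores, labels))
  }

  # a class absent from the ground truth yields NA AUROC
  probs3 <- cbind(a = c(.9, .1), b = c(.05, .85), c = c(.05, .05))
  m3 <- nucleus_metrics(probs3, c("a", "b"))
  expect_true(is.na(m3$auroc[m3$class == "c"]))
  expect_false(is.na(m3$auroc[m3$class == "macro"]))
})

test_that("MCC stays within bounds and vanishes on independence", {
  set.seed(12)
  n <- 500
  gt <- sample(c("a", "b"), n, TRUE)
  p <- runif(n)
  probs <- cbind(a = p, b = 1 - p)
  mets <- nucleus_metrics(probs, gt)
  mcc <- mets$mcc[mets$class == "a"]
  expect_true(mcc >= -1 && mcc <= 1)
  expect_equal(mcc, 0, tolerance = 0.1)
})

test_that("folds are hospital-stratified and balanced", {
  sh <- tibble::tibble(
    slide_id = sprintf("s%02d", 1:20),
    hospital_id = rep(sprintf("h%d", 1:5), each = 4)
  )
  f <- make_folds(sh, n_folds = 5, seed = 2)
  expect_equal(sort(f$hospital_fold$fold), 1:5)
  # invariant: a hospital never spans folds
  spans <- dplyr::summarise(
    dplyr::group_by(f$slide_fold, .data$hospital_id),
    n = dplyr::n_distinct(.data$fold)
  )
  expect_true(all(spans$n == 1))

  # skewed hospital sizes: fold spread bounded by the largest hospital
  set.seed(1)
  sizes <- c(12, 8, 5, 4, 3, 3, 2, 2, 1, 1)
  sh2 <- tibble::tibble(
    slide_id = sprintf("t%03d", seq_len(sum(sizes))),
    hospital_id = rep(sprintf("H%02d", seq_along(sizes)), sizes)
  )
  f2 <- make_folds(sh2, n_folds = 5, seed = 3)
  per_fold <- table(f2$slide_fold$fold)
  expect_lte(max(per_fold) - min(per_fold), max(sizes))

  expect_error(make_folds(sh[1:4, ], n_folds = 5), "hospitals")
})

test_that("fold summaries use folds 2-5 with sample sd and half-away rounding", {
  expect_equal(summarize_folds(c(81.3, 80.2, 81, 80.8, 81)),
               c(mean = 80.8, sd = 0.4))
  expect_equal(summarize_folds(c(93.3, 92.3, 93.6, 91.9, 94.2)),
               c(mean = 93.0, sd = 1.1))
  expect_equal(summarize_folds(c(7, 7, 7, 7, 7)), c(mean = 7, sd = 0))
  expect_error(summarize_folds(c(1, NA, 3, 4, 5)), "complete")

  # the reference fold table reproduces all its printed summaries
  ft <- read.csv(system.file("extdata", "benchmark_fold_metrics.csv",
                             package = "tilquant"))
  out <- summarize_fold_table(ft)
  expect_equal(out$mean[out$class == "stroma"], 80.8)
  expect_equal(out$sd[out$class == "stroma"], 0.4)
  expect_equal(out$mean[out$class == "lymphocyte"], 93.0)
  expect_equal(out$sd[out$class == "lymphocyte"], 1.1)

  # discriminating property: population sd does NOT reproduce the stroma row
  v <- c(80.2, 81, 80.8, 81)
  pop_sd <- sqrt(mean((v - mean(v))^2))
  expect_false(tilquant:::round_half_away(pop_sd, 1) == 0.4)
})
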