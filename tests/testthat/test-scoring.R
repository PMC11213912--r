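test_that("saliency geometry matches the brute-force distance oracle", {
  # half-plane at 0.5 MPP: a 64-px strip of peritumoral stroma
  m <- matrix(3L, 256, 256); m[, 1:128] <- 1L
  expect_equal(saliency(m, mpp = 0.5, dist_microns = 32), 0.25)
  expect_equal(saliency(m, mpp = 0.5),
               saliency_bruteforce(m, 0.5))

  expect_equal(saliency(matrix(3L, 16, 16), 0.5), 0)  # no tumor
  expect_equal(saliency(matrix(1L, 16, 16), 0.5), 0)  # no stroma

  # random small maps agree exactly with the all-pairs oracle
  set.seed(5)
  for (rep in 1:3) {
    rm <- matrix(sample(c(1L, 3L, 4L, 6L), 24 * 24, replace = TRUE), 24, 24)
    expect_equal(saliency(rm, mpp = 0.5), saliency_bruteforce(rm, 0.5))
  }
})

test_that("ROI counting follows centroid membership and debris exclusion", {
  region <- matrix(3L, 64, 64); region[, 1:32] <- 1L
  mk <- function(n, x, y, class) {
    tibble::tibble(instance_id = seq_len(n), x = x, y = y, class = class)
  }
  inst <- dplyr::bind_rows(
    mk(10, 45, seq(2, 56, 6), "lymphocyte"),
    mk(10, 55, seq(2, 56, 6), "fibroblast"),
    mk(20, 10, seq(1, 58, 3), "cancer"),
    mk(3, 40, c(10, 20, 30), "debris")          # excluded everywhere
  )
  cts <- roi_counts(list(region_map_hpf = region, instances = inst),
                    mpp = 0.5)
  expect_equal(cts$n_til_stroma, 10)
  expect_equal(cts$n_cells_stroma, 20)
  expect_equal(cts$n_cells_total, 40)
  expect_equal(cts$stromal_area_mm2, 32 * 64 * 0.25e-6)

  empty <- roi_counts(list(
    region_map_hpf = region,
    instances = inst[0, ]
  ))
  expect_equal(empty$n_til_stroma + empty$n_cells_total, 0)

  # generator truth: counting on truth instances equals the generator's
  # own bookkeeping
  r <- generate_roi(synth_params(roi_size_px = 128L, seed = 12))
  cts2 <- roi_counts(list(region_map_hpf = r$region_mask_20x,
                          instances = r$nucleus_classes), mpp = 0.5)
  truth <- tilquant:::roi_truth_counts(r)
  expect_equal(cts2$n_til_stroma, truth$n_til_stroma)
  expect_equal(cts2$n_cells_stroma, truth$n_cells_stroma)
  expect_equal(cts2$n_cells_total, truth$n_cells_total)
  expect_equal(cts2$stromal_area_mm2, truth$stromal_area_mm2)
})

test_that("score variants are the stated ratios with missing on zero", {
  cts <- tibble::tibble(n_til_stroma = 10, n_cells_stroma = 20,
                        n_cells_total = 40, stromal_area_mm2 = 0.5)
  sv <- score_variants(cts)
  expect_equal(sv$nTSa, 20)
  expect_equal(sv$nTnS, 0.5)
  expect_equal(sv$nTnA, 0.25)

  z <- score_variants(tibble::tibble(n_til_stroma = 0, n_cells_stroma = 0,
                                     n_cells_total = 0,
                                     stromal_area_mm2 = 0))
  expect_true(all(is.na(c(z$nTSa, z$nTnS, z$nTnA))))

  # monotonicity in the TIL count
  lo <- score_variants(cts)
  hi <- score_variants(dplyr::mutate(cts, n_til_stroma = 15))
  expect_true(all(c(hi$nTSa > lo$nTSa, hi$nTnS > lo$nTnS, hi$nTnA > lo$nTnA)))
  # nTnA <= nTnS whenever all TILs are stromal
  expect_lte(sv$nTnA, sv$nTnS)
})

test_that("aggregation pools globally and weights by saliency", {
  one <- tibble::tibble(n_til_stroma = 5, n_cells_stroma = 10,
                        n_cells_total = 20, stromal_area_mm2 = 0.2,
                        saliency = 0.4)
  same <- dplyr::bind_rows(one, one, one)
  agg <- aggregate_scores(same, "s1")
  for (v in c("nTSa", "nTnS", "nTnA")) {
    expect_equal(agg$score[agg$variant == v & agg$aggregation == "global"],
                 agg$score[agg$variant == v &
                             agg$aggregation == "saliency_weighted"])
  }

  two <- tibble::tibble(
    n_til_stroma = c(2, 6), n_cells_stroma = c(10, 10),
    n_cells_total = c(10, 10), stromal_area_mm2 = c(1, 1),
    saliency = c(1, 3)
  )
  agg2 <- aggregate_scores(two, "s2")
  expect_equal(
    agg2$score[agg2$variant == "nTnS" &
                 agg2$aggregation == "saliency_weighted"],
    (1 * 0.2 + 3 * 0.6) / 4
  )

  # random cohort equals the explicit weighted-mean oracle
  set.seed(8)
  rnd <- tibble::tibble(
    n_til_stroma = rpois(20, 5), n_cells_stroma = rpois(20, 20) + 10,
    n_cells_total = rpois(20, 40) + 20,
    stromal_area_mm2 = runif(20, 0.1, 0.5), saliency = runif(20)
  )
  agg3 <- aggregate_scores(rnd, "s3")
  s <- rnd$n_til_stroma / rnd$n_cells_stroma
  expect_equal(
    agg3$score[agg3$variant == "nTnS" &
                 agg3$aggregation == "saliency_weighted"],
    sum(rnd$saliency * s) / sum(rnd$saliency), tolerance = 1e-9
  )
  # order invariance
  agg3p <- aggregate_scores(rnd[sample(20), ], "s3")
  expect_equal(dplyr::arrange(agg3, variant, aggregation)$score,
               dplyr::arrange(agg3p, variant, aggregation)$score)

  # all-zero weights fall back to the unweighted mean with a warning
  zw <- dplyr::mutate(two, saliency = 0)
  expect_warning(aggz <- aggregate_scores(zw, "sz"), "unweighted")
  expect_equal(aggz$score[aggz$variant == "nTnS" &
                            aggz$aggregation == "saliency_weighted"],
               mean(c(0.2, 0.6)))
})

test_that("calibration fits a no-intercept scale on inliers only", {
  set.seed(6)
  comp <- runif(30, 0.1, 0.6)
  d <- tibble::tibble(computational_score = comp, visual_score = 2 * comp)
  cal <- calibrate(d)
  expect_equal(cal$k, 2, tolerance = 1e-12)
  expect_true(all(cal$inlier))

  d1 <- tibble::tibble(computational_score = comp, visual_score = comp)
  expect_equal(calibrate(d1)$k, 1, tolerance = 1e-12)

  expect_error(
    calibrate(tibble::tibble(computational_score = rep(1, 10),
                             visual_score = runif(10))),
    "variance"
  )

  coh <- generate_cohort(50, visual_noise_sd = 0.02, scale = 1.8,
                         n_outliers = 3, seed = 7)
  cal3 <- calibrate(coh)
  expect_equal(sum(!cal3$inlier), 3)
  expect_setequal(which(!cal3$inlier), which(coh$injected_outlier))
  expect_lt(abs(cal3$k - 1.8), 0.05)
  # calibrated scores exist for every slide, outliers included
  td <- tidy(cal3)
  expect_equal(td$calibrated, cal3$k * coh$computational_score)
  expect_s3_class(autoplot(cal3), "ggplot")

  # noise-free recovery is exact
  coh0 <- generate_cohort(40, visual_noise_sd = 0, scale = 1.8,
                          n_outliers = 0, seed = 9)
  expect_equal(calibrate(coh0)$k, 1.8, tolerance = 1e-12)
})
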