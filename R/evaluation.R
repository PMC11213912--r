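#' Per-class Sorensen-Dice coefficient
#'
#' `2|P n G| / (|P| + |G|)` over pixels where the ground truth is
#' annotated (code 0 = ignore). If the class is absent from both masks the
#' coefficient is undefined and `NA` is returned.
#'
#' @param pred,gt integer masks of identical extent.
#' @param class_code class to score.
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
dice_per_class <- function(pred, gt, class_code) {
  stopifnot(all(dim(pred) == dim(gt)))
  keep <- gt != 0
  p <- pred[keep] == class_code
  g <- gt[keep] == class_code
  if (sum(p) + sum(g) == 0) return(NA_real_)
  2 * sum(p & g) / (sum(p) + sum(g))
}

#' Dice over grouped superclasses
#'
#' Maps both masks onto `{epithelium, stroma, TILs, other}` and returns the
#' per-superclass Dice, the practical evaluation vocabulary.
#'
#' @param pred,gt integer region masks.
#' @param taxonomy class taxonomy.
#' @return Named numeric vector of superclass Dice values.
#' @export
dice_grouped <- function(pred, gt, taxonomy = build_default_taxonomy()) {
  groups <- unique(taxonomy$region_group)
  code_group <- taxonomy$region_group[
    match(names(taxonomy$region_classes), names(taxonomy$region_group))
  ]
  to_group <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    for (i in seq_along(code_group)) {
      out[m == taxonomy$region_classes[i]] <- match(code_group[i], groups)
    }
    out
  }
  gp <- to_group(pred)
  gg <- to_group(gt)
  gg[gt == 0] <- 0L
  setNames(
    vapply(seq_along(groups), function(k) dice_per_class(gp, gg, k),
           numeric(1)),
    groups
  )
}

#' Match predicted instances to ground-truth annotations
#'
#' Greedy one-to-one matching: each prediction (in instance order) is
#' matched to the unmatched ground-truth annotation whose bounding box
#' contains the predicted centroid, ties broken by nearest ground-truth
#' centroid.
#'
#' @param pred tibble with `instance_id`, `x`, `y` (predicted centroids).
#' @param gt tibble with `instance_id`, `x`, `y` and either boxes
#'   (`xmin`, `xmax`, `ymin`, `ymax`) or a point radius column `r`.
#' @return List with `matches` (tibble `pred_id`, `gt_id`),
#'   `unmatched_pred`, `unmatched_gt` (id vectors).
#' @export
match_instances <- function(pred, gt) {
  if (!all(c("xmin", "xmax", "ymin", "ymax") %in% names(gt))) {
    r <- if ("r" %in% names(gt)) gt$r else rep(5, nrow(gt))
    gt$xmin <- gt$x - r; gt$xmax <- gt$x + r
    gt$ymin <- gt$y - r; gt$ymax <- gt$y + r
  }
  taken <- rep(FALSE, nrow(gt))
  matches <- list()
  for (i in seq_len(nrow(pred))) {
    cand <- which(
      !taken &
        pred$x[i] >= gt$xmin & pred$x[i] <= gt$xmax &
        pred$y[i] >= gt$ymin & pred$y[i] <= gt$ymax
    )
    if (length(cand) == 0) next
    dd <- (gt$x[cand] - pred$x[i])^2 + (gt$y[cand] - pred$y[i])^2
    j <- cand[which.min(dd)]
    taken[j] <- TRUE
    matches[[length(matches) + 1]] <-
      tibble::tibble(pred_id = pred$instance_id[i], gt_id = gt$instance_id[j])
  }
  m <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(pred_id = integer(), gt_id = integer())
  list(
    matches = m,
    unmatched_pred = setdiff(pred$instance_id, m$pred_id),
    unmatched_gt = setdiff(gt$instance_id, m$gt_id)
  )
}

# one-vs-rest AUROC by the rank statistic (midranks for ties)
auroc_rank <- function(scores, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_counts <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

binary_metrics <- function(cts) {
  tp <- cts["tp"]; fp <- cts["fp"]; fn <- cts["fn"]; tn <- cts["tn"]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  acc <- (tp + tn) / sum(cts)
  c(sensitivity = unname(sens), specificity = unname(spec),
    precision = unname(prec), recall = unname(sens), f1 = unname(f1),
    mcc = unname(mcc), accuracy = unname(acc))
}

#' Nucleus classification metrics on matched instances
#'
#' Per-class one-vs-rest AUROC (rank statistic with midranks for ties)
#' from the predicted class probabilities, plus discrete metrics
#' (sensitivity, specificity, precision, recall, F1, MCC, accuracy) from
#' the argmax confusion. Micro averages pool the binary indicators over
#' classes; macro averages are unweighted class means. Classes absent from
#' the ground truth get `NA` AUROC and are excluded from the macro mean.
#'
#' @param probs matrix (n x C) of class probabilities for matched
#'   predictions (columns named by class).
#' @param gt_class character or integer vector of ground-truth classes
#'   (length n).
#' @param classes class labels defining the column order.
#' @return Tibble: one row per class plus `micro` and `macro` rows, with
#'   metric columns.
#' @export
nucleus_metrics <- function(probs, gt_class,
                            classes = colnames(probs)) {
  stopifnot(nrow(probs) == length(gt_class))
  if (length(unique(gt_class)) < 2) {
    stop("need at least two ground-truth classes")
  }
  pred_class <- classes[max.col(probs, ties.method = "first")]
  per <- lapply(classes, function(cl) {
    truth <- gt_class == cl
    au <- auroc_rank(probs[, cl], truth)
    mets <- binary_metrics(binary_counts(pred_class == cl, truth))
    tibble::tibble(class = cl, n_gt = sum(truth), auroc = au,
                   !!!as.list(mets))
  })
  per <- dplyr::bind_rows(per)
  # micro: pool binary indicator vectors across classes
  all_pred <- unlist(lapply(classes, function(cl) pred_class == cl))
  all_truth <- unlist(lapply(classes, function(cl) gt_class == cl))
  all_scores <- c(probs[, classes])
  micro <- binary_metrics(binary_counts(all_pred, all_truth))
  micro_auroc <- auroc_rank(all_scores, all_truth)
  present <- per$n_gt > 0
  macro <- colMeans(per[present, c("auroc", "sensitivity", "specificity",
                                   "precision", "recall", "f1", "mcc",
                                   "accuracy")], na.rm = TRUE)
  dplyr::bind_rows(
    per,
    tibble::tibble(class = "micro", n_gt = length(gt_class),
                   auroc = micro_auroc, !!!as.list(micro)),
    tibble::tibble(class = "macro", n_gt = length(gt_class),
                   !!!as.list(macro))
  )
}

#' Hospital-stratified cross-validation folds
#'
#' Internal-external folds: hospitals are shuffled (seeded), ordered by
#' slide count, and greedily dealt to the currently smallest fold, so all
#' slides from one hospital share a fold and no hospital ever spans
#' training and testing.
#'
#' @param slide_hospital tibble with `slide_id` and `hospital_id`.
#' @param n_folds number of folds (default 5).
#' @param seed shuffle seed.
#' @return A `tq_folds` list: `slide_fold` tibble (`slide_id`,
#'   `hospital_id`, `fold`) and `hospital_fold` tibble.
#' @export
make_folds <- function(slide_hospital, n_folds = 5L, seed = 1L) {
  hosp <- dplyr::count(slide_hospital, .data$hospital_id, name = "n_slides")
  if (nrow(hosp) < n_folds) {
    stop("need at least ", n_folds, " hospitals, have ", nrow(hosp))
  }
  set.seed(seed)
  hosp <- hosp[sample.int(nrow(hosp)), ]
  hosp <- hosp[order(-hosp$n_slides), ]
  load <- numeric(n_folds)
  fold <- integer(nrow(hosp))
  for (i in seq_len(nrow(hosp))) {
    f <- which.min(load)
    fold[i] <- f
    load[f] <- load[f] + hosp$n_slides[i]
  }
  hf <- tibble::tibble(hospital_id = hosp$hospital_id, fold = fold)
  sf <- dplyr::left_join(slide_hospital, hf, by = "hospital_id")
  structure(list(slide_fold = sf, hospital_fold = hf, n_folds = n_folds),
            class = "tq_folds")
}

#' Summarize a metric over cross-validation folds
#'
#' Fold 1 is reserved for hyperparameter tuning and is excluded: the
#' summary is the mean and sample (n-1) standard deviation over folds
#' 2..n, rounded half-away-from-zero to one decimal -- the convention of
#' published fold tables, which sample sd reproduces exactly and
#' population sd does not.
#'
#' @param values numeric vector of per-fold values ordered fold 1..n.
#' @param digits decimals of the rounded summary.
#' @return Named vector `c(mean, sd)` (rounded).
#' @export
summarize_folds <- function(values, digits = 1) {
  if (anyNA(values) || length(values) < 2) {
    stop("need complete per-fold values for folds 1..n")
  }
  v <- values[-1]
  round_half_away(c(mean = mean(v), sd = sd(v)), digits)
}

round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Fold-table summary in the published layout
#'
#' @param fold_table tibble with `group`, `class`, `metric` and
#'   `fold1..fold5` columns (see
#'   `system.file("extdata", "benchmark_fold_metrics.csv", package =
#'   "tilquant")`).
#' @return The table with `mean` and `sd` columns appended.
#' @export
summarize_fold_table <- function(fold_table) {
  fcols <- grep("^fold", names(fold_table), value = TRUE)
  ms <- t(apply(as.matrix(fold_table[, fcols]), 1, summarize_folds))
  fold_table$mean <- ms[, 1]
  fold_table$sd <- ms[, 2]
  fold_table
}
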