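#' Peritumoral-stroma saliency of a region map
#'
#' Tumor is the epithelium superclass; the Euclidean distance transform
#' gives each pixel's distance (in microns) to the nearest tumor pixel,
#' and saliency is the fraction of all map pixels that are
#' stromal-compartment pixels within `dist_microns` (default 32) of the
#' tumor boundary. ROIs without tumor (or without stroma) score 0.
#'
#' @param region_map integer matrix of region taxonomy codes (0.5 MPP).
#' @param mpp microns per pixel of the map.
#' @param dist_microns peritumoral band width.
#' @param taxonomy class taxonomy.
#' @return Scalar in `[0, 1]`.
#' @export
saliency <- function(region_map, mpp = 0.5, dist_microns = 32,
                     taxonomy = build_default_taxonomy()) {
  epi <- taxonomy$region_classes[taxonomy$region_group == "epithelium"]
  stromal <- taxonomy$region_classes[c("stroma", "tils_dense")]
  tumor <- region_map %in% epi
  if (!any(tumor)) return(0)
  d <- EBImage::distmap(matrix(as.numeric(!tumor), nrow(region_map)))
  d <- as.numeric(d) * mpp
  strom <- region_map %in% stromal
  sum(strom & d > 0 & d <= dist_microns) / length(region_map)
}

#' Score components of one ROI prediction
#'
#' Counts TILs (lymphocytes + plasma cells) and all viable cells (debris
#' excluded) with compartment membership decided by the instance centroid's
#' region code; the stromal compartment is stroma plus TILs-dense. Areas
#' are pixel counts times `mpp^2`.
#'
#' @param prediction a `tq_prediction` from [infer_slide()], or any list
#'   with `instances` (tibble with `x`, `y`, `class`) and
#'   `region_map_hpf`.
#' @param mpp microns per pixel of the region map.
#' @param taxonomy class taxonomy.
#' @param dist_microns saliency band passed to [saliency()].
#' @return One-row tibble: `n_til_stroma`, `n_cells_stroma`,
#'   `n_cells_total`, `stromal_area_mm2`, `saliency`.
#' @export
roi_counts <- function(prediction, mpp = 0.5,
                       taxonomy = build_default_taxonomy(),
                       dist_microns = 32) {
  region <- prediction$region_map_hpf
  inst <- prediction$instances
  stromal_codes <- taxonomy$region_classes[c("stroma", "tils_dense")]
  til_classes <- c("lymphocyte", "plasma_cell")
  viable <- inst[inst$class != "debris", , drop = FALSE]
  if (nrow(viable) > 0) {
    ridx <- cbind(
      pmin(pmax(round(viable$y) + 1, 1), nrow(region)),
      pmin(pmax(round(viable$x) + 1, 1), ncol(region))
    )
    rcode <- region[ridx]
  } else {
    rcode <- integer()
  }
  in_stroma <- rcode %in% stromal_codes
  tibble::tibble(
    n_til_stroma = sum(in_stroma & viable$class %in% til_classes),
    n_cells_stroma = sum(in_stroma),
    n_cells_total = nrow(viable),
    stromal_area_mm2 = sum(region %in% stromal_codes) * (mpp / 1000)^2,
    saliency = saliency(region, mpp, dist_microns, taxonomy)
  )
}

#' Compute the three TIL score variants from counts
#'
#' `nTSa` = TILs per mm^2 of stroma (a density); `nTnS` = TILs per cell in
#' stroma; `nTnA` = TILs per cell anywhere (both fractions in `[0, 1]`).
#' Zero denominators propagate as missing values, never as 0.
#'
#' @param counts tibble with columns `n_til_stroma`, `n_cells_stroma`,
#'   `n_cells_total`, `stromal_area_mm2` (one or more rows).
#' @return Input with `nTSa`, `nTnS`, `nTnA` columns appended.
#' @export
score_variants <- function(counts) {
  dplyr::mutate(
    counts,
    nTSa = ifelse(.data$stromal_area_mm2 > 0,
                  .data$n_til_stroma / .data$stromal_area_mm2, NA_real_),
    nTnS = ifelse(.data$n_cells_stroma > 0,
                  .data$n_til_stroma / .data$n_cells_stroma, NA_real_),
    nTnA = ifelse(.data$n_cells_total > 0,
                  .data$n_til_stroma / .data$n_cells_total, NA_real_)
  )
}

#' Aggregate per-ROI counts into slide-level scores
#'
#' Two aggregation modes: `"global"` pools the raw counts over ROIs and
#' applies [score_variants()] once; `"saliency_weighted"` computes per-ROI
#' variant scores and averages them with the peritumoral-stroma saliency
#' as weight, skipping ROIs whose score is undefined. If every usable
#' weight is zero the unweighted mean is used with a warning.
#'
#' @param roi_table tibble of per-ROI counts + saliency ([roi_counts()]
#'   rows).
#' @param slide_id identifier carried into the output.
#' @return A `tq_slide_score` tibble: one row per variant x aggregation,
#'   columns `slide_id`, `variant`, `aggregation`, `score`, `n_rois`.
#' @export
aggregate_scores <- function(roi_table, slide_id = "slide") {
  stopifnot(nrow(roi_table) >= 1)
  pooled <- score_variants(tibble::tibble(
    n_til_stroma = sum(roi_table$n_til_stroma),
    n_cells_stroma = sum(roi_table$n_cells_stroma),
    n_cells_total = sum(roi_table$n_cells_total),
    stromal_area_mm2 = sum(roi_table$stromal_area_mm2)
  ))
  per_roi <- score_variants(roi_table)
  if (all(per_roi$saliency == 0)) {
    warning("all saliency weights are zero; falling back to unweighted means")
  }
  wavg <- function(s, w) {
    ok <- !is.na(s)
    if (!any(ok)) return(NA_real_)
    s <- s[ok]; w <- w[ok]
    if (sum(w) == 0) return(mean(s))
    sum(w * s) / sum(w)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(
      variant = c("nTSa", "nTnS", "nTnA"), aggregation = "global",
      score = c(pooled$nTSa, pooled$nTnS, pooled$nTnA)
    ),
    tibble::tibble(
      variant = c("nTSa", "nTnS", "nTnA"), aggregation = "saliency_weighted",
      score = c(
        wavg(per_roi$nTSa, per_roi$saliency),
        wavg(per_roi$nTnS, per_roi$saliency),
        wavg(per_roi$nTnA, per_roi$saliency)
      )
    )
  )
  out <- dplyr::mutate(out, slide_id = slide_id, n_rois = nrow(roi_table),
                       .before = 1)
  class(out) <- c("tq_slide_score", class(out))
  out
}

#' Calibrate computational scores against visual scores
#'
#' Both score lists are z-scored; slides whose z-disagreement
#' `z_visual - z_computational`, standardized by its own sd, exceeds 1.96
#' in magnitude are outliers. The inliers define a scaling factor by
#' linear regression with no intercept
#' (`k = sum(vis * comp) / sum(comp^2)`); calibrated scores `k * comp` are
#' returned for every slide -- outliers are excluded only from the fit,
#' never from downstream use.
#'
#' @param data tibble with one row per slide.
#' @param computational,visual column names (strings) of the two score
#'   lists.
#' @param z_threshold disagreement threshold in standardized units.
#' @return A `tq_calibration` object; see [tidy.tq_calibration()] and
#'   [glance.tq_calibration()].
#' @export
calibrate <- function(data, computational = "computational_score",
                      visual = "visual_score", z_threshold = 1.96) {
  comp <- data[[computational]]
  vis <- data[[visual]]
  stopifnot(length(comp) == length(vis), length(comp) >= 3)
  if (sd(comp) == 0 || sd(vis) == 0) {
    stop("zero variance in scores; cannot calibrate")
  }
  zc <- (comp - mean(comp)) / sd(comp)
  zv <- (vis - mean(vis)) / sd(vis)
  d <- zv - zc
  # perfect linear agreement leaves no disagreement to standardize
  zd <- if (sd(d) == 0) rep(0, length(d)) else d / sd(d)
  inlier <- abs(zd) <= z_threshold
  if (!any(inlier)) stop("all slides flagged as outliers; cannot calibrate")
  k <- sum(vis[inlier] * comp[inlier]) / sum(comp[inlier]^2)
  structure(
    list(
      k = k, inlier = inlier, z_disagreement = zd,
      computational = comp, visual = vis,
      calibrated = k * comp,
      slide_id = data[["slide_id"]] %||% as.character(seq_along(comp)),
      z_threshold = z_threshold
    ),
    class = "tq_calibration"
  )
}

#' @export
print.tq_calibration <- function(x, ...) {
  cat(
    "<tq_calibration> k = ", signif(x$k, 4), "; ",
    sum(!x$inlier), " outlier(s) of ", length(x$inlier), " slides\n",
    sep = ""
  )
  invisible(x)
}
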