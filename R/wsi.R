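#' Detect tissue on a slide thumbnail
#'
#' HSV rule: tissue pixels have saturation > 0.05 and value < 0.95,
#' morphologically closed with a small disc to fill pinholes.
#'
#' @param thumb H x W x 3 RGB array in `[0, 255]` (typically ~8 MPP).
#' @return Logical matrix.
#' @export
detect_tissue <- function(thumb) {
  d <- dim(thumb)
  hsv <- grDevices::rgb2hsv(
    r = c(thumb[, , 1]), g = c(thumb[, , 2]), b = c(thumb[, , 3]),
    maxColorValue = 255
  )
  m <- matrix(hsv["s", ] > 0.05 & hsv["v", ] < 0.95, d[1], d[2])
  closed <- EBImage::closing(
    EBImage::Image(m * 1), EBImage::makeBrush(5, shape = "disc")
  )
  matrix(as.numeric(closed) > 0.5, d[1], d[2])
}

#' Remove marker/ink artifacts from a tissue mask
#'
#' Connected components of the tissue mask whose hue histogram is
#' concentrated in a single bin (peak purity > 0.8) at high saturation are
#' typical of pen ink and are removed. If more than half of the mask would
#' disappear a warning is emitted (the mask is still returned).
#'
#' @param thumb RGB thumbnail matching the mask.
#' @param mask logical tissue mask from [detect_tissue()].
#' @param purity_threshold hue-histogram peak purity above which a
#'   component is called ink.
#' @param min_saturation mean saturation a component needs before it can
#'   be called ink.
#' @return Cleaned logical mask.
#' @export
exclude_artifacts <- function(thumb, mask, purity_threshold = 0.8,
                              min_saturation = 0.5) {
  stopifnot(all(dim(thumb)[1:2] == dim(mask)))
  lab <- .label4(mask)
  if (max(lab) == 0) return(mask)
  hsv <- grDevices::rgb2hsv(
    r = c(thumb[, , 1]), g = c(thumb[, , 2]), b = c(thumb[, , 3]),
    maxColorValue = 255
  )
  out <- mask
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    s <- hsv["s", idx]
    if (mean(s) < min_saturation) next
    bins <- floor(hsv["h", idx] * 12) %% 12
    purity <- max(tabulate(bins + 1, 12)) / length(idx)
    if (purity > purity_threshold) out[idx] <- FALSE
  }
  if (sum(out) < 0.5 * sum(mask)) {
    warning("artifact exclusion removed more than half of the tissue mask")
  }
  out
}

#' Tile a slide and rank tiles by informativeness
#'
#' Lays a non-overlapping grid of `tile_microns` tiles over the slide,
#' scores every tile that touches the cleaned tissue mask by
#' [informativeness()] at low resolution (`mpp_score`, default 2 MPP) and
#' returns the records sorted by score (descending), with grid row/column
#' as the deterministic tie-break. Tiles without tissue keep score 0 and
#' rank last.
#'
#' @param slide a `tq_slide`.
#' @param tile_microns tile footprint in microns (default 512).
#' @param mpp_score scoring resolution.
#' @param mask optional cleaned tissue mask (at `mask_mpp`); computed from
#'   the thumbnail when omitted.
#' @param mask_mpp resolution of `mask`.
#' @return Tibble of tile records: `tile_id`, `grid_row`, `grid_col`,
#'   `origin_x`, `origin_y` (level-0 pixels), `mpp_score`,
#'   `informativeness`, `rank`, `selected`, `model_index`, `saliency`.
#' @export
tile_and_rank <- function(slide, tile_microns = 512, mpp_score = 2.0,
                          mask = NULL, mask_mpp = 8) {
  tp0 <- as.integer(round(tile_microns / slide$mpp))   # tile in level-0 px
  if (is.null(mask)) {
    thumb <- slide_thumbnail(slide, mask_mpp)
    mask <- exclude_artifacts(thumb, detect_tissue(thumb))
  }
  sc <- mask_mpp / slide$mpp
  n_cols <- floor(slide$dims[1] / tp0)
  n_rows <- floor(slide$dims[2] / tp0)
  if (n_cols < 1 || n_rows < 1 || sum(mask) == 0) {
    warning("no tissue to tile")
    return(tibble::tibble(
      tile_id = character(), grid_row = integer(), grid_col = integer(),
      origin_x = numeric(), origin_y = numeric(), mpp_score = numeric(),
      informativeness = numeric(), rank = integer(), selected = logical(),
      model_index = integer(), saliency = numeric()
    ))
  }
  recs <- tidyr::expand_grid(grid_row = 0:(n_rows - 1),
                             grid_col = 0:(n_cols - 1))
  score_one <- function(gr, gc) {
    # mask footprint of this tile at thumbnail resolution
    mr <- floor(gr * tp0 / sc + 1):ceiling((gr + 1) * tp0 / sc)
    mc <- floor(gc * tp0 / sc + 1):ceiling((gc + 1) * tp0 / sc)
    mr <- mr[mr <= nrow(mask)]; mc <- mc[mc <= ncol(mask)]
    if (!any(mask[mr, mc])) return(0)
    tile <- read_region(slide, gc * tp0, gr * tp0, tp0, tp0, mpp_score)
    informativeness(tile)
  }
  recs$informativeness <-
    purrr::map2_dbl(recs$grid_row, recs$grid_col, score_one)
  recs <- dplyr::arrange(
    recs, dplyr::desc(.data$informativeness), .data$grid_row, .data$grid_col
  )
  dplyr::mutate(
    recs,
    tile_id = sprintf("tile_%d_%d", .data$grid_row, .data$grid_col),
    origin_x = .data$grid_col * tp0,
    origin_y = .data$grid_row * tp0,
    mpp_score = mpp_score,
    rank = dplyr::row_number() - 1L,
    selected = FALSE, model_index = NA_integer_, saliency = NA_real_,
    .before = 1
  ) |>
    dplyr::relocate("tile_id", "grid_row", "grid_col")
}

#' Select the top-k most informative tiles as ROIs
#'
#' The analysis budget is fixed (default 300 ROIs) so whole-slide runtime
#' is near-constant regardless of slide size.
#'
#' @param records ranked tile records from [tile_and_rank()].
#' @param k ROI budget.
#' @return Records with the first `min(k, n)` rows marked `selected`.
#' @export
select_rois <- function(records, k = 300L) {
  records$selected <- records$rank < k
  records
}

#' Assign selected ROIs to ensemble members cyclically
#'
#' Every `n_models`-th ROI (in informativeness order) goes to the same
#' cross-validation model: `model_index = rank mod n_models`.
#'
#' @param records records from [select_rois()].
#' @param n_models ensemble size (default 5).
#' @return Records with `model_index` set on selected rows.
#' @export
assign_models_cyclic <- function(records, n_models = 5L) {
  if (n_models < 1) stop("n_models must be >= 1")
  sel <- which(records$selected)
  records$model_index[sel] <- (seq_along(sel) - 1L) %% n_models
  records
}

#' Run ensemble inference over the selected ROIs of a slide
#'
#' Each selected ROI is read at 1 MPP (full tile footprint) and 0.5 MPP
#' (central half, the high-power field), forwarded through its assigned
#' ensemble member (`mode = "cyclic"`) or through all members with the
#' probability maps averaged (`mode = "all_models"`), and post-processed
#' into classified nucleus instances.
#'
#' @param slide a `tq_slide`.
#' @param models list of `tq_network` ensemble members.
#' @param records tile records after [assign_models_cyclic()].
#' @param mode `"cyclic"` or `"all_models"`.
#' @param min_instance_px minimum instance size for
#'   [extract_instances()].
#' @param taxonomy class taxonomy.
#' @return List of `tq_prediction` objects (one per selected ROI): tile
#'   metadata, HPF region class map and probabilities, constrained nucleus
#'   probabilities and the instance table.
#' @export
infer_slide <- function(slide, models, records,
                        mode = c("cyclic", "all_models"),
                        min_instance_px = 10L,
                        taxonomy = build_default_taxonomy()) {
  mode <- match.arg(mode)
  sel <- records[records$selected, ]
  cf <- models[[1]]$config
  tp0 <- as.integer(round(cf$roi_input_px * 1.0 / slide$mpp))
  preds <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    r <- sel[i, ]
    if (r$origin_x + tp0 > slide$dims[1] || r$origin_y + tp0 > slide$dims[2]) {
      stop("ROI ", r$tile_id, " exceeds slide extent at 1 MPP footprint")
    }
    rgb_10x <- read_region(slide, r$origin_x, r$origin_y, tp0, tp0, 1.0)
    q <- tp0 / 4
    rgb_20x_hpf <- read_region(slide, r$origin_x + q, r$origin_y + q,
                               tp0 / 2, tp0 / 2, 0.5)
    outs <- if (mode == "cyclic") {
      predict_roi(models[[r$model_index + 1L]], rgb_10x, rgb_20x_hpf)
    } else {
      all <- lapply(models, predict_roi, rgb_10x = rgb_10x,
                    rgb_20x_hpf = rgb_20x_hpf)
      avg <- all[[1]]
      for (f in c("roi_region_probs", "hpf_region_probs",
                  "nucleus_probs_unconstrained", "nucleus_probs_constrained",
                  "attention")) {
        avg[[f]] <- Reduce(`+`, lapply(all, `[[`, f)) / length(all)
      }
      avg
    }
    d <- dim(outs$hpf_region_probs)
    region_map <- matrix(
      max.col(matrix(outs$hpf_region_probs, d[1] * d[2], d[3]),
              ties.method = "first"),
      d[1], d[2]
    )
    inst <- extract_instances(outs$nucleus_probs_constrained,
                              min_size_px = min_instance_px,
                              taxonomy = taxonomy)
    preds[[i]] <- structure(
      list(
        tile_id = r$tile_id, origin_x = r$origin_x, origin_y = r$origin_y,
        model_index = r$model_index, mode = mode,
        region_map_hpf = region_map,
        hpf_region_probs = outs$hpf_region_probs,
        nucleus_probs_constrained = outs$nucleus_probs_constrained,
        instances = inst, mpp = 0.5
      ),
      class = "tq_prediction"
    )
  }
  preds
}
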