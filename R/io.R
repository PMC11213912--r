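#' Write an integer-coded mask as an 8-bit grayscale PNG
#'
#' Codes are stored as gray levels `code/255`, which round-trips
#' losslessly for taxonomy codes (0..6).
#'
#' @param mask integer matrix of class codes.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (any(mask < 0 | mask > 255)) stop("mask codes must lie in 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read an integer-coded mask PNG
#'
#' @param path PNG path (single-channel, 8-bit).
#' @param max_code if given, validate that every code is `<= max_code` and
#'   report offending codes by value.
#' @return Integer matrix of codes.
#' @export
read_mask <- function(path, max_code = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1 &&
        !all(img[, , 1] == img[, , 2] & img[, , 1] == img[, , 3])) {
      stop("mask PNG must be single-channel: ", path)
    }
    img <- img[, , 1]
  }
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  if (!is.null(max_code) && any(m > max_code)) {
    stop(
      "mask codes outside taxonomy (max ", max_code, "): found ",
      paste(sort(unique(m[m > max_code])), collapse = ", "), " in ", path
    )
  }
  m
}

#' Read an RGB image PNG as a 0..255 array
#' @param path PNG path.
#' @return H x W x 3 numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Serialize taxonomy, kernel, priors and pipeline constants to YAML
#'
#' @param path output file.
#' @param taxonomy,kernel,prior the class configuration.
#' @param constants named list of pipeline constants (see
#'   [default_run_config()]).
#' @export
write_run_config <- function(path, taxonomy = build_default_taxonomy(),
                             kernel = build_default_kernel(taxonomy),
                             prior = build_uniform_prior(kernel),
                             constants = default_run_config()) {
  cfg <- list(
    region_classes = as.list(taxonomy$region_classes),
    nucleus_classes = as.list(taxonomy$nucleus_classes),
    region_group = as.list(taxonomy$region_group),
    nucleus_group = as.list(taxonomy$nucleus_group),
    kernel = apply(kernel, 1, as.list, simplify = FALSE),
    prior = apply(prior, 1, as.list, simplify = FALSE),
    constants = constants
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path YAML path.
#' @return List with `taxonomy`, `kernel`, `prior`, `constants`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tax <- structure(
    list(
      region_classes = unlist(cfg$region_classes),
      nucleus_classes = unlist(cfg$nucleus_classes),
      region_group = unlist(cfg$region_group),
      nucleus_group = unlist(cfg$nucleus_group)
    ),
    class = "tq_taxonomy"
  )
  dn <- list(names(tax$region_classes), names(tax$nucleus_classes))
  K <- t(vapply(cfg$kernel, function(r) unlist(r), numeric(length(dn[[2]]))))
  P <- t(vapply(cfg$prior, function(r) unlist(r), numeric(length(dn[[2]]))))
  dimnames(K) <- dn
  dimnames(P) <- dn
  list(taxonomy = tax, kernel = K, prior = validate_prior(P, K),
       constants = cfg$constants)
}

#' Default pipeline constants
#'
#' All whole-slide constants in one place: scoring resolution (2 MPP),
#' tile footprint in microns, the fixed 300-ROI budget, the 32-micron
#' peritumoral-stroma distance, the minimum instance size, the 5-member
#' ensemble, and the survival-threshold constants exposed for downstream
#' use (10% stromal score, 3% nTnA).
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(
    mpp_score = 2.0, mpp_roi = 1.0, mpp_hpf = 0.5,
    tile_microns = 512, top_k = 300, saliency_distance_microns = 32,
    min_instance_px = 10, n_models = 5,
    stromal_score_threshold = 0.10, ntna_score_threshold = 0.03
  )
}

#' Save / load a network checkpoint
#'
#' One file holding the weights, the learned prior logits and the embedded
#' configuration.
#'
#' @param network a `tq_network`.
#' @param path checkpoint path (`.rds`).
#' @export
save_network <- function(network, path) {
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @return `load_network()` returns the `tq_network`.
#' @export
load_network <- function(path) {
  network <- readRDS(path)
  stopifnot(inherits(network, "tq_network"))
  network
}

#' Write a per-nucleus interchange table
#'
#' Fixed columns `(slide_id, roi_id, instance_id, x, y, class,
#' p_<class>...)`, 0-based pixel coordinates at 0.5 MPP.
#'
#' @param instances tibble from [extract_instances()].
#' @param path CSV path.
#' @param slide_id,roi_id identifiers prepended to each row.
#' @export
write_nuclei_csv <- function(instances, path, slide_id = "slide",
                             roi_id = "roi") {
  df <- dplyr::mutate(instances, slide_id = slide_id, roi_id = roi_id,
                      .before = 1)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a synthetic ROI directory or annotation-layout ROI into a `tq_roi`
#'
#' Expects an RGB image PNG, a region mask PNG over the full extent and
#' (optionally) a nucleus CSV whose annotations may cover only the central
#' portion of the field, matching the layout in which nuclei are annotated
#' within the central 256 x 256 of a 1024 x 1024 region mask.
#'
#' @param image_path RGB PNG at 0.5 MPP.
#' @param region_path region-mask PNG (taxonomy codes).
#' @param nuclei_path optional CSV with columns `instance_id, x, y, class`
#'   (0-based pixel centers at 0.5 MPP).
#' @param taxonomy class taxonomy for validation.
#' @return A `tq_roi` (without instance map; nuclei as point annotations).
#' @export
read_roi <- function(image_path, region_path, nuclei_path = NULL,
                     taxonomy = build_default_taxonomy()) {
  rgb <- read_image(image_path)
  region <- read_mask(region_path, max_code = max(taxonomy$region_classes))
  stopifnot(all(dim(rgb)[1:2] == dim(region)))
  n <- nrow(region)
  odd <- seq(1, n, 2)
  nuclei <- if (!is.null(nuclei_path)) {
    df <- tibble::as_tibble(read.csv(nuclei_path))
    stopifnot(all(c("instance_id", "x", "y", "class") %in% names(df)))
    df$class_code <- unname(taxonomy$nucleus_classes[df$class])
    if (anyNA(df$class_code)) stop("unknown nucleus class in ", nuclei_path)
    ridx <- cbind(round(df$y) + 1, round(df$x) + 1)
    df$region_code <- region[ridx]
    df
  } else {
    tibble::tibble(
      instance_id = integer(), class = character(), class_code = integer(),
      x = numeric(), y = numeric(), region_code = integer()
    )
  }
  structure(
    list(
      rgb_20x = rgb, rgb_10x = round(.box_downsample(rgb, 2L)),
      region_mask_20x = region, region_mask_10x = region[odd, odd],
      nucleus_instance_map_20x = matrix(0L, n, n),
      nucleus_classes = nuclei,
      mpp = 0.5, slide_id = "roi", hospital_id = NA_character_,
      origin_xy = c(0, 0)
    ),
    class = "tq_roi"
  )
}
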