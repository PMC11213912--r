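#' Parameters for the synthetic H&E generator
#'
#' The generator emulates the geometry of the annotation layout used for
#' training and validation: square ROIs at 0.5 MPP (20x objective) with a
#' paired 2x-downsampled 1 MPP view, a region mask over the six region
#' classes and non-overlapping nucleus instances over the six nucleus
#' classes. Color is formed by Beer-Lambert absorption from known stain
#' vectors, so rendered images deconvolve back to the generating
#' concentration maps.
#'
#' @param roi_size_px ROI side at 0.5 MPP (default 1024).
#' @param mpp microns per pixel of the 20x view (default 0.5).
#' @param region_layout one of `"half_plane"`, `"blobs"`, `"rings"`,
#'   `"stroma"` (pure stroma) or `"empty"` (background tile).
#' @param til_fraction probability that a stromal-compartment nucleus is a
#'   TIL (lymphocyte or plasma cell), in `[0, 1]`.
#' @param stromal_cellularity expected nuclei per mm^2 of stroma
#'   (default 3000; TILs-dense regions use twice this).
#' @param epithelial_cellularity expected nuclei per mm^2 of epithelium.
#' @param nucleus_radius_px mean and sd of the nucleus radius in pixels at
#'   0.5 MPP (class-specific multipliers apply).
#' @param tumor_coverage target tumor area fraction for the `"blobs"`
#'   layout.
#' @param stain_vectors 3x2 unit optical-density stain matrix.
#' @param background_rgb background color (white).
#' @param seed integer seed; same seed, same bytes out.
#' @return A `tq_synth_params` list.
#' @export
synth_params <- function(roi_size_px = 1024L, mpp = 0.5,
                         region_layout = c("blobs", "half_plane", "rings",
                                           "stroma", "empty"),
                         til_fraction = 0.3,
                         stromal_cellularity = 3000,
                         epithelial_cellularity = 6000,
                         nucleus_radius_px = c(mean = 6, sd = 1),
                         tumor_coverage = 0.35,
                         stain_vectors = default_stain_matrix(),
                         background_rgb = c(255, 255, 255),
                         seed = 1L) {
  region_layout <- match.arg(region_layout)
  if (roi_size_px <= 0) stop("roi_size_px must be positive")
  if (roi_size_px %% 4 != 0) stop("roi_size_px must be divisible by 4")
  if (til_fraction < 0 || til_fraction > 1) {
    stop("til_fraction must lie in [0, 1]")
  }
  nv <- sqrt(colSums(stain_vectors^2))
  if (any(abs(nv - 1) > 1e-6)) stop("stain vectors must be unit norm")
  if (abs(det(crossprod(stain_vectors))) < 1e-8) {
    stop("stain vectors must be linearly independent")
  }
  structure(
    list(
      roi_size_px = as.integer(roi_size_px), mpp = mpp,
      region_layout = region_layout, til_fraction = til_fraction,
      stromal_cellularity = stromal_cellularity,
      epithelial_cellularity = epithelial_cellularity,
      nucleus_radius_px = nucleus_radius_px,
      tumor_coverage = tumor_coverage,
      stain_vectors = stain_vectors, background_rgb = background_rgb,
      seed = as.integer(seed)
    ),
    class = "tq_synth_params"
  )
}

# region layout at 20x; integer matrix of taxonomy codes
synth_region_layout <- function(params) {
  n <- params$roi_size_px
  m <- matrix(3L, n, n)                       # stroma background
  lay <- params$region_layout
  if (lay == "empty") {
    m[] <- 6L
  } else if (lay == "stroma") {
    # pure stroma
  } else if (lay == "half_plane") {
    m[, seq_len(n / 2)] <- 1L
  } else if (lay == "blobs") {
    cover <- 0
    tries <- 0
    while (cover < params$tumor_coverage && tries < 8) {
      tries <- tries + 1
      cx <- runif(1, 0.2, 0.8) * n
      cy <- runif(1, 0.2, 0.8) * n
      a <- runif(1, 0.12, 0.22) * n
      b <- runif(1, 0.12, 0.22) * n
      th <- runif(1, 0, pi)
      m[ellipse_mask(n, cx, cy, a, b, th)] <- 1L
      cover <- mean(m == 1L)
    }
    # dense infiltrate band hugging the tumor boundary
    if (any(m == 1L)) {
      dtum <- EBImage::distmap(matrix(as.numeric(m != 1L), n, n))
      m[m == 3L & dtum > 0 & dtum <= 12] <- 4L
    }
    # strip of glass at the right edge
    m[, (n - n / 8 + 1):n] <- 6L
  } else if (lay == "rings") {
    cx <- n / 2
    cy <- n / 2
    r <- sqrt((row(m) - cy)^2 + (col(m) - cx)^2)
    m[r <= n / 6] <- 5L                       # necrotic core
    m[r > n / 6 & r <= n / 3] <- 1L           # cancer annulus
    m[r > n / 3 & r <= n / 3 + 10] <- 2L      # rim of residual normal epithelium
    m[r > 0.55 * n] <- 6L
  }
  m
}

ellipse_mask <- function(n, cx, cy, a, b, theta) {
  x <- col(matrix(0, n, n)) - cx
  y <- row(matrix(0, n, n)) - cy
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# class-specific appearance: radius multiplier, aspect, hematoxylin level
synth_nucleus_profile <- function(class) {
  switch(class,
    cancer = list(rmul = 1.4, aspect = 1.0, h = 0.90),
    normal_epithelium = list(rmul = 1.2, aspect = 1.0, h = 0.85),
    fibroblast = list(rmul = 1.0, aspect = 2.4, h = 0.80),
    lymphocyte = list(rmul = 0.8, aspect = 1.0, h = 1.25),
    plasma_cell = list(rmul = 0.9, aspect = 1.2, h = 1.10),
    debris = list(rmul = 0.7, aspect = 1.0, h = 0.45)
  )
}

synth_region_cellularity <- function(params, region) {
  switch(region,
    cancer = params$epithelial_cellularity,
    normal_epithelium = params$epithelial_cellularity,
    stroma = params$stromal_cellularity,
    tils_dense = 2 * params$stromal_cellularity,
    necrosis_debris = 0.5 * params$stromal_cellularity,
    empty = 0
  )
}

synth_sample_class <- function(params, region) {
  switch(region,
    cancer = "cancer",
    normal_epithelium = "normal_epithelium",
    stroma = ,
    tils_dense = {
      if (runif(1) < params$til_fraction) {
        if (runif(1) < 0.75) "lymphocyte" else "plasma_cell"
      } else {
        "fibroblast"
      }
    },
    necrosis_debris = {
      u <- runif(1)
      if (u < 0.85) "debris" else if (u < 0.95) "lymphocyte" else "plasma_cell"
    }
  )
}

#' Generate one synthetic ROI with exact ground truth
#'
#' Draws the region layout, places non-overlapping nucleus instances by
#' dart throwing (each candidate keeps its class admissible under the
#' default compatibility kernel by construction: classes are sampled from
#' the region the nucleus sits in, and a nucleus must fit entirely inside
#' its region), then renders RGB by Beer-Lambert absorption
#' (`rgb = 255 * exp(-S %*% c)`) with hematoxylin concentrated in nuclei
#' and eosin in stroma/cytoplasm. The 1 MPP view is a 2x box-filter
#' downsample; masks are nearest-neighbor subsampled.
#'
#' @param params a [synth_params()] object.
#' @param slide_id,hospital_id,origin_xy provenance fields.
#' @return A `tq_roi` list: `rgb_20x`, `rgb_10x`, `region_mask_20x`,
#'   `region_mask_10x`, `nucleus_instance_map_20x`, `nucleus_classes`
#'   (tibble), `mpp`, provenance, and the concentration maps used for
#'   rendering (`conc_h`, `conc_e`).
#' @export
generate_roi <- function(params, slide_id = "synthetic_slide",
                         hospital_id = "hospital_1", origin_xy = c(0, 0)) {
  stopifnot(inherits(params, "tq_synth_params"))
  set.seed(params$seed)
  tax <- build_default_taxonomy()
  n <- params$roi_size_px
  region <- synth_region_layout(params)
  occupied <- matrix(FALSE, n, n)
  imap <- matrix(0L, n, n)
  recs <- list()
  inst <- 0L
  rmean <- params$nucleus_radius_px[["mean"]]
  rsd <- params$nucleus_radius_px[["sd"]]

  for (rname in names(tax$region_classes)) {
    code <- tax$region_classes[[rname]]
    pix <- which(region == code)
    cellularity <- synth_region_cellularity(params, rname)
    if (length(pix) == 0 || cellularity <= 0) next
    area_mm2 <- length(pix) * (params$mpp / 1000)^2
    n_target <- rpois(1, area_mm2 * cellularity)
    for (k in seq_len(n_target)) {
      class <- synth_sample_class(params, rname)
      prof <- synth_nucleus_profile(class)
      rad <- max(2, rnorm(1, rmean * prof$rmul, rsd))
      a <- rad * sqrt(prof$aspect)
      b <- rad / sqrt(prof$aspect)
      th <- if (prof$aspect > 1) runif(1, 0, pi) else 0
      placed <- FALSE
      for (try in seq_len(50)) {
        p <- pix[sample.int(length(pix), 1)]
        ci <- (p - 1) %% n + 1
        cj <- (p - 1) %/% n + 1
        ext <- ceiling(max(a, b) + 2)
        if (ci - ext < 1 || ci + ext > n || cj - ext < 1 || cj + ext > n) next
        ii <- (ci - ext):(ci + ext)
        jj <- (cj - ext):(cj + ext)
        xr <- outer(rep(1, length(ii)), jj - cj) * cos(th) +
          outer(ii - ci, rep(1, length(jj))) * sin(th)
        yr <- -outer(rep(1, length(ii)), jj - cj) * sin(th) +
          outer(ii - ci, rep(1, length(jj))) * cos(th)
        inside <- (xr / a)^2 + (yr / b)^2 <= 1
        # exclusion ring one pixel wider keeps instances 4-disconnected
        near <- (xr / (a + 1.6))^2 + (yr / (b + 1.6))^2 <= 1
        sub_reg <- region[ii, jj]
        sub_occ <- occupied[ii, jj]
        if (any(sub_reg[inside] != code) || any(sub_occ[near])) next
        inst <- inst + 1L
        occ <- sub_occ
        occ[inside] <- TRUE
        occupied[ii, jj] <- occ
        sub_map <- imap[ii, jj]
        sub_map[inside] <- inst
        imap[ii, jj] <- sub_map
        recs[[inst]] <- list(
          instance_id = inst, class = class,
          class_code = tax$nucleus_classes[[class]],
          x = cj - 1, y = ci - 1, region_code = code, h_level = prof$h
        )
        placed <- TRUE
        break
      }
      if (!placed) next
    }
  }

  nucleus_classes <- if (inst == 0) {
    tibble::tibble(
      instance_id = integer(), class = character(), class_code = integer(),
      x = numeric(), y = numeric(), region_code = integer()
    )
  } else {
    dplyr::bind_rows(lapply(recs, function(r) {
      tibble::tibble(
        instance_id = r$instance_id, class = r$class,
        class_code = r$class_code, x = r$x, y = r$y,
        region_code = r$region_code
      )
    }))
  }

  # concentration maps: hematoxylin in nuclei, eosin in stroma/cytoplasm
  tissue <- region != 6L
  conc_h <- matrix(0, n, n)
  conc_h[tissue] <- 0.04
  if (inst > 0) {
    h_levels <- vapply(recs, function(r) r$h_level, numeric(1))
    h_jit <- pmax(h_levels + rnorm(inst, 0, 0.05), 0.1)
    nz <- imap > 0
    conc_h[nz] <- h_jit[imap[nz]]
  }
  conc_e <- matrix(0, n, n)
  conc_e[region %in% c(1L, 2L)] <- 0.45
  conc_e[region == 3L] <- 0.75
  conc_e[region == 4L] <- 0.70
  conc_e[region == 5L] <- 0.30
  conc_e[imap > 0] <- conc_e[imap > 0] * 0.3
  conc_e[tissue] <- pmax(conc_e[tissue] + rnorm(sum(tissue), 0, 0.02), 0)

  S <- params$stain_vectors
  rgb_20x <- array(0, c(n, n, 3))
  for (k in 1:3) {
    rgb_20x[, , k] <- round(255 * exp(-(S[k, 1] * conc_h + S[k, 2] * conc_e)))
  }
  rgb_10x <- round(.box_downsample(rgb_20x, 2L))
  odd <- seq(1, n, 2)

  structure(
    list(
      rgb_20x = rgb_20x, rgb_10x = rgb_10x,
      region_mask_20x = region, region_mask_10x = region[odd, odd],
      nucleus_instance_map_20x = imap, nucleus_classes = nucleus_classes,
      conc_h = conc_h, conc_e = conc_e,
      mpp = params$mpp, slide_id = slide_id, hospital_id = hospital_id,
      origin_xy = origin_xy, params = params
    ),
    class = "tq_roi"
  )
}

#' Generate a synthetic multi-tile slide with truth tables
#'
#' Writes a grid of tiles (`tile_<row>_<col>.png` plus
#' `tile_<row>_<col>.region.png`), a per-nucleus `nuclei.csv`, per-tile
#' ground-truth counts (`truth_counts.csv`) and `slide.json` metadata. A
#' configurable number of tiles are pure background to exercise
#' informativeness ranking; the rest are stroma tiles or tumor-bearing
#' blob tiles in proportion `tumor_coverage`.
#'
#' @param n_tiles number of tiles (near-square grid, row-major).
#' @param params a [synth_params()]; `roi_size_px` is the tile size.
#' @param tumor_coverage fraction of tissue tiles that carry tumor blobs.
#' @param out_dir output directory (created).
#' @param n_background number of pure-background tiles.
#' @param slide_id,hospital_id metadata.
#' @return The slide directory path, invisibly; side effect: files.
#' @export
generate_slide <- function(n_tiles, params, tumor_coverage = 0.5,
                           out_dir, n_background = round(0.25 * n_tiles),
                           slide_id = "synthetic_slide",
                           hospital_id = "hospital_1") {
  stopifnot(n_tiles >= 1, n_background <= n_tiles)
  set.seed(params$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nc <- ceiling(sqrt(n_tiles))
  nr <- ceiling(n_tiles / nc)
  ord <- sample.int(n_tiles)
  type <- rep("stroma", n_tiles)
  type[ord[seq_len(n_background)]] <- "empty"
  tissue_idx <- ord[-seq_len(n_background)]
  n_tumor <- round(tumor_coverage * length(tissue_idx))
  if (n_tumor > 0) type[tissue_idx[seq_len(n_tumor)]] <- "blobs"

  nuclei <- list()
  truth <- list()
  tax <- build_default_taxonomy()
  for (t in seq_len(n_tiles)) {
    gr <- (t - 1) %/% nc
    gc <- (t - 1) %% nc
    tile_seed <- (params$seed + 7919 * t) %% 2147483647L
    tp <- params
    tp$region_layout <- type[t]
    tp$seed <- as.integer(tile_seed)
    roi <- generate_roi(tp, slide_id = slide_id, hospital_id = hospital_id,
                        origin_xy = c(gc, gr) * params$roi_size_px)
    base <- file.path(out_dir, sprintf("tile_%d_%d", gr, gc))
    png::writePNG(pmin(pmax(roi$rgb_20x / 255, 0), 1), paste0(base, ".png"))
    write_mask(roi$region_mask_20x, paste0(base, ".region.png"))
    if (nrow(roi$nucleus_classes) > 0) {
      nuclei[[t]] <- dplyr::mutate(
        roi$nucleus_classes,
        tile = sprintf("tile_%d_%d", gr, gc), .before = 1
      )
    }
    truth[[t]] <- roi_truth_counts(roi, tax) |>
      dplyr::mutate(tile = sprintf("tile_%d_%d", gr, gc), .before = 1)
  }
  nuc_df <- if (length(nuclei)) dplyr::bind_rows(nuclei) else
    tibble::tibble(tile = character(), instance_id = integer(),
                   class = character(), class_code = integer(),
                   x = numeric(), y = numeric(), region_code = integer())
  write.csv(nuc_df, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
  write.csv(dplyr::bind_rows(truth), file.path(out_dir, "truth_counts.csv"),
            row.names = FALSE)
  meta <- list(
    slide_id = slide_id, hospital_id = hospital_id, mpp = params$mpp,
    grid = c(nr, nc), tile_px = params$roi_size_px, n_tiles = n_tiles,
    seed = params$seed, tile_type = type
  )
  jsonlite::write_json(meta, file.path(out_dir, "slide.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

# exact per-tile score components from generator truth
roi_truth_counts <- function(roi, taxonomy = build_default_taxonomy()) {
  nc <- roi$nucleus_classes
  stromal_codes <- taxonomy$region_classes[c("stroma", "tils_dense")]
  til_codes <- taxonomy$nucleus_classes[c("lymphocyte", "plasma_cell")]
  debris_code <- taxonomy$nucleus_classes[["debris"]]
  viable <- nc[nc$class_code != debris_code, ]
  in_stroma <- viable$region_code %in% stromal_codes
  tibble::tibble(
    n_til_stroma = sum(in_stroma & viable$class_code %in% til_codes),
    n_cells_stroma = sum(in_stroma),
    n_cells_total = nrow(viable),
    stromal_area_mm2 = sum(roi$region_mask_20x %in% stromal_codes) *
      (roi$mpp / 1000)^2
  )
}

#' Generate a synthetic calibration cohort
#'
#' Each slide carries a computational score equal to its true TIL fraction
#' and a visual score `scale * true + noise`. `n_outliers` slides get a
#' large disagreement injected (alternating sign) so they exceed the
#' 1.96-SD z-disagreement rule used by [calibrate()].
#'
#' @param n_slides cohort size.
#' @param true_scores per-slide true fractions (default drawn uniform on
#'   `[0.05, 0.6]`).
#' @param visual_noise_sd Gaussian noise sd on the visual score.
#' @param scale linear scale between computational and visual scores.
#' @param n_outliers number of injected outliers (< `n_slides`).
#' @param seed integer seed.
#' @return Tibble: `slide_id`, `true_score`, `computational_score`,
#'   `visual_score`, `injected_outlier`.
#' @export
generate_cohort <- function(n_slides, true_scores = NULL,
                            visual_noise_sd = 0.02, scale = 1.8,
                            n_outliers = 0L, seed = 1L) {
  set.seed(seed)
  if (is.null(true_scores)) true_scores <- runif(n_slides, 0.05, 0.6)
  stopifnot(length(true_scores) == n_slides)
  if (n_outliers >= n_slides) stop("n_outliers must be < n_slides")
  visual <- scale * true_scores + rnorm(n_slides, 0, visual_noise_sd)
  out_idx <- if (n_outliers > 0) sample.int(n_slides, n_outliers) else integer()
  if (n_outliers > 0) {
    delta <- 3.5 * stats::sd(scale * true_scores) + 10 * visual_noise_sd
    signs <- rep(c(1, -1), length.out = n_outliers)
    visual[out_idx] <- visual[out_idx] + signs * delta
  }
  tibble::tibble(
    slide_id = sprintf("slide_%03d", seq_len(n_slides)),
    true_score = true_scores,
    computational_score = true_scores,
    visual_score = visual,
    injected_outlier = seq_len(n_slides) %in% out_idx
  )
}
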