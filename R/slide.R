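#' Open a synthetic tile-directory slide
#'
#' The tile-directory backend is first-class: a directory written by
#' [generate_slide()] (tile PNGs at native 0.5 MPP plus `slide.json`
#' metadata) behaves like a pyramidal slide. Regions at coarser
#' resolutions are produced by integer box-filter downsampling, reading
#' only the tiles that intersect the request.
#'
#' @param path slide directory containing `slide.json`.
#' @return A `tq_slide` handle with `mpp`, `grid`, `tile_px` and level-0
#'   `dims` (width, height in pixels).
#' @export
slide_handle <- function(path) {
  meta_path <- file.path(path, "slide.json")
  if (!file.exists(meta_path)) stop("no slide.json under ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (meta$mpp <= 0) stop("slide mpp must be positive")
  structure(
    list(
      path = path, mpp = meta$mpp, grid = meta$grid,
      tile_px = meta$tile_px, n_tiles = meta$n_tiles,
      dims = c(meta$grid[2], meta$grid[1]) * meta$tile_px,
      meta = meta
    ),
    class = "tq_slide"
  )
}

#' @export
print.tq_slide <- function(x, ...) {
  cat(
    "<tq_slide> ", x$dims[1], "x", x$dims[2], " px @ ", x$mpp, " MPP (",
    x$grid[1], "x", x$grid[2], " tiles of ", x$tile_px, " px)\n", sep = ""
  )
  invisible(x)
}

#' Read a region from a slide at a requested resolution
#'
#' @param slide a `tq_slide`.
#' @param x0,y0 origin in level-0 (native-resolution) pixels, 0-based.
#' @param w,h extent in level-0 pixels.
#' @param mpp_out requested microns per pixel; must be an integer multiple
#'   of the native resolution and at least as coarse.
#' @return H x W x 3 array in `[0, 255]`; missing tiles read as white.
#' @export
read_region <- function(slide, x0, y0, w, h, mpp_out = slide$mpp) {
  f <- mpp_out / slide$mpp
  if (f < 1 || abs(f - round(f)) > 1e-9) {
    stop("requested resolution must be an integer multiple of native ",
         slide$mpp, " MPP")
  }
  f <- as.integer(round(f))
  if (x0 < 0 || y0 < 0 || x0 + w > slide$dims[1] || y0 + h > slide$dims[2]) {
    stop("requested region exceeds slide extent")
  }
  out <- array(255, c(h, w, 3))
  tp <- slide$tile_px
  nc <- slide$grid[2]
  t0c <- floor(x0 / tp); t1c <- floor((x0 + w - 1) / tp)
  t0r <- floor(y0 / tp); t1r <- floor((y0 + h - 1) / tp)
  for (tr in t0r:t1r) {
    for (tc in t0c:t1c) {
      idx <- tr * nc + tc + 1
      if (idx > slide$n_tiles) next
      p <- file.path(slide$path, sprintf("tile_%d_%d.png", tr, tc))
      if (!file.exists(p)) next
      img <- read_image(p)
      # overlap of this tile with the request, in level-0 coordinates
      ox0 <- max(x0, tc * tp); ox1 <- min(x0 + w, (tc + 1) * tp)
      oy0 <- max(y0, tr * tp); oy1 <- min(y0 + h, (tr + 1) * tp)
      if (ox1 <= ox0 || oy1 <= oy0) next
      src_r <- (oy0 - tr * tp + 1):(oy1 - tr * tp)
      src_c <- (ox0 - tc * tp + 1):(ox1 - tc * tp)
      dst_r <- (oy0 - y0 + 1):(oy1 - y0)
      dst_c <- (ox0 - x0 + 1):(ox1 - x0)
      out[dst_r, dst_c, ] <- img[src_r, src_c, ]
    }
  }
  if (f > 1) out <- .box_downsample(out, f)
  out
}

#' Slide thumbnail for tissue detection
#'
#' @param slide a `tq_slide`.
#' @param mpp_out thumbnail resolution (default 8 MPP).
#' @return RGB array at the requested resolution.
#' @export
slide_thumbnail <- function(slide, mpp_out = 8) {
  read_region(slide, 0, 0, slide$dims[1], slide$dims[2], mpp_out)
}
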