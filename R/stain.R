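#' Convert an RGB image to optical density
#'
#' Beer-Lambert transmission: `od = -log10((rgb + 1) / 256)`, elementwise
#' and nonnegative; white (255) maps to ~0 and black to `log10(256)`.
#'
#' @param rgb numeric array (H x W x 3) or matrix/vector with values in
#'   `[0, 255]`.
#' @return Array of the same shape with optical densities.
#' @export
rgb_to_od <- function(rgb) {
  -log10((rgb + 1) / 256)
}

#' Inverse of [rgb_to_od()]
#' @param od nonnegative optical densities.
#' @return RGB values in `[0, 255]` (continuous, not rounded).
#' @export
od_to_rgb <- function(od) {
  256 * 10^(-od) - 1
}

#' Reference H&E stain matrix
#'
#' Columns are unit optical-density vectors for hematoxylin and eosin, the
#' widely used reference pair (`[0.65, 0.70, 0.29]` and `[0.07, 0.99, 0.11]`,
#' normalized). Used to seed the synthetic renderer and as fallback when
#' per-tile estimation is impossible.
#'
#' @return 3x2 matrix with columns `hematoxylin`, `eosin`.
#' @export
default_stain_matrix <- function() {
  S <- cbind(
    hematoxylin = c(0.65, 0.70, 0.29),
    eosin = c(0.07, 0.99, 0.11)
  )
  sweep(S, 2, sqrt(colSums(S^2)), "/")
}

#' Tissue mask for masked stain estimation
#'
#' A pixel participates in stain estimation iff its mean RGB is below 220
#' (not white space) and its optical-density magnitude exceeds 0.05. This is
#' the "masked" part of the masked Macenko routine.
#'
#' @param rgb H x W x 3 array in `[0, 255]`.
#' @return Logical H x W matrix.
#' @export
tissue_mask_for_stains <- function(rgb) {
  mu <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  od <- rgb_to_od(rgb)
  odmag <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2)
  mu < 220 & odmag > 0.05
}

#' Estimate the stain matrix by the Macenko method
#'
#' Projects masked optical-density pixels onto the plane of their top two
#' singular vectors and takes robust angular extremes (default 1st/99th
#' percentile) as the stain directions. The hematoxylin column is the one
#' with the larger red/blue OD ratio (hematoxylin transmits blue light);
#' columns are unit-norm and must be more than 10 degrees apart.
#'
#' @param od H x W x 3 optical-density array.
#' @param mask logical matrix from [tissue_mask_for_stains()].
#' @param angle_percentiles robust extremes of the angular distribution.
#' @return 3x2 stain matrix, hematoxylin first.
#' @export
estimate_stain_matrix <- function(od, mask, angle_percentiles = c(1, 99)) {
  X <- cbind(od[, , 1][mask], od[, , 2][mask], od[, , 3][mask])
  if (nrow(X) < 100) {
    stop(
      "too few masked pixels (", nrow(X),
      ") for stain estimation; fall back to default_stain_matrix()"
    )
  }
  sv <- svd(X, nu = 0, nv = 2)
  V <- sv$v                                   # 3 x 2 basis of the stain plane
  proj <- X %*% V
  # orient the basis so projections land in a half-plane, then take angular
  # extremes; flip basis vectors toward positive mean projection
  for (k in 1:2) if (mean(proj[, k]) < 0) {
    V[, k] <- -V[, k]
    proj[, k] <- -proj[, k]
  }
  ang <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(ang, angle_percentiles / 100, names = FALSE)
  v1 <- V %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- V %*% c(cos(qs[2]), sin(qs[2]))
  v1 <- abs(v1) / sqrt(sum(v1^2))             # OD vectors are nonnegative
  v2 <- abs(v2) / sqrt(sum(v2^2))
  sep <- acos(pmin(1, sum(v1 * v2))) * 180 / pi
  if (sep < 10) {
    stop("stain vectors nearly parallel (", round(sep, 2), " degrees apart)")
  }
  # hematoxylin absorbs red/green and transmits blue, so its OD vector has
  # the larger red/blue ratio (eosin's OD is concentrated in green)
  if (v1[1] / v1[3] >= v2[1] / v2[3]) S <- cbind(v1, v2) else S <- cbind(v2, v1)
  dimnames(S) <- list(c("r", "g", "b"), c("hematoxylin", "eosin"))
  S
}

#' Unmix optical densities into stain concentrations
#'
#' Per-pixel least squares via the pseudoinverse of the stain matrix;
#' negative concentrations are clipped to zero.
#'
#' @param od H x W x 3 optical-density array.
#' @param S 3x2 stain matrix.
#' @return List with `H` and `E` concentration matrices (H x W).
#' @export
deconvolve <- function(od, S) {
  if (abs(det(crossprod(S))) < 1e-12) stop("singular stain matrix")
  pinv <- solve(crossprod(S), t(S))           # 2 x 3
  d <- dim(od)
  X <- cbind(c(od[, , 1]), c(od[, , 2]), c(od[, , 3]))
  C <- pmax(X %*% t(pinv), 0)
  list(
    H = matrix(C[, 1], d[1], d[2]),
    E = matrix(C[, 2], d[1], d[2])
  )
}

#' Tile informativeness score
#'
#' The product of the mean hematoxylin and mean eosin concentrations over
#' tissue pixels. Tiles rich in both cellular (hematoxylin) and acellular
#' (eosin) material -- i.e. peritumoral stroma -- score highest; pure-stain
#' or empty tiles score near zero. Tiles with under 5% tissue return 0.
#'
#' @param rgb H x W x 3 tile in `[0, 255]`.
#' @param fallback_stains stain matrix used when per-tile estimation fails.
#' @return Nonnegative scalar.
#' @export
informativeness <- function(rgb, fallback_stains = default_stain_matrix()) {
  mask <- tissue_mask_for_stains(rgb)
  if (mean(mask) < 0.05) return(0)
  od <- rgb_to_od(rgb)
  S <- tryCatch(
    estimate_stain_matrix(od, mask),
    error = function(e) fallback_stains
  )
  conc <- deconvolve(od, S)
  max(mean(conc$H[mask]) * mean(conc$E[mask]), 0)
}
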