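#' Class taxonomy for tissue regions and cell nuclei
#'
#' The fixed vocabularies used throughout the package: six tissue-region
#' classes segmented at 10x objective (1 MPP) and six nucleus classes
#' classified at 20x objective (0.5 MPP). Integer code 0 is reserved in both
#' vocabularies for unannotated/ignore (regions) and background (nuclei), so
#' masks double as loss-weight masks. Each class maps to exactly one
#' superclass in `{epithelium, stroma, TILs, other}`; the superclasses are
#' the practical ground truth for evaluation (cancer and normal epithelium
#' merge into epithelium; lymphocytes and plasma cells are the TILs).
#'
#' @return An object of class `tq_taxonomy`: a list with `region_classes`,
#'   `nucleus_classes` (named integer vectors, codes 1..6), `region_group`
#'   and `nucleus_group` (named character vectors onto the superclasses).
#' @examples
#' tax <- build_default_taxonomy()
#' tax$nucleus_group[["lymphocyte"]]
#' @export
build_default_taxonomy <- function() {
  region_classes <- c(
    cancer = 1L, normal_epithelium = 2L, stroma = 3L,
    tils_dense = 4L, necrosis_debris = 5L, empty = 6L
  )
  nucleus_classes <- c(
    cancer = 1L, normal_epithelium = 2L, fibroblast = 3L,
    lymphocyte = 4L, plasma_cell = 5L, debris = 6L
  )
  region_group <- c(
    cancer = "epithelium", normal_epithelium = "epithelium",
    stroma = "stroma", tils_dense = "stroma",
    necrosis_debris = "other", empty = "other"
  )
  nucleus_group <- c(
    cancer = "epithelium", normal_epithelium = "epithelium",
    fibroblast = "stroma", lymphocyte = "TILs",
    plasma_cell = "TILs", debris = "other"
  )
  structure(
    list(
      region_classes = region_classes, nucleus_classes = nucleus_classes,
      region_group = region_group, nucleus_group = nucleus_group
    ),
    class = "tq_taxonomy"
  )
}

#' Map class labels to superclasses
#'
#' @param taxonomy a [build_default_taxonomy()] object.
#' @param labels character vector of region or nucleus class labels.
#' @param what `"region"` or `"nucleus"`.
#' @return Character vector of superclasses in
#'   `{epithelium, stroma, TILs, other}`.
#' @export
class_group <- function(taxonomy, labels, what = c("region", "nucleus")) {
  what <- match.arg(what)
  map <- if (what == "region") taxonomy$region_group else taxonomy$nucleus_group
  unknown <- setdiff(labels, names(map))
  if (length(unknown) > 0) {
    stop("unknown ", what, " class(es): ", paste(unknown, collapse = ", "))
  }
  unname(map[labels])
}

#' Default region-nucleus compatibility kernel
#'
#' A binary matrix `K[region, nucleus]` of biologically admissible
#' co-occurrences: 1 where a nucleus class may occur inside a region class,
#' 0 where it is prohibited (e.g. a fibroblast nucleus inside a tumor
#' region). Epithelial regions prohibit fibroblasts; stromal regions
#' (stroma, TILs-dense) prohibit epithelial nuclei; necrosis/debris admits
#' debris and the mononuclear infiltrate often found at its margins; empty
#' regions carry no evidence and admit everything.
#'
#' @param taxonomy a [build_default_taxonomy()] object.
#' @return 6x6 binary matrix with region rows and nucleus columns (named).
#' @export
build_default_kernel <- function(taxonomy) {
  rn <- names(taxonomy$region_classes)
  cn <- names(taxonomy$nucleus_classes)
  K <- matrix(1, length(rn), length(cn), dimnames = list(rn, cn))
  K["cancer", "fibroblast"] <- 0
  K["normal_epithelium", "fibroblast"] <- 0
  K["stroma", c("cancer", "normal_epithelium")] <- 0
  K["tils_dense", c("cancer", "normal_epithelium")] <- 0
  K["necrosis_debris", c("cancer", "normal_epithelium", "fibroblast")] <- 0
  # debris material spills beyond necrotic regions but not into epithelium
  K["cancer", "debris"] <- 0
  K["normal_epithelium", "debris"] <- 0
  stopifnot(all(rowSums(K) >= 1))
  K
}

#' Uniform prior over admissible nucleus classes per region
#'
#' @param kernel a compatibility kernel from [build_default_kernel()].
#' @return Row-stochastic matrix, zero on prohibited entries.
#' @export
build_uniform_prior <- function(kernel) {
  sweep(kernel, 1, rowSums(kernel), "/")
}

#' Validate and renormalize a prior matrix against a kernel
#'
#' Masks the prior by the kernel and renormalizes each row to sum to one.
#' A region whose admissible prior mass is entirely zero is a configuration
#' error and is reported by name.
#'
#' @param P nonnegative matrix `[region, nucleus]`.
#' @param kernel binary compatibility kernel of the same shape.
#' @return The masked, row-stochastic prior.
#' @export
validate_prior <- function(P, kernel) {
  stopifnot(all(dim(P) == dim(kernel)))
  if (any(P < 0)) stop("prior matrix must be nonnegative")
  P <- P * kernel
  rs <- rowSums(P)
  if (any(rs == 0)) {
    bad <- rownames(kernel)[rs == 0] %||% which(rs == 0)
    stop(
      "prior row(s) with zero admissible mass after kernel masking: ",
      paste(bad, collapse = ", ")
    )
  }
  out <- sweep(P, 1, rs, "/")
  dimnames(out) <- dimnames(kernel)
  out
}

#' Display palette for integer-coded masks
#'
#' @param taxonomy a [build_default_taxonomy()] object.
#' @param what `"region"` or `"nucleus"`.
#' @return Tibble with `code`, `class`, `color` (hex).
#' @export
mask_palette <- function(taxonomy, what = c("region", "nucleus")) {
  what <- match.arg(what)
  cls <- if (what == "region") taxonomy$region_classes else taxonomy$nucleus_classes
  cols <- if (what == "region") {
    c("#d62728", "#ff9896", "#2ca02c", "#98df8a", "#8c564b", "#f0f0f0")
  } else {
    c("#d62728", "#ff9896", "#2ca02c", "#1f77b4", "#9467bd", "#8c564b")
  }
  tibble::tibble(
    code = c(0L, unname(cls)),
    class = c(if (what == "region") "unannotated" else "background", names(cls)),
    color = c("#000000", cols)
  )
}
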