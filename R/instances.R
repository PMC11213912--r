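#' Extract classified nucleus instances from constrained probabilities
#'
#' Panoptic post-processing: foreground is every pixel whose argmax is not
#' background; 4-connected foreground components become instances;
#' components smaller than `min_size_px` are dropped. Instance class
#' probabilities are the mean per-pixel constrained class probabilities
#' over the component (renormalized over the six nucleus classes) and the
#' instance class is their argmax, ties broken toward the lower class code.
#'
#' @param probs H x W x (1 + C) constrained probabilities, background
#'   channel first.
#' @param min_size_px minimum component size in pixels (default 10 at
#'   0.5 MPP).
#' @param taxonomy class taxonomy used to label classes.
#' @return Tibble with one row per instance: `instance_id`, `pixel_count`,
#'   `x`, `y` (0-based centroid, 0.5 MPP pixels), `class_code`, `class`,
#'   and `p_<class>` probability columns.
#' @export
extract_instances <- function(probs, min_size_px = 10L,
                              taxonomy = build_default_taxonomy()) {
  d <- dim(probs)
  ncls <- d[3] - 1L
  pm <- matrix(probs, d[1] * d[2], d[3])
  am <- max.col(pm, ties.method = "first")
  fg <- matrix(am != 1L, d[1], d[2])
  lab <- .label4(fg)
  n_lab <- max(lab)
  empty <- tibble::tibble(
    instance_id = integer(), pixel_count = integer(),
    x = numeric(), y = numeric(), class_code = integer(), class = character()
  )
  if (n_lab == 0) {
    pcols <- matrix(numeric(), 0, ncls)
    colnames(pcols) <- paste0("p_", names(taxonomy$nucleus_classes))
    return(dplyr::bind_cols(empty, tibble::as_tibble(pcols)))
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  sizes <- tabulate(lv, n_lab)
  keep <- which(sizes >= min_size_px)
  if (length(keep) == 0) {
    pcols <- matrix(numeric(), 0, ncls)
    colnames(pcols) <- paste0("p_", names(taxonomy$nucleus_classes))
    return(dplyr::bind_cols(empty, tibble::as_tibble(pcols)))
  }
  rows <- (idx - 1L) %% d[1]          # 0-based
  cols <- (idx - 1L) %/% d[1]
  # labels from .label4 are consecutive 1..n_lab, so rowsum keeps order
  cy <- rowsum(rows, lv)[, 1] / sizes
  cx <- rowsum(cols, lv)[, 1] / sizes
  # mean class probabilities (channels 2..) per component
  P <- matrix(0, n_lab, ncls)
  for (k in seq_len(ncls)) {
    P[, k] <- rowsum(pm[idx, k + 1L], lv)[, 1]
  }
  P <- P / rowSums(P)
  out <- tibble::tibble(
    instance_id = seq_along(keep),
    pixel_count = sizes[keep],
    x = unname(cx[keep]),
    y = unname(cy[keep]),
    class_code = max.col(P[keep, , drop = FALSE], ties.method = "first")
  )
  out$class <- names(taxonomy$nucleus_classes)[out$class_code]
  pcols <- P[keep, , drop = FALSE]
  colnames(pcols) <- paste0("p_", names(taxonomy$nucleus_classes))
  dplyr::bind_cols(out, tibble::as_tibble(pcols))
}

# integer map of nucleus class codes (0 background) for a tq_roi sample
nucleus_class_map <- function(sample) {
  imap <- sample$nucleus_instance_map_20x
  if (nrow(sample$nucleus_classes) == 0) {
    return(imap * 0L)
  }
  lut <- integer(max(sample$nucleus_classes$instance_id))
  lut[sample$nucleus_classes$instance_id] <- sample$nucleus_classes$class_code
  out <- imap
  nz <- imap > 0
  out[nz] <- lut[imap[nz]]
  out
}

# oracle probability maps (1 + C channels) from ground truth, used to test
# the scorer and instance extraction independently of any trained network
oracle_probs_from_truth <- function(sample, eps = 0) {
  cmap <- nucleus_class_map(sample)
  ncls <- 6L
  d <- dim(cmap)
  out <- array(eps, c(d[1], d[2], ncls + 1L))
  out[, , 1] <- (cmap == 0) * 1
  for (k in seq_len(ncls)) out[, , k + 1L] <- (cmap == k) * 1
  if (eps > 0) out <- out / as.vector(rowSums(out, dims = 2))
  out
}
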