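# Shared fixtures. Expensive objects are memoized for the duration of one
# test run; everything is generated in code, nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

toy_net_config <- function() {
  network_config(
    depth = 3L, base_channels = 8L,
    roi_input_px = 48L, hpf_input_px = 48L, hook_level = 2L
  )
}

# small, nucleus-dense ROI used by network tests
tiny_roi <- function(seed = 3) {
  memo(paste0("tiny_roi_", seed), generate_roi(synth_params(
    roi_size_px = 16L, region_layout = "half_plane",
    nucleus_radius_px = c(mean = 2, sd = 0.1),
    stromal_cellularity = 3e5, epithelial_cellularity = 3e5, seed = seed
  )))
}

tiny_net_config <- function() {
  network_config(
    depth = 2L, base_channels = 3L,
    roi_input_px = 8L, hpf_input_px = 8L, hook_level = 1L
  )
}

toy_samples <- function(n = 5, seed0 = 100) {
  memo(paste0("toy_samples_", n, "_", seed0), lapply(seq_len(n), function(i) {
    generate_roi(synth_params(roi_size_px = 96L, region_layout = "blobs",
                              seed = seed0 + i))
  }))
}

# per-ROI grouped-superclass Dice of the region head against truth
roi_region_dice <- function(network, sample) {
  cf <- network$config
  ins <- tilquant:::roi_network_inputs(sample, cf)
  out <- predict_roi(network, ins$rgb_10x, ins$rgb_20x_hpf)
  d <- dim(out$roi_region_probs)
  pm <- matrix(
    max.col(matrix(out$roi_region_probs, d[1] * d[2], d[3]),
            ties.method = "first"),
    d[1], d[2]
  )
  mean(dice_grouped(pm, sample$region_mask_10x), na.rm = TRUE)
}

# brute-force all-pairs distance saliency oracle for small maps
saliency_bruteforce <- function(region_map, mpp, dist_microns = 32,
                                taxonomy = build_default_taxonomy()) {
  epi <- taxonomy$region_classes[taxonomy$region_group == "epithelium"]
  stromal <- taxonomy$region_classes[c("stroma", "tils_dense")]
  tum <- which(matrix(region_map %in% epi, nrow(region_map)),
               arr.ind = TRUE)
  if (nrow(tum) == 0) return(0)
  cnt <- 0
  for (i in seq_len(nrow(region_map))) {
    for (j in seq_len(ncol(region_map))) {
      if (!(region_map[i, j] %in% stromal)) next
      d <- sqrt(min((tum[, 1] - i)^2 + (tum[, 2] - j)^2)) * mpp
      if (d > 0 && d <= dist_microns) cnt <- cnt + 1
    }
  }
  cnt / length(region_map)
}

# exhaustive concordant-pair AUROC oracle (ties get half credit)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

file_md5 <- function(paths) unname(tools::md5sum(paths))
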