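#' Configuration for the two-branch panoptic segmentation network
#'
#' Two parallel U-Nets: a region branch at 10x (1 MPP) and a nucleus branch
#' at 20x (0.5 MPP). The high-power field (HPF) seen by the nucleus branch
#' covers the central half of the region branch's footprint in microns, so
#' `hpf_input_px * 0.5 == roi_input_px * 1.0 / 2`, i.e. the two inputs have
#' the same pixel extent. `hook_level` is the decoder level (counted up from
#' the bottleneck) at which region-branch context features are cropped,
#' upsampled and concatenated into the nucleus decoder.
#'
#' @param depth U-Net depth (number of encoder levels); default 5.
#' @param base_channels channels at the finest level; default 32
#'   (use 8 for a desk-scale toy profile).
#' @param roi_input_px region-branch input size at 1 MPP.
#' @param hpf_input_px nucleus-branch input size at 0.5 MPP.
#' @param n_region_classes,n_nucleus_classes vocabulary sizes (6 and 6; the
#'   nucleus branch additionally predicts a background channel).
#' @param hook_level decoder level of the cross-branch concatenation.
#' @return A `tq_net_config` list.
#' @export
network_config <- function(depth = 5L, base_channels = 32L,
                           roi_input_px = 512L, hpf_input_px = 512L,
                           n_region_classes = 6L, n_nucleus_classes = 6L,
                           hook_level = 2L) {
  if (depth < 2) stop("depth must be >= 2")
  if (hpf_input_px * 0.5 != roi_input_px * 1.0 / 2) {
    stop(
      "HPF footprint must be half the ROI footprint: need ",
      "hpf_input_px * 0.5 MPP == roi_input_px * 1.0 MPP / 2"
    )
  }
  if (roi_input_px %% 2^(depth - 1) != 0) {
    stop("roi_input_px must be divisible by 2^(depth - 1)")
  }
  if (hook_level < 1 || hook_level > depth - 1) {
    stop("hook_level must lie in 1..depth-1")
  }
  structure(
    list(
      depth = as.integer(depth), base_channels = as.integer(base_channels),
      roi_input_px = as.integer(roi_input_px),
      hpf_input_px = as.integer(hpf_input_px),
      n_region_classes = as.integer(n_region_classes),
      n_nucleus_classes = as.integer(n_nucleus_classes),
      hook_level = as.integer(hook_level)
    ),
    class = "tq_net_config"
  )
}

ch_at <- function(config, level) config$base_channels * 2^(level - 1)

conv_init <- function(kh, kw, cin, cout) {
  w <- matrix(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
              kh * kw * cin, cout)
  list(w = w, b = numeric(cout))
}

branch_param_specs <- function(config, prefix, n_out) {
  d <- config$depth
  specs <- list()
  cin <- 3
  for (l in seq_len(d)) {
    specs[[paste0(prefix, "_enc", l, "_c1")]] <- c(3, 3, cin, ch_at(config, l))
    specs[[paste0(prefix, "_enc", l, "_c2")]] <-
      c(3, 3, ch_at(config, l), ch_at(config, l))
    cin <- ch_at(config, l)
  }
  for (k in seq_len(d - 1)) {
    co <- ch_at(config, d - k)
    specs[[paste0(prefix, "_dec", k, "_up")]] <- c(3, 3, ch_at(config, d - k + 1), co)
    cat_in <- 2 * co
    if (prefix == "n" && k == config$hook_level) {
      cat_in <- cat_in + ch_at(config, d - config$hook_level)
    }
    specs[[paste0(prefix, "_dec", k, "_c1")]] <- c(3, 3, cat_in, co)
    specs[[paste0(prefix, "_dec", k, "_c2")]] <- c(3, 3, co, co)
  }
  specs[[paste0(prefix, "_head")]] <- c(1, 1, ch_at(config, 1), n_out)
  specs
}

#' Build the two-branch network
#'
#' Constructs parameter tensors for both U-Net branches (He-initialized,
#' seeded), the cross-branch hook, and the learnable region-to-nucleus
#' prior matrix (row-softmax logits, initialized uniform over the classes
#' the compatibility kernel admits).
#'
#' @param config a [network_config()].
#' @param kernel region-nucleus compatibility kernel
#'   ([build_default_kernel()]).
#' @param seed integer seed for parameter initialization.
#' @return A `tq_network` list with `config`, `kernel`, `params` and
#'   `P_logits`.
#' @export
build_network <- function(config,
                          kernel = build_default_kernel(build_default_taxonomy()),
                          seed = 1L) {
  stopifnot(inherits(config, "tq_net_config"))
  set.seed(seed)
  specs <- c(
    branch_param_specs(config, "r", config$n_region_classes),
    branch_param_specs(config, "n", config$n_nucleus_classes + 1L)
  )
  params <- lapply(specs, function(s) conv_init(s[1], s[2], s[3], s[4]))
  structure(
    list(
      config = config, kernel = kernel, params = params,
      param_specs = specs,
      P_logits = matrix(0, nrow(kernel), ncol(kernel),
                        dimnames = dimnames(kernel))
    ),
    class = "tq_network"
  )
}

#' Number of trainable parameters
#' @param network a `tq_network`.
#' @return Integer count of scalar parameters (convolutions, biases, prior
#'   logits).
#' @export
n_parameters <- function(network) {
  sum(vapply(network$params, function(p) length(p$w) + length(p$b), numeric(1))) +
    length(network$P_logits)
}

# run one U-Net branch on the tape; hook_in (nucleus branch) is injected at
# config$hook_level; returns list(head = logits node, dec = decoder nodes)
run_branch <- function(tape, config, pnodes, prefix, x, hook_in = NULL) {
  d <- config$depth
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    p1 <- pnodes[[paste0(prefix, "_enc", l, "_c1")]]
    p2 <- pnodes[[paste0(prefix, "_enc", l, "_c2")]]
    x <- op_relu(tape, op_conv(tape, x, p1$w, p1$b))
    x <- op_relu(tape, op_conv(tape, x, p2$w, p2$b))
    skips[[l]] <- x
    if (l < d) x <- op_maxpool2(tape, x)
  }
  dec <- vector("list", d - 1)
  for (k in seq_len(d - 1)) {
    pu <- pnodes[[paste0(prefix, "_dec", k, "_up")]]
    p1 <- pnodes[[paste0(prefix, "_dec", k, "_c1")]]
    p2 <- pnodes[[paste0(prefix, "_dec", k, "_c2")]]
    x <- op_relu(tape, op_conv(tape, op_up2(tape, x), pu$w, pu$b))
    parts <- list(x, skips[[d - k]])
    if (prefix == "n" && k == config$hook_level && !is.null(hook_in)) {
      parts <- c(parts, list(hook_in))
    }
    x <- op_concat_c(tape, parts)
    x <- op_relu(tape, op_conv(tape, x, p1$w, p1$b))
    x <- op_relu(tape, op_conv(tape, x, p2$w, p2$b))
    dec[[k]] <- x
  }
  ph <- pnodes[[paste0(prefix, "_head")]]
  list(head = op_conv(tape, x, ph$w, ph$b, 1L, 1L), dec = dec)
}

# full forward pass on a fresh tape; inputs are raw 0..255 RGB arrays
forward_net <- function(network, rgb_10x, rgb_20x_hpf) {
  cf <- network$config
  stopifnot(
    all(dim(rgb_10x) == c(cf$roi_input_px, cf$roi_input_px, 3)),
    all(dim(rgb_20x_hpf) == c(cf$hpf_input_px, cf$hpf_input_px, 3))
  )
  tape <- tq_tape()
  pnodes <- lapply(network$params, function(p) {
    list(w = tq_node(tape, p$w), b = tq_node(tape, p$b))
  })
  P_logits <- tq_node(tape, network$P_logits)
  xr <- op_const(tape, rgb_10x / 255 - 0.5)
  xn <- op_const(tape, rgb_20x_hpf / 255 - 0.5)

  rb <- run_branch(tape, cf, pnodes, "r", xr)
  hook <- op_up2(tape, op_crop_half(tape, rb$dec[[cf$hook_level]]))
  nb <- run_branch(tape, cf, pnodes, "n", xn, hook_in = hook)

  roi_probs <- op_softmax_c(tape, rb$head)
  hpf_region_probs <- op_up2(tape, op_crop_half(tape, roi_probs))

  # attention: region probabilities are detached so the constrained loss
  # updates the nucleus branch and the prior logits only; zeros stay exact
  # so prohibited classes stay prohibited (admissible mass is always
  # positive because every kernel row admits at least one class)
  P_row <- op_row_softmax_masked(tape, P_logits, network$kernel)
  A_raw <- op_mix_prior(tape, hpf_region_probs$val, P_row)
  A <- op_bdiv(tape, A_raw, op_sum_c(tape, A_raw))

  s <- op_softmax_c(tape, nb$head)
  s_bg <- op_slice_c(tape, s, 1L)
  s_fg <- op_slice_c(tape, s, 1L + seq_len(cf$n_nucleus_classes))
  num <- tq_mul3(tape, s_fg, A)
  ratio <- op_mdiv(tape, op_sum_c(tape, s_fg), op_sum_c(tape, num))
  q_fg <- op_bmul_m(tape, num, ratio)
  q <- op_concat_c(tape, list(s_bg, q_fg))

  list(
    tape = tape, pnodes = pnodes, P_logits_node = P_logits, P_row = P_row,
    roi_logits = rb$head, roi_probs = roi_probs,
    hpf_region_probs = hpf_region_probs,
    nucleus_logits = nb$head, nucleus_probs_unconstrained = s,
    attention = A, constrained = q
  )
}

# helpers kept next to forward_net: elementwise product of two maps and
# broadcast multiply by a matrix node
tq_mul3 <- function(tape, a, b) {
  tq_node(tape, a$val * b$val, list(a, b), bw = function(self) {
    tq_acc(a, self$grad * b$val)
    tq_acc(b, self$grad * a$val)
  })
}

op_bmul_m <- function(tape, x, s) {
  tq_node(tape, x$val * as.vector(s$val), list(x, s), bw = function(self) {
    tq_acc(x, self$grad * as.vector(s$val))
    tq_acc(s, rowSums(self$grad * x$val, dims = 2))
  })
}

#' Run the network on one ROI
#'
#' @param network a `tq_network`.
#' @param rgb_10x ROI image at 1 MPP (`roi_input_px` square, 0..255).
#' @param rgb_20x_hpf HPF image at 0.5 MPP (central half of the ROI
#'   footprint, `hpf_input_px` square).
#' @return A `tq_raw_outputs` list: `roi_region_logits`,
#'   `hpf_region_probs`, `nucleus_logits_unconstrained`,
#'   `nucleus_probs_constrained`, `attention`, and the current learned
#'   prior `P`.
#' @export
predict_roi <- function(network, rgb_10x, rgb_20x_hpf) {
  fw <- forward_net(network, rgb_10x, rgb_20x_hpf)
  structure(
    list(
      roi_region_logits = fw$roi_logits$val,
      roi_region_probs = fw$roi_probs$val,
      hpf_region_probs = fw$hpf_region_probs$val,
      nucleus_logits_unconstrained = fw$nucleus_logits$val,
      nucleus_probs_unconstrained = fw$nucleus_probs_unconstrained$val,
      nucleus_probs_constrained = fw$constrained$val,
      attention = fw$attention$val,
      P = fw$P_row$val
    ),
    class = "tq_raw_outputs"
  )
}

#' Class-specific attention maps from region probabilities
#'
#' For each nucleus class `c`, `A_c(x) = sum_r rho_r(x) K[r,c] P[r,c]`,
#' renormalized over classes: the per-pixel likelihood of each nucleus
#' class given the surrounding tissue. Exact zeros are preserved, so a
#' class prohibited by a one-hot region keeps attention (and hence
#' constrained probability) exactly zero. Pixels whose admissible mass
#' falls below `eps` fall back to a uniform distribution over the classes
#' the argmax region admits (or over all classes, with a warning, if that
#' region admits none).
#'
#' @param hpf_region_probs H x W x R array of region probabilities.
#' @param kernel binary compatibility kernel `[region, nucleus]`.
#' @param prior row-stochastic prior matrix (validated by
#'   [validate_prior()]).
#' @param eps admissible-mass threshold below which a pixel is treated as
#'   degenerate.
#' @return H x W x C array; each pixel a distribution over nucleus classes.
#' @export
compute_attention <- function(hpf_region_probs, kernel, prior, eps = 1e-8) {
  d <- dim(hpf_region_probs)
  M <- kernel * prior
  A <- matrix(hpf_region_probs, d[1] * d[2], d[3]) %*% M
  dead <- rowSums(A) < eps
  if (any(dead)) {
    argm <- max.col(matrix(hpf_region_probs, d[1] * d[2], d[3]),
                    ties.method = "first")
    for (i in which(dead)) {
      allowed <- kernel[argm[i], ] == 1
      if (!any(allowed)) {
        warning("pixel with no admissible nucleus class; using uniform")
        allowed <- rep(TRUE, ncol(kernel))
      }
      A[i, ] <- allowed / sum(allowed)
    }
  }
  A <- A / rowSums(A)
  array(A, c(d[1], d[2], ncol(kernel)), dimnames = list(NULL, NULL, colnames(kernel)))
}

#' Constrain nucleus predictions with an attention map
#'
#' Re-weights the foreground-conditional class distribution by the
#' attention map: the background probability passes through unchanged and
#' the nucleus-class probabilities are multiplied by `A_c` and renormalized
#' to the remaining foreground mass, so the result is a valid per-pixel
#' distribution. A uniform attention map leaves the prediction unchanged;
#' a prohibited class under a one-hot region is suppressed to (at most) the
#' attention floor.
#'
#' @param nucleus_logits H x W x (1 + C) logits, background channel first.
#' @param attention H x W x C attention maps from [compute_attention()].
#' @return H x W x (1 + C) array of constrained probabilities.
#' @export
constrain_nuclei <- function(nucleus_logits, attention) {
  if (any(!is.finite(nucleus_logits))) stop("non-finite nucleus logits")
  d <- dim(nucleus_logits)
  m <- apply(nucleus_logits, c(1, 2), max)
  e <- exp(nucleus_logits - as.vector(m))
  s <- e / as.vector(rowSums(e, dims = 2))
  fg <- s[, , -1, drop = FALSE]
  num <- fg * attention
  ratio <- rowSums(fg, dims = 2) / rowSums(num, dims = 2)
  out <- array(0, d)
  out[, , 1] <- s[, , 1]
  out[, , -1] <- num * as.vector(ratio)
  out
}

# one-hot encode an integer mask into channels for codes `codes`
onehot_codes <- function(mask, codes) {
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], length(codes)))
  for (k in seq_along(codes)) out[, , k] <- (mask == codes[k]) * 1
  out
}

# build loss targets from a training sample; nucleus background (code 0) is
# supervised as its own channel, ignore masks come from region code 0
loss_targets <- function(sample, config) {
  R <- config$roi_input_px
  roi_mask <- sample$region_mask_10x
  stopifnot(all(dim(roi_mask) == c(R, R)))
  H2 <- nrow(sample$region_mask_20x)
  ri <- (H2 / 4 + 1):(3 * H2 / 4)
  hpf_mask <- sample$region_mask_20x[ri, ri]
  nuc_class_map <- nucleus_class_map(sample)[ri, ri]
  list(
    roi = list(g = onehot_codes(roi_mask, seq_len(config$n_region_classes)),
               m = (roi_mask > 0) * 1),
    hpf = list(g = onehot_codes(hpf_mask, seq_len(config$n_region_classes)),
               m = (hpf_mask > 0) * 1),
    nuc = list(g = onehot_codes(nuc_class_map, 0:config$n_nucleus_classes),
               m = (hpf_mask > 0) * 1)
  )
}

#' Multi-task loss for one ROI
#'
#' Equal-weight mean of four components, each pixel-wise categorical
#' cross-entropy plus one minus soft-DICE (averaged over classes), with
#' unannotated pixels ignored: (1) ROI region prediction at 1 MPP, (2) the
#' HPF-footprint region prediction at 0.5 MPP, (3) the unconstrained
#' nucleus prediction, (4) the region-constrained nucleus prediction. An
#' all-ignore target contributes 0 with a warning.
#'
#' @param outputs a `tq_raw_outputs` from [predict_roi()].
#' @param sample a `tq_roi` training sample carrying region masks at both
#'   scales and the nucleus instance map.
#' @param config the [network_config()] used to produce `outputs`.
#' @return List with `total` and the four named components.
#' @export
multitask_loss <- function(outputs, sample, config) {
  tg <- loss_targets(sample, config)
  comp <- function(p, t) {
    if (sum(t$m) == 0) {
      warning("all-ignore target; component contributes 0")
      return(0)
    }
    N <- sum(t$m)
    ce <- -sum(as.vector(t$m) * rowSums(t$g * log(p + 1e-8), dims = 2)) / N
    pm <- p * as.vector(t$m)
    gm <- t$g * as.vector(t$m)
    num <- 2 * colSums(pm * gm, dims = 2) + 1
    den <- colSums(pm, dims = 2) + colSums(gm, dims = 2) + 1
    ce + (1 - mean(num / den))
  }
  c1 <- comp(outputs$roi_region_probs, tg$roi)
  c2 <- comp(outputs$hpf_region_probs, tg$hpf)
  c3 <- comp(outputs$nucleus_probs_unconstrained, tg$nuc)
  c4 <- comp(outputs$nucleus_probs_constrained, tg$nuc)
  list(
    total = mean(c(c1, c2, c3, c4)),
    roi_region = c1, hpf_region = c2,
    nucleus_unconstrained = c3, nucleus_constrained = c4
  )
}

# tape version of the loss used during training; mirrors multitask_loss()
tape_loss <- function(fw, sample, config) {
  tg <- loss_targets(sample, config)
  tape <- fw$tape
  comp <- function(pnode, t) {
    op_add_s(
      tape,
      op_ce_masked(tape, pnode, t$g, t$m),
      op_dice_masked(tape, pnode, t$g, t$m)
    )
  }
  c1 <- comp(fw$roi_probs, tg$roi)
  c2 <- comp(fw$hpf_region_probs, tg$hpf)
  c3 <- comp(fw$nucleus_probs_unconstrained, tg$nuc)
  c4 <- comp(fw$constrained, tg$nuc)
  list(total = op_mean_s(tape, list(c1, c2, c3, c4)),
       components = list(c1, c2, c3, c4))
}
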