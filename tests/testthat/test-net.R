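test_that("network configuration enforces the two-magnification geometry", {
  expect_error(network_config(roi_input_px = 512, hpf_input_px = 256),
               "half the ROI footprint")
  expect_error(network_config(depth = 1), "depth")
  expect_error(network_config(depth = 5, roi_input_px = 100,
                              hpf_input_px = 100), "divisible")
  expect_error(network_config(depth = 3, roi_input_px = 64,
                              hpf_input_px = 64, hook_level = 3),
               "hook_level")
  cf <- toy_net_config()
  expect_s3_class(cf, "tq_net_config")
})

test_that("forward pass produces correctly shaped, valid outputs", {
  cf <- toy_net_config()
  net <- build_network(cf, seed = 1)
  s <- toy_samples(1)[[1]]
  ins <- tilquant:::roi_network_inputs(s, cf)
  out <- predict_roi(net, ins$rgb_10x, ins$rgb_20x_hpf)
  expect_equal(dim(out$roi_region_logits), c(48, 48, 6))
  expect_equal(dim(out$hpf_region_probs), c(48, 48, 6))
  expect_equal(dim(out$nucleus_logits_unconstrained), c(48, 48, 7))
  expect_equal(dim(out$nucleus_probs_constrained), c(48, 48, 7))
  # constrained outputs are distributions
  expect_equal(max(abs(rowSums(out$nucleus_probs_constrained, dims = 2) - 1)),
               0, tolerance = 1e-5)
  expect_true(all(out$nucleus_probs_constrained >= 0))
  # deterministic initialization
  net2 <- build_network(cf, seed = 1)
  expect_identical(net$params, net2$params)
})

test_that("parameter count matches an independent shape oracle", {
  # oracle: enumerate every convolution's (kh*kw*cin*cout + cout) from the
  # architecture definition, independently of the builder's bookkeeping
  oracle_count <- function(depth, base, hook_level, n_reg = 6, n_nuc = 7) {
    ch <- base * 2^(0:(depth - 1))
    tot <- 0
    for (branch in c("r", "n")) {
      cin <- 3
      for (l in seq_len(depth)) {
        tot <- tot + 9 * cin * ch[l] + ch[l] + 9 * ch[l]^2 + ch[l]
        cin <- ch[l]
      }
      for (k in seq_len(depth - 1)) {
        co <- ch[depth - k]
        tot <- tot + 9 * ch[depth - k + 1] * co + co       # up conv
        cat_in <- 2 * co + if (branch == "n" && k == hook_level)
          ch[depth - hook_level] else 0
        tot <- tot + 9 * cat_in * co + co + 9 * co^2 + co  # two convs
      }
      nout <- if (branch == "r") n_reg else n_nuc
      tot <- tot + ch[1] * nout + nout                     # 1x1 head
    }
    tot + 36                                               # prior logits
  }
  for (base in c(4, 8)) {
    cf <- network_config(depth = 3, base_channels = base,
                         roi_input_px = 16, hpf_input_px = 16,
                         hook_level = 2)
    expect_equal(n_parameters(build_network(cf, seed = 1)),
                 oracle_count(3, base, 2))
  }
})

test_that("backpropagated gradients match finite differences", {
  roi <- tiny_roi()
  cf <- tiny_net_config()
  tax <- build_default_taxonomy()
  K1 <- build_default_kernel(tax); K1[, ] <- 1   # constant attention path
  net <- build_network(cf, kernel = K1, seed = 2)
  ins <- tilquant:::roi_network_inputs(roi, cf)
  lossval <- function(net) {
    fw <- tilquant:::forward_net(net, ins$rgb_10x, ins$rgb_20x_hpf)
    tilquant:::tape_loss(fw, roi, cf)$total$val
  }
  fw <- tilquant:::forward_net(net, ins$rgb_10x, ins$rgb_20x_hpf)
  ls <- tilquant:::tape_loss(fw, roi, cf)
  tilquant:::tq_backward(fw$tape, ls$total)
  h <- 1e-5
  set.seed(42)
  for (nm in c("r_enc1_c1", "r_head", "n_dec1_c1", "n_head")) {
    W <- net$params[[nm]]$w
    for (rep in 1:3) {
      i <- sample(length(W), 1)
      n1 <- net; n1$params[[nm]]$w[i] <- W[i] + h
      n2 <- net; n2$params[[nm]]$w[i] <- W[i] - h
      fd <- (lossval(n1) - lossval(n2)) / (2 * h)
      an <- fw$pnodes[[nm]]$w$grad[i]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("attention maps mix kernel and prior as stated", {
  tax <- build_default_taxonomy()
  K <- build_default_kernel(tax)
  P <- build_uniform_prior(K)

  # one-hot stroma region: uniform over the classes stroma admits
  rho <- array(0, c(2, 2, 6)); rho[, , 3] <- 1
  A <- compute_attention(rho, K, P)
  allowed <- which(K["stroma", ] == 1)
  expect_equal(unname(A[1, 1, allowed]),
               rep(1 / length(allowed), length(allowed)))
  expect_true(all(A[, , -allowed] <= 1e-7))

  # all-ones kernel + uniform prior: uniform attention whatever the regions
  K1 <- K; K1[, ] <- 1
  set.seed(1)
  rnd <- array(runif(2 * 2 * 6), c(2, 2, 6))
  rnd <- rnd / as.vector(rowSums(rnd, dims = 2))
  A1 <- compute_attention(rnd, K1, build_uniform_prior(K1))
  expect_equal(c(A1), rep(1 / 6, length(A1)), tolerance = 1e-9)

  # mixed region probabilities match the brute-force per-pixel mixture
  rho2 <- array(0, c(1, 1, 6)); rho2[1, 1, 3] <- 0.6; rho2[1, 1, 1] <- 0.4
  A2 <- compute_attention(rho2, K, P)
  raw <- sapply(1:6, function(cc) {
    sum(sapply(1:6, function(r) rho2[1, 1, r] * K[r, cc] * P[r, cc]))
  })
  raw <- raw / sum(raw)
  expect_equal(unname(A2[1, 1, ]), raw, tolerance = 1e-12)

  # dead pixels fall back to the argmax region's admissible classes
  P0 <- P; P0["stroma", ] <- 0   # deliberately invalid prior row
  rho3 <- array(0, c(1, 1, 6)); rho3[1, 1, 3] <- 1
  A3 <- compute_attention(rho3, K, P0)
  expect_equal(unname(A3[1, 1, allowed]),
               rep(1 / length(allowed), length(allowed)))
})

test_that("constraint re-weights foreground and is conservative", {
  set.seed(7)
  logits <- array(rnorm(4 * 4 * 7), c(4, 4, 7))

  # uniform attention: identity
  Au <- array(1 / 6, c(4, 4, 6))
  sm <- exp(logits) / as.vector(rowSums(exp(logits), dims = 2))
  q <- constrain_nuclei(logits, Au)
  expect_equal(q, sm, tolerance = 1e-6)

  # one-hot attention on lymphocyte: all foreground mass on lymphocyte
  A1 <- array(0, c(4, 4, 6)); A1[, , 4] <- 1
  q1 <- constrain_nuclei(array(0, c(4, 4, 7)), A1)
  expect_equal(c(q1[, , 5]), rep(6 / 7, 16), tolerance = 1e-12)
  expect_equal(c(q1[, , 1]), rep(1 / 7, 16), tolerance = 1e-12)
  expect_true(all(q1[, , c(2:4, 6:7)] == 0))

  # random attention matches the product-then-renormalize oracle
  Ar <- array(runif(4 * 4 * 6), c(4, 4, 6))
  Ar <- Ar / as.vector(rowSums(Ar, dims = 2))
  qr <- constrain_nuclei(logits, Ar)
  for (i in 1:4) for (j in 1:4) {
    s <- sm[i, j, ]
    num <- s[-1] * Ar[i, j, ]
    expect_equal(qr[i, j, ], c(s[1], (1 - s[1]) * num / sum(num)),
                 tolerance = 1e-6)
  }
  expect_equal(max(abs(rowSums(qr, dims = 2) - 1)), 0, tolerance = 1e-12)

  expect_error(constrain_nuclei(logits * NA, Au), "finite")
})

test_that("prohibited classes are suppressed under one-hot regions", {
  cf <- toy_net_config()
  net <- build_network(cf, seed = 5)
  s <- toy_samples(1)[[1]]
  ins <- tilquant:::roi_network_inputs(s, cf)
  out <- predict_roi(net, ins$rgb_10x, ins$rgb_20x_hpf)
  K <- net$kernel
  d <- dim(out$hpf_region_probs)
  rho <- matrix(out$hpf_region_probs, d[1] * d[2], d[3])
  onehot <- which(apply(rho, 1, max) > 1 - 1e-9)
  if (length(onehot) > 0) {
    reg <- max.col(rho[onehot, , drop = FALSE])
    qf <- matrix(out$nucleus_probs_constrained[, , -1], d[1] * d[2], 6)
    for (ii in seq_along(onehot)) {
      bad <- which(K[reg[ii], ] == 0)
      expect_true(all(qf[onehot[ii], bad] <= 1e-6))
    }
  }
  # and for synthetic one-hot regions directly
  rho1 <- array(0, c(2, 2, 6)); rho1[, , 1] <- 1    # cancer region
  A <- compute_attention(rho1, K, build_uniform_prior(K))
  q <- constrain_nuclei(array(rnorm(2 * 2 * 7), c(2, 2, 7)), A)
  expect_true(all(q[, , 1 + which(K["cancer", ] == 0)] <= 1e-6))
})

test_that("multi-task loss composes its four components with equal weight", {
  cf <- tiny_net_config()
  roi <- tiny_roi()
  net <- build_network(cf, seed = 1)
  ins <- tilquant:::roi_network_inputs(roi, cf)
  out <- predict_roi(net, ins$rgb_10x, ins$rgb_20x_hpf)
  ml <- multitask_loss(out, roi, cf)
  expect_equal(ml$total,
               mean(c(ml$roi_region, ml$hpf_region,
                      ml$nucleus_unconstrained, ml$nucleus_constrained)))

  # perfect predictions give (numerically) zero loss
  perfect <- out
  tg <- tilquant:::loss_targets(roi, cf)
  perfect$roi_region_probs <- tg$roi$g
  perfect$hpf_region_probs <- tg$hpf$g
  perfect$nucleus_probs_unconstrained <- tg$nuc$g
  perfect$nucleus_probs_constrained <- tg$nuc$g
  expect_lt(multitask_loss(perfect, roi, cf)$total, 1e-6)

  # tape loss agrees with the plain implementation
  fw <- tilquant:::forward_net(net, ins$rgb_10x, ins$rgb_20x_hpf)
  tl <- tilquant:::tape_loss(fw, roi, cf)
  expect_equal(tl$total$val, ml$total, tolerance = 1e-12)
})

test_that("loss matches a per-pixel oracle on a random case", {
  # random 8x8 probabilities and targets, one component
  set.seed(13)
  C <- 4
  p <- array(runif(8 * 8 * C), c(8, 8, C))
  p <- p / as.vector(rowSums(p, dims = 2))
  tgt <- matrix(sample(0:C, 64, replace = TRUE), 8, 8)
  g <- array(0, c(8, 8, C))
  for (k in seq_len(C)) g[, , k] <- (tgt == k) * 1
  m <- (tgt > 0) * 1

  # oracle: explicit loops
  ce <- 0; N <- sum(m)
  for (i in 1:8) for (j in 1:8) {
    if (m[i, j] == 0) next
    ce <- ce - log(p[i, j, tgt[i, j]] + 1e-8)
  }
  ce <- ce / N
  dice <- numeric(C)
  for (k in 1:C) {
    num <- 0; den <- 0
    for (i in 1:8) for (j in 1:8) {
      if (m[i, j] == 0) next
      num <- num + 2 * p[i, j, k] * g[i, j, k]
      den <- den + p[i, j, k] + g[i, j, k]
    }
    dice[k] <- (num + 1) / (den + 1)
  }
  oracle <- ce + (1 - mean(dice))

  tape <- tilquant:::tq_tape()
  pn <- tilquant:::op_const(tape, p)
  val <- tilquant:::op_add_s(
    tape,
    tilquant:::op_ce_masked(tape, pn, g, m),
    tilquant:::op_dice_masked(tape, pn, g, m)
  )$val
  expect_equal(val, oracle, tolerance = 1e-5)
})

test_that("instance extraction follows the stated post-processing", {
  # two disjoint disks with known centroids
  probs <- array(0, c(32, 32, 7)); probs[, , 1] <- 1
  mk_disk <- function(ci, cj, r, ch) {
    for (i in 1:32) for (j in 1:32) {
      if ((i - ci)^2 + (j - cj)^2 <= r^2) {
        probs[i, j, ] <<- 0; probs[i, j, ch] <<- 1
      }
    }
  }
  mk_disk(8, 8, 4, 5)     # lymphocyte
  mk_disk(24, 24, 4, 4)   # fibroblast
  inst <- extract_instances(probs, min_size_px = 10)
  expect_equal(nrow(inst), 2)
  inst <- inst[order(inst$x), ]
  expect_equal(inst$class, c("lymphocyte", "fibroblast"))
  expect_equal(inst$x, c(7, 23), tolerance = 0.2)  # 0-based centroids
  expect_equal(inst$y, c(7, 23), tolerance = 0.2)

  # a 5-pixel blob is dropped at min_size 10
  small <- array(0, c(16, 16, 7)); small[, , 1] <- 1
  small[8, 6:10, ] <- 0; small[8, 6:10, 3] <- 1
  expect_equal(nrow(extract_instances(small, min_size_px = 10)), 0)
  expect_equal(nrow(extract_instances(small, min_size_px = 5)), 1)

  # generator-truth oracle: exact instance recovery, classes correct
  r <- generate_roi(synth_params(roi_size_px = 192L, til_fraction = 0.4,
                                 seed = 21))
  probs <- tilquant:::oracle_probs_from_truth(r)
  inst <- extract_instances(probs, min_size_px = 10)
  expect_equal(nrow(inst), nrow(r$nucleus_classes))
  m <- match_instances(inst, r$nucleus_classes)
  expect_equal(nrow(m$matches), nrow(r$nucleus_classes))
  pred_cls <- inst$class[match(m$matches$pred_id, inst$instance_id)]
  gt_cls <- r$nucleus_classes$class[
    match(m$matches$gt_id, r$nucleus_classes$instance_id)
  ]
  expect_gte(mean(pred_cls == gt_cls), 0.95)
})
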