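# Minimal reverse-mode tape for the two-branch segmentation network.
# Nodes are environments holding `val`, `grad`, `parents` and a backward
# closure; `tq_backward()` walks the tape in reverse creation order.
# Feature maps are H x W x C arrays, scalars are length-1 numerics.

tq_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

tq_node <- function(tape, val, parents = list(), bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  if (tape$n >= length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- n
  n
}

tq_acc <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

tq_backward <- function(tape, loss) {
  loss$grad <- if (is.null(dim(loss$val))) {
    rep(1, length(loss$val))
  } else {
    array(1, dim(loss$val))
  }
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

op_const <- function(tape, val) tq_node(tape, val)

op_conv <- function(tape, x, w, b, kh = 3L, kw = 3L) {
  y <- .conv2d_fw(x$val, w$val, b$val, kh, kw)
  tq_node(tape, y, list(x, w, b), bw = function(self) {
    r <- .conv2d_bw(x$val, w$val, self$grad, kh, kw)
    tq_acc(x, r$dx)
    tq_acc(w, r$dw)
    tq_acc(b, as.numeric(r$db))
  })
}

op_relu <- function(tape, x) {
  tq_node(tape, pmax(x$val, 0), list(x), bw = function(self) {
    tq_acc(x, self$grad * (x$val > 0))
  })
}

op_maxpool2 <- function(tape, x) {
  r <- .maxpool2_fw(x$val)
  d <- dim(x$val)
  n <- tq_node(tape, r$y, list(x), bw = function(self) {
    tq_acc(x, .maxpool2_bw(r$idx, self$grad, d[1], d[2]))
  })
  n
}

op_up2 <- function(tape, x) {
  tq_node(tape, .upsample2_fw(x$val), list(x), bw = function(self) {
    tq_acc(x, .upsample2_bw(self$grad))
  })
}

# central crop to half the spatial extent
op_crop_half <- function(tape, x) {
  d <- dim(x$val)
  ri <- (d[1] / 4 + 1):(3 * d[1] / 4)
  ci <- (d[2] / 4 + 1):(3 * d[2] / 4)
  tq_node(tape, x$val[ri, ci, , drop = FALSE], list(x), bw = function(self) {
    g <- array(0, d)
    g[ri, ci, ] <- self$grad
    tq_acc(x, g)
  })
}

op_concat_c <- function(tape, xs) {
  d1 <- dim(xs[[1]]$val)
  chs <- vapply(xs, function(x) dim(x$val)[3], numeric(1))
  val <- array(unlist(lapply(xs, function(x) x$val), use.names = FALSE),
               dim = c(d1[1], d1[2], sum(chs)))
  tq_node(tape, val, xs, bw = function(self) {
    off <- 0
    for (k in seq_along(xs)) {
      tq_acc(xs[[k]], self$grad[, , off + seq_len(chs[k]), drop = FALSE])
      off <- off + chs[k]
    }
  })
}

op_slice_c <- function(tape, x, idx) {
  d <- dim(x$val)
  tq_node(tape, x$val[, , idx, drop = FALSE], list(x), bw = function(self) {
    g <- array(0, d)
    g[, , idx] <- self$grad
    tq_acc(x, g)
  })
}

# channelwise softmax over dim 3
op_softmax_c <- function(tape, x) {
  m <- apply(x$val, c(1, 2), max)
  e <- exp(x$val - as.vector(m))
  p <- e / as.vector(rowSums(e, dims = 2))
  tq_node(tape, p, list(x), bw = function(self) {
    s <- rowSums(self$grad * p, dims = 2)
    tq_acc(x, p * (self$grad - as.vector(s)))
  })
}

op_pmax_const <- function(tape, x, k) {
  tq_node(tape, pmax(x$val, k), list(x), bw = function(self) {
    tq_acc(x, self$grad * (x$val > k))
  })
}

# x: H x W x C, s: H x W matrix; broadcast multiply over channels
op_bmul <- function(tape, x, s) {
  tq_node(tape, x$val * as.vector(s$val), list(x, s), bw = function(self) {
    tq_acc(x, self$grad * as.vector(s$val))
    tq_acc(s, rowSums(self$grad * x$val, dims = 2))
  })
}

op_bdiv <- function(tape, x, s) {
  tq_node(tape, x$val / as.vector(s$val), list(x, s), bw = function(self) {
    tq_acc(x, self$grad / as.vector(s$val))
    tq_acc(s, -rowSums(self$grad * x$val, dims = 2) / (s$val^2))
  })
}

op_sum_c <- function(tape, x) {
  d <- dim(x$val)
  tq_node(tape, rowSums(x$val, dims = 2), list(x), bw = function(self) {
    tq_acc(x, array(rep(self$grad, d[3]), d))
  })
}

# elementwise matrix division a / b (H x W each)
op_mdiv <- function(tape, a, b) {
  tq_node(tape, a$val / b$val, list(a, b), bw = function(self) {
    tq_acc(a, self$grad / b$val)
    tq_acc(b, -self$grad * a$val / (b$val^2))
  })
}

# per-row softmax of a logit matrix restricted to kernel-admissible entries
op_row_softmax_masked <- function(tape, L, K) {
  P <- matrix(0, nrow(K), ncol(K), dimnames = dimnames(K))
  for (r in seq_len(nrow(K))) {
    a <- which(K[r, ] == 1)
    z <- L$val[r, a]
    e <- exp(z - max(z))
    P[r, a] <- e / sum(e)
  }
  tq_node(tape, P, list(L), bw = function(self) {
    dL <- matrix(0, nrow(K), ncol(K))
    for (r in seq_len(nrow(K))) {
      a <- which(K[r, ] == 1)
      p <- P[r, a]
      g <- self$grad[r, a]
      dL[r, a] <- p * (g - sum(g * p))
    }
    tq_acc(L, dL)
  })
}

# attention mixture A[,,c] = sum_r rho[,,r] * M[r, c]; rho is a constant
op_mix_prior <- function(tape, rho, M) {
  d <- dim(rho)
  R <- matrix(rho, d[1] * d[2], d[3])
  A <- R %*% M$val
  tq_node(tape, array(A, c(d[1], d[2], ncol(M$val))), list(M),
          bw = function(self) {
    G <- matrix(self$grad, d[1] * d[2], ncol(M$val))
    tq_acc(M, t(R) %*% G)
  })
}

# masked categorical cross-entropy on probabilities: scalar
op_ce_masked <- function(tape, p, target, mask, eps = 1e-8) {
  N <- sum(mask)
  if (N == 0) {
    return(tq_node(tape, 0, list(p), bw = function(self) NULL))
  }
  mb <- as.vector(mask)
  val <- -sum(as.vector(mask) * rowSums(target * log(p$val + eps), dims = 2)) / N
  tq_node(tape, val, list(p), bw = function(self) {
    tq_acc(p, -self$grad * target * mb / (p$val + eps) / N)
  })
}

# masked soft-DICE loss: 1 - mean_c dice_c, smoothing keeps 0/0 classes at 1
op_dice_masked <- function(tape, p, target, mask, smooth = 1) {
  if (sum(mask) == 0) {
    return(tq_node(tape, 0, list(p), bw = function(self) NULL))
  }
  C <- dim(p$val)[3]
  mb <- as.vector(mask)
  pm <- p$val * mb
  gm <- target * mb
  num <- 2 * colSums(pm * gm, dims = 2) + smooth
  den <- colSums(pm, dims = 2) + colSums(gm, dims = 2) + smooth
  val <- 1 - mean(num / den)
  tq_node(tape, val, list(p), bw = function(self) {
    dp <- array(0, dim(p$val))
    for (cc in seq_len(C)) {
      dp[, , cc] <- -(1 / C) * mb * (2 * gm[, , cc] * den[cc] - num[cc]) / den[cc]^2
    }
    tq_acc(p, self$grad * dp)
  })
}

op_add_s <- function(tape, a, b) {
  tq_node(tape, a$val + b$val, list(a, b), bw = function(self) {
    tq_acc(a, self$grad)
    tq_acc(b, self$grad)
  })
}

op_mean_s <- function(tape, xs) {
  n <- length(xs)
  tq_node(tape, mean(vapply(xs, function(x) x$val, numeric(1))), xs,
          bw = function(self) {
    for (x in xs) tq_acc(x, self$grad / n)
  })
}
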