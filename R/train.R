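#' Desk-scale training loop
#'
#' Trains the two-branch network on a small set of ROIs with Adam, cycling
#' through the samples one per step. Intended for overfitting tiny
#' synthetic sets (sanity checks, toy profiles), not for production-scale
#' training. Fully deterministic for a fixed seed.
#'
#' @param samples list of `tq_roi` samples ([generate_roi()]).
#' @param config a [network_config()]; ignored when `network` is supplied.
#' @param steps number of optimization steps (0 returns the initialization).
#' @param lr Adam learning rate.
#' @param seed seed controlling initialization and nothing else (the sample
#'   schedule is a deterministic cycle).
#' @param network optionally continue training an existing `tq_network`.
#' @param clip_norm global gradient-norm clip applied before each Adam
#'   update (stabilizes the Dice term early in training).
#' @return A `tq_fit` list: `network`, `trace` (tibble of per-step loss
#'   components), `config`.
#' @export
train_toy <- function(samples, config = NULL, steps = 500L, lr = 1e-2,
                      seed = 1L, network = NULL, clip_norm = 5) {
  stopifnot(length(samples) >= 1)
  if (is.null(network)) {
    stopifnot(!is.null(config))
    network <- build_network(config, seed = seed)
  }
  cf <- network$config
  adam <- new.env(parent = emptyenv())
  adam$m <- list(); adam$v <- list(); adam$t <- 0
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8

  upd <- function(name, theta, g) {
    if (is.null(adam$m[[name]])) {
      adam$m[[name]] <- theta * 0
      adam$v[[name]] <- theta * 0
    }
    adam$m[[name]] <- b1 * adam$m[[name]] + (1 - b1) * g
    adam$v[[name]] <- b2 * adam$v[[name]] + (1 - b2) * g^2
    mh <- adam$m[[name]] / (1 - b1^adam$t)
    vh <- adam$v[[name]] / (1 - b2^adam$t)
    theta - lr * mh / (sqrt(vh) + aeps)
  }

  trace <- vector("list", steps)
  inputs <- lapply(samples, function(s) roi_network_inputs(s, cf))

  for (step in seq_len(steps)) {
    i <- (step - 1L) %% length(samples) + 1L
    fw <- forward_net(network, inputs[[i]]$rgb_10x, inputs[[i]]$rgb_20x_hpf)
    ls <- tape_loss(fw, samples[[i]], cf)
    comp_vals <- vapply(ls$components, function(x) x$val, numeric(1))
    trace[[step]] <- c(step, comp_vals, ls$total$val)
    if (!is.finite(ls$total$val)) {
      cond <- structure(
        class = c("tq_divergence", "error", "condition"),
        list(message = paste0("loss diverged at step ", step),
             call = NULL, trace = finish_trace(trace[seq_len(step)]))
      )
      stop(cond)
    }
    tq_backward(fw$tape, ls$total)
    # global gradient-norm clipping
    sq <- 0
    for (nm in names(network$params)) {
      gw <- fw$pnodes[[nm]]$w$grad
      gb <- fw$pnodes[[nm]]$b$grad
      if (!is.null(gw)) sq <- sq + sum(gw^2)
      if (!is.null(gb)) sq <- sq + sum(gb^2)
    }
    gp <- fw$P_logits_node$grad
    if (!is.null(gp)) sq <- sq + sum(gp^2)
    scale <- if (sqrt(sq) > clip_norm) clip_norm / sqrt(sq) else 1
    adam$t <- adam$t + 1
    for (nm in names(network$params)) {
      gw <- fw$pnodes[[nm]]$w$grad
      gb <- fw$pnodes[[nm]]$b$grad
      if (!is.null(gw)) gw <- gw * scale
      if (!is.null(gb)) gb <- gb * scale
      if (!is.null(gw)) {
        network$params[[nm]]$w <- upd(paste0(nm, ".w"), network$params[[nm]]$w, gw)
      }
      if (!is.null(gb)) {
        network$params[[nm]]$b <- upd(paste0(nm, ".b"), network$params[[nm]]$b, gb)
      }
    }
    if (!is.null(gp)) {
      network$P_logits <- upd("P_logits", network$P_logits, gp * scale)
    }
  }

  structure(
    list(network = network, trace = finish_trace(trace), config = cf),
    class = "tq_fit"
  )
}

finish_trace <- function(rows) {
  if (length(rows) == 0) {
    return(tibble::tibble(
      step = integer(), roi_region = numeric(), hpf_region = numeric(),
      nucleus_unconstrained = numeric(), nucleus_constrained = numeric(),
      total = numeric()
    ))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(
    step = as.integer(m[, 1]), roi_region = m[, 2], hpf_region = m[, 3],
    nucleus_unconstrained = m[, 4], nucleus_constrained = m[, 5],
    total = m[, 6]
  )
}

# extract the network inputs (10x image, 20x HPF crop) from a tq_roi
roi_network_inputs <- function(sample, config) {
  H2 <- nrow(sample$region_mask_20x)
  ri <- (H2 / 4 + 1):(3 * H2 / 4)
  list(
    rgb_10x = sample$rgb_10x,
    rgb_20x_hpf = sample$rgb_20x[ri, ri, , drop = FALSE]
  )
}

#' @export
print.tq_fit <- function(x, ...) {
  cat(
    "<tq_fit> ", nrow(x$trace), " steps; final total loss ",
    signif(utils::tail(x$trace$total, 1), 4), "\n", sep = ""
  )
  invisible(x)
}
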