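# Minimal define-by-run reverse-mode autodiff over dense arrays.
#
# Values are numeric arrays with dims (H, W, C, N). A tape records op nodes
# in creation order (which is a topological order); backward() walks it in
# reverse. Parameters are persistent environments holding $value/$grad and
# are valid parents of op nodes without living on the tape themselves.

ag_tape <- function(grad_on = TRUE) {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e$grad_on <- grad_on
  e
}

ag_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

ag_node <- function(tape, value, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  ag_push(tape, node)
}

#' @keywords internal
ag_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p
}

ag_leaf <- function(tape, value) ag_node(tape, value)

ag_accum <- function(target, g) {
  if (is.null(target$grad)) target$grad <- g else target$grad <- target$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) ag_accum(node$parents[[j]], gs[[j]])
    }
    node$grad <- NULL # free memory as we go
  }
  invisible(NULL)
}

dims4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a dim-ed array")
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("expected a rank-3 or rank-4 array")
  as.integer(d)
}

# ---- ops ---------------------------------------------------------------

op_conv <- function(tape, x, w, b, k) {
  d <- dims4(x$value)
  cout <- length(b$value)
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, d[1], d[2], d[3], cout, k,
                      d[4])
  dim(y) <- c(d[1], d[2], cout, d[4])
  ag_node(tape, y, list(x, w, b), function(node) {
    g <- cpp_conv2d_bwd(x$value, w$value, node$grad,
                        d[1], d[2], d[3], cout, k, d[4])
    dim(g$gx) <- dim(x$value)
    dim(g$gw) <- dim(w$value)
    list(g$gx, g$gw, g$gb)
  })
}

op_convT2 <- function(tape, x, w, b) {
  d <- dims4(x$value)
  cout <- length(b$value)
  y <- cpp_convT2_fwd(x$value, w$value, b$value, d[1], d[2], d[3], cout, d[4])
  dim(y) <- c(2L * d[1], 2L * d[2], cout, d[4])
  ag_node(tape, y, list(x, w, b), function(node) {
    g <- cpp_convT2_bwd(x$value, w$value, node$grad,
                        d[1], d[2], d[3], cout, d[4])
    dim(g$gx) <- dim(x$value)
    dim(g$gw) <- dim(w$value)
    list(g$gx, g$gw, g$gb)
  })
}

op_maxpool2 <- function(tape, x) {
  d <- dims4(x$value)
  r <- cpp_maxpool2_fwd(x$value, d[1], d[2], d[3], d[4])
  y <- r$y
  dim(y) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  idx <- r$idx
  ag_node(tape, y, list(x), function(node) {
    gx <- cpp_maxpool2_bwd(idx, node$grad, d[1], d[2], d[3], d[4])
    dim(gx) <- dim(x$value)
    list(gx)
  })
}

op_upsample2 <- function(tape, x) {
  d <- dims4(x$value)
  y <- cpp_upsample2_fwd(x$value, d[1], d[2], d[3], d[4])
  dim(y) <- c(2L * d[1], 2L * d[2], d[3], d[4])
  ag_node(tape, y, list(x), function(node) {
    gx <- cpp_upsample2_bwd(node$grad, d[1], d[2], d[3], d[4])
    dim(gx) <- dim(x$value)
    list(gx)
  })
}

op_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  dim(y) <- dim(x$value)
  ag_node(tape, y, list(x), function(node) {
    list(node$grad * (x$value > 0))
  })
}

# PReLU with one trainable slope per channel (dim 3).
op_prelu <- function(tape, x, alpha) {
  d <- dims4(x$value)
  hw <- d[1] * d[2]
  pos <- pmax(x$value, 0)
  neg <- x$value - pos
  y <- pos + neg * rep(alpha$value, each = hw)
  dim(y) <- d
  ag_node(tape, y, list(x, alpha), function(node) {
    gx <- node$grad * ((x$value > 0) + (x$value <= 0) * rep(alpha$value,
                                                            each = hw))
    dim(gx) <- d
    gneg <- node$grad * neg
    ga <- .rowSums(matrix(.colSums(matrix(gneg, hw, d[3] * d[4]), hw,
                                   d[3] * d[4]), d[3], d[4]), d[3], d[4])
    list(gx, ga)
  })
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  dim(y) <- dim(x$value)
  ag_node(tape, y, list(x), function(node) {
    list(node$grad * y * (1 - y))
  })
}

op_add <- function(tape, ...) {
  xs <- list(...)
  y <- xs[[1]]$value
  for (i in seq_along(xs)[-1]) y <- y + xs[[i]]$value
  ag_node(tape, y, xs, function(node) {
    lapply(xs, function(.) node$grad)
  })
}

# Broadcast multiply by a single-channel spatial mask (H, W, 1, N).
op_mul_mask <- function(tape, x, mask) {
  d <- dims4(x$value)
  dm <- dims4(mask$value)
  if (dm[3] != 1L || any(dm[c(1, 2, 4)] != d[c(1, 2, 4)])) {
    stop("attention mask must be (H, W, 1, N) matching the gated features",
         call. = FALSE)
  }
  hw <- d[1] * d[2]
  mfull <- array(apply(array(mask$value, c(hw, d[4])), 2,
                       function(col) rep(col, times = d[3])), dim = d)
  y <- x$value * mfull
  ag_node(tape, y, list(x, mask), function(node) {
    gx <- node$grad * mfull
    gm3 <- array(node$grad * x$value, c(hw, d[3], d[4]))
    gm <- array(0, c(hw, d[4]))
    for (c in seq_len(d[3])) gm <- gm + gm3[, c, , drop = FALSE][, 1, ]
    dim(gm) <- dm
    list(gx, gm)
  })
}

op_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dims4(x$value))
  cs <- vapply(ds, function(d) d[3], integer(1))
  d0 <- ds[[1]]
  ctot <- sum(cs)
  n <- d0[4]
  hw <- d0[1] * d0[2]
  y <- array(0, c(d0[1], d0[2], ctot, n))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(cs[i]), ] <- xs[[i]]$value
    off <- off + cs[i]
  }
  ag_node(tape, y, xs, function(node) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      g <- node$grad[, , off + seq_len(cs[i]), , drop = FALSE]
      dim(g) <- c(d0[1], d0[2], cs[i], n)
      out[[i]] <- g
      off <- off + cs[i]
    }
    out
  })
}

# Batch normalization over (H, W, N) per channel. `state` is the layer env
# carrying running statistics (used in eval mode). Channel-wise vectors are
# broadcast by recycling a length-(H*W*C) pattern across the batch, which
# avoids any aperm of the activations.
op_batchnorm <- function(tape, x, gamma, beta, state, training,
                         eps = 1e-5, momentum = 0.9) {
  d <- dims4(x$value)
  hw <- d[1] * d[2]
  C <- d[3]
  nb <- hw * d[4]
  bcast <- function(v) rep(v, each = hw) # recycles over the batch dim
  chan_sum <- function(a) {
    .rowSums(matrix(.colSums(matrix(a, hw, C * d[4]), hw, C * d[4]), C, d[4]),
             C, d[4])
  }
  if (training) {
    mu <- chan_sum(x$value) / nb
    va <- pmax(chan_sum(x$value * x$value) / nb - mu^2, 0)
    state$run_mean <- momentum * state$run_mean + (1 - momentum) * mu
    state$run_var <- momentum * state$run_var + (1 - momentum) * va
  } else {
    mu <- state$run_mean
    va <- state$run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (x$value - bcast(mu)) * bcast(invstd)
  y <- xhat * bcast(gamma$value) + bcast(beta$value)
  dim(y) <- d
  ag_node(tape, y, list(x, gamma, beta), function(node) {
    gy <- node$grad
    ggamma <- chan_sum(gy * xhat)
    gbeta <- chan_sum(gy)
    gxhat <- gy * bcast(gamma$value)
    if (training) {
      gx <- (gxhat - bcast(chan_sum(gxhat) / nb) -
               xhat * bcast(chan_sum(gxhat * xhat) / nb)) * bcast(invstd)
    } else {
      gx <- gxhat * bcast(invstd)
    }
    dim(gx) <- d
    list(gx, ggamma, gbeta)
  })
}

# Per-pixel softmax over the channel axis; pure function, used at inference.
softmax_channels <- function(x) {
  d <- dims4(x)
  m <- matrix(aperm(array(x, d), c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])
  mx <- m[1, ]
  if (d[3] > 1L) for (k in 2:d[3]) mx <- pmax(mx, m[k, ])
  ex <- exp(m - rep(mx, each = d[3]))
  p <- ex / rep(.colSums(ex, d[3], ncol(ex)), each = d[3])
  aperm(array(p, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

# Fused softmax + categorical cross-entropy, mean over all pixels and the
# batch. `y` is a one-hot array with the logits' dims. The softmax
# probabilities are kept on the node ($probs) for reuse (e.g. accuracy).
op_softmax_ce <- function(tape, logits, y) {
  d <- dims4(logits$value)
  np <- d[1] * d[2] * d[4]
  p <- softmax_channels(logits$value)
  eps <- 1e-12
  loss <- -sum(log(pmax(p, eps)) * y) / np
  node <- ag_node(tape, loss, list(logits), function(node) {
    g <- node$grad * (p - y) / np
    dim(g) <- d
    list(g)
  })
  node$probs <- p
  node
}
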