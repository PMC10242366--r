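# Interchangeable network building blocks.
#
# A "module" is a list with $kind, $params (list of parameter environments)
# and $fwd(tape, ..., training), classed "spineseg_module". Blocks preserve
# spatial extent (same padding); only pooling halves it and transposed
# convolution / nearest upsampling doubles it.

he_uniform <- function(k, cin, cout) {
  limit <- sqrt(6 / (k * k * cin))
  array(stats::runif(k * k * cin * cout, -limit, limit), c(k, k, cin, cout))
}

make_conv <- function(cin, cout, k) {
  list(w = ag_param(he_uniform(k, cin, cout)),
       b = ag_param(numeric(cout)), k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout))
}

make_convT2 <- function(cin, cout) {
  limit <- sqrt(6 / (4 * cin))
  list(w = ag_param(array(stats::runif(4 * cin * cout, -limit, limit),
                          c(2, 2, cin, cout))),
       b = ag_param(numeric(cout)), cin = cin, cout = cout)
}

make_bn <- function(channels) {
  state <- new.env(parent = emptyenv())
  state$run_mean <- numeric(channels)
  state$run_var <- rep(1, channels)
  list(gamma = ag_param(rep(1, channels)), beta = ag_param(numeric(channels)),
       state = state)
}

make_act <- function(channels, activation) {
  activation <- match.arg(activation, c("relu", "prelu"))
  if (activation == "relu") {
    list(kind = "relu")
  } else {
    list(kind = "prelu", alpha = ag_param(rep(0.25, channels)))
  }
}

conv_node <- function(tape, layer, x) op_conv(tape, x, layer$w, layer$b, layer$k)
convT2_node <- function(tape, layer, x) op_convT2(tape, x, layer$w, layer$b)
bn_node <- function(tape, layer, x, training) {
  op_batchnorm(tape, x, layer$gamma, layer$beta, layer$state, training)
}
act_node <- function(tape, layer, x) {
  if (layer$kind == "relu") op_relu(tape, x) else op_prelu(tape, x, layer$alpha)
}

collect_params <- function(...) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x) && !identical(class(x), "spineseg_module")) {
      for (el in x) walk(el)
    } else if (inherits(x, "spineseg_module")) {
      for (p in x$params) out[[length(out) + 1L]] <<- p
    }
  }
  for (a in list(...)) walk(a)
  out
}

param_list <- function(layers) {
  # pull out ag_param environments from nested layer lists
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (!is.null(x$value) && is.null(x$run_mean)) {
        out[[length(out) + 1L]] <<- x
      }
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(layers)
  out
}

new_module <- function(kind, layers, fwd, ...) {
  structure(c(list(kind = kind, layers = layers, params = param_list(layers),
                   fwd = fwd), list(...)),
            class = "spineseg_module")
}

#' Number of trainable parameters in a module or model
#'
#' Counts every trainable scalar: convolution kernels and biases, batch-norm
#' scale/shift pairs and PReLU slopes. Batch-norm running statistics are not
#' trainable and are excluded.
#'
#' @param x A module (see [conv_block()]) or a model from [build_topology()].
#' @return Integer number of trainable parameters.
#' @export
n_params <- function(x) {
  sum(vapply(x$params, function(p) length(p$value), numeric(1)))
}

#' Convolutional building blocks
#'
#' Constructs one of the three convolutional block types used throughout the
#' encoder/decoder branches:
#' \describe{
#'   \item{`unet`}{two 3x3 convolutions, each followed by batch
#'     normalization and an activation.}
#'   \item{`vgg`}{two or three 3x3 convolutions, each followed by an
#'     activation (PReLU in its registry use).}
#'   \item{`dense`}{three units of batch norm, activation and convolution
#'     with kernel sizes 5x5, 3x3 and 1x1, all 64 channels, with dense
#'     connections: unit 2 sees `concat(input, out1)` and unit 3 sees
#'     `concat(input, out1, out2)`. Output width is fixed at 64 regardless
#'     of `channels`.}
#' }
#'
#' @param kind One of `"unet"`, `"vgg"`, `"dense"`.
#' @param cin Input channel count.
#' @param channels Output channel count (ignored by `"dense"`, fixed at 64).
#' @param depth For `"vgg"` only: 2 or 3 convolution layers.
#' @param activation `"relu"` or `"prelu"`.
#' @return A module; run it with [module_forward()].
#' @export
conv_block <- function(kind = c("unet", "vgg", "dense"), cin, channels,
                       depth = 2L, activation = "relu") {
  kind <- match.arg(kind)
  if (kind != "dense" && channels < 1) {
    stop("channels must be >= 1", call. = FALSE)
  }
  if (kind == "unet") {
    layers <- list(conv1 = make_conv(cin, channels, 3L), bn1 = make_bn(channels),
                   act1 = make_act(channels, activation),
                   conv2 = make_conv(channels, channels, 3L),
                   bn2 = make_bn(channels),
                   act2 = make_act(channels, activation))
    fwd <- function(tape, x, training = FALSE) {
      h <- act_node(tape, layers$act1,
                    bn_node(tape, layers$bn1,
                            conv_node(tape, layers$conv1, x), training))
      act_node(tape, layers$act2,
               bn_node(tape, layers$bn2,
                       conv_node(tape, layers$conv2, h), training))
    }
    return(new_module("unet_conv", layers, fwd, cout = channels))
  }
  if (kind == "vgg") {
    if (!depth %in% c(2L, 3L)) stop("vgg block depth must be 2 or 3",
                                    call. = FALSE)
    convs <- list()
    acts <- list()
    ci <- cin
    for (i in seq_len(depth)) {
      convs[[i]] <- make_conv(ci, channels, 3L)
      acts[[i]] <- make_act(channels, activation)
      ci <- channels
    }
    layers <- list(convs = convs, acts = acts)
    fwd <- function(tape, x, training = FALSE) {
      h <- x
      for (i in seq_len(depth)) {
        h <- act_node(tape, layers$acts[[i]], conv_node(tape, layers$convs[[i]], h))
      }
      h
    }
    return(new_module("vgg_conv", layers, fwd, cout = channels, depth = depth))
  }
  # dense block: fixed 64 channels, kernels 5/3/1, BN -> act -> conv units
  ks <- c(5L, 3L, 1L)
  cins <- c(cin, cin + 64L, cin + 128L)
  units <- lapply(1:3, function(i) {
    list(bn = make_bn(cins[i]), act = make_act(cins[i], activation),
         conv = make_conv(cins[i], 64L, ks[i]))
  })
  layers <- list(units = units)
  fwd <- function(tape, x, training = FALSE) {
    u <- function(i, inp) {
      conv_node(tape, layers$units[[i]]$conv,
                act_node(tape, layers$units[[i]]$act,
                         bn_node(tape, layers$units[[i]]$bn, inp, training)))
    }
    o1 <- u(1, x)
    o2 <- u(2, op_concat(tape, list(x, o1)))
    u(3, op_concat(tape, list(x, o1, o2)))
  }
  new_module("dense_conv", layers, fwd, cout = 64L)
}

#' Multi-kernel input block
#'
#' Four parallel convolution paths over the raw input with kernel sizes 1, 3,
#' 5 and 7, each `m/4` channels wide and followed by an activation; their
#' outputs are concatenated to `m` channels (a naive Inception-style
#' multilevel feature extractor).
#'
#' @param cin Input channels (2 for a T2w/T1w slice pair).
#' @param m Total output channels; must be divisible by 4.
#' @inheritParams conv_block
#' @export
multi_kernel_input <- function(cin, m, activation = "relu") {
  if (m %% 4L != 0L) stop("m must be divisible by 4", call. = FALSE)
  w <- m %/% 4L
  ks <- c(1L, 3L, 5L, 7L)
  paths <- lapply(ks, function(k) {
    list(conv = make_conv(cin, w, k), act = make_act(w, activation))
  })
  layers <- list(paths = paths)
  fwd <- function(tape, x, training = FALSE) {
    outs <- lapply(layers$paths, function(p) {
      act_node(tape, p$act, conv_node(tape, p$conv, x))
    })
    op_concat(tape, outs)
  }
  new_module("multi_kernel", layers, fwd, cout = m)
}

#' Attention gate
#'
#' Learns a single-channel spatial mask that filters encoder features before
#' fusion. The encoder features and the gating signal (the decoder output one
#' level below, upsampled x2 to match) are each passed through a 1x1
#' convolution, added, ReLU-activated, reduced to one channel by another 1x1
#' convolution and squashed by a sigmoid; the mask multiplies the encoder
#' features elementwise, so the gate can only attenuate.
#'
#' @param enc_channels Channels of the encoder feature map being gated.
#' @param gate_channels Channels of the gating signal from the level below.
#' @export
attention_gate <- function(enc_channels, gate_channels) {
  f_int <- max(1L, enc_channels %/% 2L)
  layers <- list(theta = make_conv(enc_channels, f_int, 1L),
                 phi = make_conv(gate_channels, f_int, 1L),
                 psi = make_conv(f_int, 1L, 1L))
  fwd <- function(tape, enc, gate, training = FALSE) {
    g <- op_upsample2(tape, gate)
    if (!all(dims4(g$value)[1:2] == dims4(enc$value)[1:2])) {
      stop("attention gate: spatial mismatch between encoder and gating signal",
           call. = FALSE)
    }
    a <- op_relu(tape, op_add(tape, conv_node(tape, layers$theta, enc),
                              conv_node(tape, layers$phi, g)))
    mask <- op_sigmoid(tape, conv_node(tape, layers$psi, a))
    op_mul_mask(tape, enc, mask)
  }
  new_module("attention_gate", layers, fwd, cout = enc_channels)
}

#' Deep-supervision signal heads
#'
#' Builds the auxiliary 1x1-convolution signal graphs used for feature
#' fusion or classification-input enrichment. All 1x1 convolutions emit `m`
#' channels and upsampling is nearest-neighbour x2.
#' \describe{
#'   \item{v1}{`S[n] = conv1x1(C[n]) + up(S[n+1])`, `S[5] = conv1x1(C[5])`;
#'     returns signals `S1..S5` over the encoder outputs.}
#'   \item{v2}{intermediate signals `prevS[n] = conv1x1(C[n]) +
#'     up(prevS[n+1])` computed bottom-up with `prevS[5] = conv1x1(C[5])`,
#'     then `S1 = prevS1` and `S[n] = conv1x1(C[n]) + up(prevS[n+1]) +
#'     maxpool2(S[n-1])` for n = 2..4 (the max-pooled term flows down from
#'     the shallower level); returns `S1..S4`.}
#'   \item{v3}{`Z[n] = conv1x1(T[n]) + up(Z[n+1])`, `Z[5] = conv1x1(T[5])`
#'     over the decoder outputs; returns the single full-extent `Z1`.}
#' }
#'
#' @param version 1, 2 or 3.
#' @param channels Integer vector of input channel counts for levels 1..L
#'   (shallowest first; the last entry is the bottleneck).
#' @param m Channel width of every signal.
#' @export
ds_head <- function(version, channels, m) {
  version <- as.integer(version)
  L <- length(channels)
  convs <- lapply(channels, function(cn) make_conv(cn, m, 1L))
  if (version == 1L) {
    layers <- list(convs = convs)
    fwd <- function(tape, C, training = FALSE) {
      S <- vector("list", L)
      S[[L]] <- conv_node(tape, layers$convs[[L]], C[[L]])
      for (n in rev(seq_len(L - 1L))) {
        S[[n]] <- op_add(tape, conv_node(tape, layers$convs[[n]], C[[n]]),
                         op_upsample2(tape, S[[n + 1L]]))
      }
      S
    }
    return(new_module("ds_v1", layers, fwd, cout = m))
  }
  if (version == 2L) {
    sconvs <- lapply(channels[-c(1L, L)], function(cn) make_conv(cn, m, 1L))
    layers <- list(pconvs = convs, sconvs = sconvs)
    fwd <- function(tape, C, training = FALSE) {
      prevS <- vector("list", L)
      prevS[[L]] <- conv_node(tape, layers$pconvs[[L]], C[[L]])
      for (n in rev(seq_len(L - 1L))) {
        prevS[[n]] <- op_add(tape, conv_node(tape, layers$pconvs[[n]], C[[n]]),
                             op_upsample2(tape, prevS[[n + 1L]]))
      }
      S <- vector("list", L - 1L)
      S[[1L]] <- prevS[[1L]]
      if (L > 2L) {
        for (n in 2:(L - 1L)) {
          S[[n]] <- op_add(tape,
                           conv_node(tape, layers$sconvs[[n - 1L]], C[[n]]),
                           op_upsample2(tape, prevS[[n + 1L]]),
                           op_maxpool2(tape, S[[n - 1L]]))
        }
      }
      S
    }
    return(new_module("ds_v2", layers, fwd, cout = m))
  }
  if (version == 3L) {
    layers <- list(convs = convs)
    fwd <- function(tape, T, training = FALSE) {
      Z <- conv_node(tape, layers$convs[[L]], T[[L]])
      for (n in rev(seq_len(L - 1L))) {
        Z <- op_add(tape, conv_node(tape, layers$convs[[n]], T[[n]]),
                    op_upsample2(tape, Z))
      }
      Z
    }
    return(new_module("ds_v3", layers, fwd, cout = m))
  }
  stop("unknown deep-supervision version", call. = FALSE)
}

#' Run a module forward on plain arrays
#'
#' Convenience wrapper for inspecting blocks outside a training graph: wraps
#' the inputs as constant nodes, runs the module and returns plain arrays.
#' Inputs may be rank-3 `(H, W, C)` or rank-4 `(H, W, C, N)`.
#'
#' @param module A module from [conv_block()], [multi_kernel_input()],
#'   [attention_gate()] or [ds_head()].
#' @param ... Input arrays (one per module input; `ds_head` modules take a
#'   single list of per-level arrays).
#' @param training Use batch statistics in batch-norm layers.
#' @return An array, or a list of arrays for multi-output modules.
#' @export
module_forward <- function(module, ..., training = FALSE) {
  tape <- ag_tape(grad_on = FALSE)
  wrap <- function(x) {
    if (is.list(x)) {
      lapply(x, wrap)
    } else {
      d <- dims4(x)
      dim(x) <- d
      ag_leaf(tape, x)
    }
  }
  inputs <- lapply(list(...), wrap)
  out <- do.call(module$fwd, c(list(tape), inputs, list(training = training)))
  unwrap <- function(o) if (is.list(o)) lapply(o, unwrap) else o$value
  unwrap(out)
}
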