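# Assembly of complete encoder-decoder networks from letter-coded
# identifiers, plus the registry of the thirteen evaluated configurations.
#
# Letter code: U = original U-Net conv block, V = VGG16-style block (encoder
# only; the decoder falls back to U), Q = dense block, M = multi-kernel
# input, A = attention gates replacing skip connections, D = deep
# supervision (DS.v3 on the classification input; DS.v1/DS.v2 as fusion).

topology_table <- function() {
  # id, configuration, encoder, decoder, multi-kernel, fusion, ds_v3,
  # optimizer, learning rate, activation
  rows <- list(
    list("UDD2", "U-Net + DS.v3 + DS.v2", "U", "U", FALSE, "ds_v2", TRUE,
         "adam", 0.00033, "relu"),
    list("UMDD", "U-Net + multi-kernel + DS.v3 + DS.v1", "U", "U", TRUE,
         "ds_v1", TRUE, "adam", 0.00033, "relu"),
    list("UDD", "U-Net + DS.v3 + DS.v1", "U", "U", FALSE, "ds_v1", TRUE,
         "adam", 0.00033, "relu"),
    list("UQD", "U-Net + DenseBlock + DS.v3", "Q", "Q", FALSE, "skip", TRUE,
         "adam", 0.00033, "relu"),
    list("UVDD", "U-Net + VGG16 + DS.v3 + DS.v1", "V", "U", FALSE, "ds_v1",
         TRUE, "adam", 0.00033, "prelu"),
    list("UVMD", "U-Net + VGG16 + multi-kernel + DS.v3", "V", "U", TRUE,
         "skip", TRUE, "adam", 0.00033, "relu"),
    list("UAMD", "U-Net + attGate + multi-kernel + DS.v3", "U", "U", TRUE,
         "attention", TRUE, "adam", 0.00033, "relu"),
    list("UMD", "U-Net + multi-kernel + DS.v3", "U", "U", TRUE, "skip", TRUE,
         "adam", 0.00033, "relu"),
    list("UAD", "U-Net + attGate + DS.v3", "U", "U", FALSE, "attention", TRUE,
         "rmsprop", 0.001, "relu"),
    list("UD", "U-Net + DS.v3", "U", "U", FALSE, "skip", TRUE,
         "adam", 0.00033, "relu"),
    list("UA", "U-Net + attGate", "U", "U", FALSE, "attention", FALSE,
         "adam", 0.00033, "relu"),
    list("U1", "U-Net", "U", "U", FALSE, "skip", FALSE,
         "adadelta", 1.0, "relu"),
    list("FCN", "FCN8", NA, NA, FALSE, NA, FALSE, "adam", 0.00033, "relu")
  )
  rows
}

#' Registry of the thirteen network topologies
#'
#' Returns the declarative specifications of all thirteen registered
#' configurations: twelve U-Net variants assembled from the interchangeable
#' blocks plus the FCN8 baseline, each with its tuned optimizer, learning
#' rate and hidden-layer activation (U1 uses Adadelta with learning rate 1.0,
#' UAD uses RMSprop with 0.001, all others Adam with 0.00033; UVDD is the
#' only PReLU configuration). DS.v2 fusion appears only in UDD2.
#'
#' @param m Base channel count at the first encoder level (default 64;
#'   reduce for desk-scale experiments).
#' @return A list of `spineseg_topology_spec` objects, one per identifier.
#' @seealso [build_topology()]
#' @export
topology_registry <- function(m = 64L) {
  lapply(topology_table(), function(r) {
    structure(list(id = r[[1]], configuration = r[[2]], encoder_block = r[[3]],
                   decoder_block = r[[4]], multi_kernel = r[[5]],
                   fusion = r[[6]], use_ds_v3 = r[[7]], m = as.integer(m),
                   levels = 4L, optimizer = r[[8]], learning_rate = r[[9]],
                   activation = r[[10]]),
              class = "spineseg_topology_spec")
  })
}

#' @export
print.spineseg_topology_spec <- function(x, ...) {
  cat(sprintf("<topology %s> %s | optimizer %s (lr %g), %s\n",
              x$id, x$configuration, x$optimizer, x$learning_rate,
              toupper(x$activation)))
  invisible(x)
}

#' Look up one topology specification
#'
#' @param id A registered identifier (e.g. `"UMD"`).
#' @inheritParams topology_registry
#' @export
topology_spec <- function(id, m = 64L) {
  reg <- topology_registry(m)
  ids <- vapply(reg, `[[`, character(1), "id")
  i <- match(id, ids)
  if (is.na(i)) {
    stop(sprintf("unknown topology id '%s'; registered ids: %s", id,
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  reg[[i]]
}

enc_channels_for <- function(block, m) {
  if (block == "Q") rep(64L, 5L) else as.integer(m * 2^(0:4))
}

#' Build a network from a registered topology identifier
#'
#' Realizes the declarative specification as a trainable graph: a four-level
#' encoder (2x2 max-pooling between levels), a bottleneck block, a
#' four-level decoder where each level's input is
#' `D[n] = concat(S[n], transposed_conv(T[n+1]))` with the fusion signal
#' `S[n]` given by plain skip connections, attention gates, or the DS.v1 /
#' DS.v2 deep-supervision graphs, an optional multi-kernel input block, an
#' optional DS.v3 head enriching the classification input, and a
#' classification block (1x1 convolution to `num_classes` channels followed
#' by a per-pixel softmax).
#'
#' Dense (Q) blocks keep a fixed width of 64 channels at every level; the
#' other block types double the width per level from `m`. Combining Q blocks
#' with DS.v1/DS.v2 fusion is rejected (no registered configuration does).
#'
#' @param id Registered topology identifier; `"FCN"` dispatches to
#'   [build_fcn8()].
#' @param m Base channel count (must be divisible by 4 when the topology has
#'   a multi-kernel input).
#' @param num_classes Output classes `K` (12 in the lumbar-spine task).
#' @param input_channels Input channels (2: T2w then T1w).
#' @return A `spineseg_model`; run it with [model_forward()] or
#'   [predict_scores()].
#' @export
build_topology <- function(id, m = 64L, num_classes = 12L,
                           input_channels = 2L) {
  spec <- topology_spec(id, m)
  if (identical(spec$id, "FCN")) {
    return(build_fcn8(num_classes, input_channels, base_filters = m,
                      spec = spec))
  }
  m <- as.integer(m)
  if (spec$encoder_block == "Q" && spec$fusion %in% c("ds_v1", "ds_v2")) {
    stop("dense (Q) blocks cannot be combined with DS.v1/DS.v2 fusion",
         call. = FALSE)
  }
  act <- spec$activation
  enc_ch <- enc_channels_for(spec$encoder_block, m)
  dec_ch <- enc_channels_for(spec$decoder_block, m)
  vgg_depth <- c(2L, 2L, 3L, 3L, 3L) # VGG16 layout per level

  mk <- if (spec$multi_kernel) multi_kernel_input(input_channels, m, act)
  in1 <- if (spec$multi_kernel) m else input_channels

  make_block <- function(branch_block, cin, level) {
    switch(branch_block,
           U = conv_block("unet", cin, enc_channels_for("U", m)[level],
                          activation = act),
           V = conv_block("vgg", cin, enc_channels_for("V", m)[level],
                          depth = vgg_depth[level], activation = act),
           Q = conv_block("dense", cin, 64L, activation = act))
  }
  enc <- vector("list", 4L)
  cin <- in1
  for (n in 1:4) {
    enc[[n]] <- make_block(spec$encoder_block, cin, n)
    cin <- enc_ch[n]
  }
  bottleneck <- make_block(spec$encoder_block, enc_ch[4], 5L)

  s_ch <- switch(spec$fusion,
                 skip = enc_ch[1:4],
                 attention = enc_ch[1:4],
                 ds_v1 = rep(m, 4L),
                 ds_v2 = rep(m, 4L))
  fusion_mod <- switch(spec$fusion,
                       skip = NULL,
                       attention = lapply(1:4, function(n) {
                         gate_ch <- if (n == 4L) enc_ch[5] else dec_ch[n + 1L]
                         attention_gate(enc_ch[n], gate_ch)
                       }),
                       ds_v1 = ds_head(1L, enc_ch, m),
                       ds_v2 = ds_head(2L, enc_ch, m))
  upconv <- lapply(1:4, function(n) {
    cin_up <- if (n == 4L) enc_ch[5] else dec_ch[n + 1L]
    make_convT2(cin_up, dec_ch[n])
  })
  dec <- lapply(1:4, function(n) {
    make_block(spec$decoder_block, s_ch[n] + dec_ch[n], n)
  })
  ds3 <- if (spec$use_ds_v3) ds_head(3L, c(dec_ch[1:4], enc_ch[5]), m)
  feat_ch <- if (spec$use_ds_v3) m else dec_ch[1]
  cls <- make_conv(feat_ch, as.integer(num_classes), 1L)

  layers <- list(mk = mk, enc = enc, bottleneck = bottleneck,
                 fusion = fusion_mod, upconv = upconv, dec = dec, ds3 = ds3,
                 cls = cls)

  fwd <- function(tape, x, training = FALSE) {
    h <- x
    if (!is.null(layers$mk)) h <- layers$mk$fwd(tape, h, training)
    C <- vector("list", 5L)
    for (n in 1:4) {
      C[[n]] <- layers$enc[[n]]$fwd(tape, h, training)
      h <- op_maxpool2(tape, C[[n]])
    }
    C[[5]] <- layers$bottleneck$fwd(tape, h, training)
    S <- switch(spec$fusion,
                skip = C[1:4],
                attention = vector("list", 4L),
                ds_v1 = fusion_mod$fwd(tape, C, training)[1:4],
                ds_v2 = fusion_mod$fwd(tape, C, training))
    T <- vector("list", 5L)
    T[[5]] <- C[[5]]
    for (n in 4:1) {
      up <- convT2_node(tape, layers$upconv[[n]], T[[n + 1L]])
      if (spec$fusion == "attention") {
        S[[n]] <- layers$fusion[[n]]$fwd(tape, C[[n]], T[[n + 1L]], training)
      }
      D_in <- op_concat(tape, list(S[[n]], up))
      T[[n]] <- layers$dec[[n]]$fwd(tape, D_in, training)
    }
    feat <- if (!is.null(layers$ds3)) layers$ds3$fwd(tape, T, training)
            else T[[1]]
    logits <- conv_node(tape, layers$cls, feat)
    list(logits = logits, feat = feat)
  }

  structure(list(spec = spec, layers = layers,
                 params = param_list(layers),
                 num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels),
                 feat_channels = feat_ch,
                 extent_divisor = 16L, fwd = fwd),
            class = "spineseg_model")
}

#' Build the FCN8 baseline
#'
#' A VGG16-style backbone (block widths `b, 2b, 4b, 8b, 8b` with depths
#' 2/2/3/3/3 and 2x2 max-pooling after each block, giving stride 32),
#' 1x1 score taps at pool3, pool4 and the post-pool5 convolution, fused by
#' successive x2 learnable upsampling steps and brought back to full extent
#' by a final x8 (three stacked 2x2 transposed convolutions), ending in a
#' per-pixel softmax. Trained from scratch (no pretrained weights).
#'
#' @param num_classes Output classes.
#' @param input_channels Input channels.
#' @param base_filters Width `b` of the first block (64 in the original
#'   VGG16; reduce for desk-scale work).
#' @param spec Optional topology spec to attach (used by [build_topology()]).
#' @export
build_fcn8 <- function(num_classes = 12L, input_channels = 2L,
                       base_filters = 64L, spec = NULL) {
  if (is.null(spec)) spec <- topology_spec("FCN", base_filters)
  b <- as.integer(base_filters)
  K <- as.integer(num_classes)
  widths <- c(b, 2L * b, 4L * b, 8L * b, 8L * b)
  depths <- c(2L, 2L, 3L, 3L, 3L)
  blocks <- vector("list", 5L)
  cin <- as.integer(input_channels)
  for (n in 1:5) {
    blocks[[n]] <- conv_block("vgg", cin, widths[n], depth = depths[n],
                              activation = "relu")
    cin <- widths[n]
  }
  conv7 <- list(conv = make_conv(widths[5], widths[5], 3L),
                act = make_act(widths[5], "relu"))
  score5 <- make_conv(widths[5], K, 1L)
  score4 <- make_conv(widths[4], K, 1L)
  score3 <- make_conv(widths[3], K, 1L)
  up5 <- make_convT2(K, K)
  up4 <- make_convT2(K, K)
  up8 <- lapply(1:3, function(i) make_convT2(K, K))
  layers <- list(blocks = blocks, conv7 = conv7, score5 = score5,
                 score4 = score4, score3 = score3, up5 = up5, up4 = up4,
                 up8 = up8)
  fwd <- function(tape, x, training = FALSE) {
    d <- dims4(x$value)
    if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
      stop("FCN8 requires input extents divisible by 32", call. = FALSE)
    }
    h <- x
    pools <- vector("list", 5L)
    for (n in 1:5) {
      h <- op_maxpool2(tape, blocks[[n]]$fwd(tape, h, training))
      pools[[n]] <- h
    }
    h <- act_node(tape, conv7$act, conv_node(tape, conv7$conv, pools[[5]]))
    s5 <- conv_node(tape, layers$score5, h)
    f16 <- op_add(tape, convT2_node(tape, layers$up5, s5),
                  conv_node(tape, layers$score4, pools[[4]]))
    f8 <- op_add(tape, convT2_node(tape, layers$up4, f16),
                 conv_node(tape, layers$score3, pools[[3]]))
    out <- f8
    for (i in 1:3) out <- convT2_node(tape, layers$up8[[i]], out)
    list(logits = out, feat = NULL)
  }
  structure(list(spec = spec, layers = layers, params = param_list(layers),
                 num_classes = K, input_channels = as.integer(input_channels),
                 feat_channels = NA_integer_, extent_divisor = 32L, fwd = fwd),
            class = "spineseg_model")
}

#' @export
print.spineseg_model <- function(x, ...) {
  cat(sprintf("<spineseg model %s> %s | %d classes, %d input channels, %d parameters\n",
              x$spec$id, x$spec$configuration, x$num_classes,
              x$input_channels, n_params(x)))
  invisible(x)
}

#' Forward pass of a model
#'
#' @param model A `spineseg_model`.
#' @param x Input array `(H, W, C)` or batch `(H, W, C, N)`; extents must be
#'   divisible by the model's extent divisor (16; 32 for FCN8).
#' @param training Logical; use batch statistics in batch-norm layers.
#' @param features Also return the pre-classification feature tensor (the
#'   decoder top level or the DS.v3 output), used by tensor-input stacking.
#' @return Softmax score array with `num_classes` channels (per-pixel channel
#'   sums equal 1), or `list(scores, features)` when `features = TRUE`.
#' @export
model_forward <- function(model, x, training = FALSE, features = FALSE) {
  rank3 <- length(dim(x)) == 3L
  dim(x) <- dims4(x)
  if (dim(x)[3] != model$input_channels) {
    stop(sprintf("model expects %d input channels, got %d",
                 model$input_channels, dim(x)[3]), call. = FALSE)
  }
  tape <- ag_tape(grad_on = FALSE)
  out <- model$fwd(tape, ag_leaf(tape, x), training = training)
  scores <- softmax_channels(out$logits$value)
  if (rank3) scores <- scores[, , , 1, drop = TRUE]
  if (!features) return(scores)
  feat <- if (is.null(out$feat)) NULL else {
    f <- out$feat$value
    if (rank3) f <- f[, , , 1, drop = TRUE]
    f
  }
  list(scores = scores, features = feat)
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the topology identity (id, `m`, classes, input
#' channels) plus all trainable weights and batch-norm running statistics;
#' loading rebuilds the network and restores the state.
#'
#' @param model A `spineseg_model`.
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(id = model$spec$id, m = model$spec$m,
               num_classes = model$num_classes,
               input_channels = model$input_channels,
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_topology(ck$id, m = ck$m, num_classes = ck$num_classes,
                          input_channels = ck$input_channels)
  restore_model_state(model, ck$state)
  model
}

# snapshot / restore of all trainable weights and batch-norm running stats
model_state <- function(model) {
  list(params = lapply(model$params, function(p) p$value),
       bn = lapply(bn_states(model), function(s) {
         list(run_mean = s$run_mean, run_var = s$run_var)
       }))
}

restore_model_state <- function(model, state) {
  for (i in seq_along(model$params)) {
    model$params[[i]]$value <- state$params[[i]]
  }
  sts <- bn_states(model)
  for (i in seq_along(sts)) {
    sts[[i]]$run_mean <- state$bn[[i]]$run_mean
    sts[[i]]$run_var <- state$bn[[i]]$run_var
  }
  invisible(model)
}

bn_states <- function(model) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (!is.null(x$run_mean)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(model$layers)
  out
}
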