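# Classifier ensembles: model averaging (arithmetic / geometric mean of
# member softmax scores) and a trainable per-pixel stacking head over merged
# member representations, plus the registered ensemble compositions and the
# leave-one-out ablation procedure.

ensemble_table <- function() {
  list(
    E4 = c("UAD", "UMD", "UQD", "UDD"),
    E5 = c("UD", "UAD", "UMD", "UAMD", "UDD2"),
    E6 = c("UD", "UAD", "UMD", "UAMD", "UVMD", "UVDD"),
    E7 = c("UD", "UAD", "UMD", "UAMD", "UVMD", "UQD", "UDD2"),
    E8 = c("FCN", "UD", "UAD", "UMD", "UAMD", "UVMD", "UQD", "UDD2"),
    E9 = c("UD", "UAD", "UMD", "UAMD", "UVMD", "UVDD", "UQD", "UDD", "UMDD"),
    E10 = c("UD", "UAD", "UMD", "UAMD", "UVMD", "UVDD", "UQD", "UDD", "UMDD",
            "UDD2"),
    E11 = c("U1", "UA", "UD", "UAD", "UMD", "UAMD", "UVMD", "UVDD", "UQD",
            "UDD", "UMDD"),
    E12 = c("U1", "UA", "UD", "UAD", "UMD", "UAMD", "UVMD", "UVDD", "UQD",
            "UDD", "UMDD", "UDD2"),
    E13 = c("FCN", "U1", "UA", "UD", "UAD", "UMD", "UAMD", "UVMD", "UVDD",
            "UQD", "UDD", "UMDD", "UDD2")
  )
}

#' Registry of ensemble compositions
#'
#' The ten registered ensembles E4..E13 and the topology identifiers each
#' combines (4 to 13 members; the FCN baseline appears only in E8 and E13).
#'
#' @param id Optional single ensemble id; when omitted the whole registry is
#'   returned.
#' @return A named list of member-id vectors, or one vector when `id` is
#'   given.
#' @export
ensemble_registry <- function(id = NULL) {
  tab <- ensemble_table()
  if (is.null(id)) return(tab)
  if (!id %in% names(tab)) {
    stop(sprintf("unknown ensemble id '%s'", id), call. = FALSE)
  }
  tab[[id]]
}

#' Combine member score maps by model averaging
#'
#' Arithmetic mean: `Z = (1/R) sum(Z_r)`, which preserves per-pixel
#' normalization exactly. Geometric mean: `Z = (prod(Z_r))^(1/R)`; since the
#' R-th root of a product of probability vectors is not itself normalized,
#' member scores are floored at 1e-12 and the result is renormalized per
#' pixel (a class scored 0 by any member keeps an essentially absorbing
#' zero). Both modes are order-invariant.
#'
#' @param member_scores List of `R >= 1` normalized `(H, W, K)` score
#'   arrays of equal shape.
#' @param mode `"arith"` or `"geo"`.
#' @return A normalized `(H, W, K)` score array.
#' @export
average_ensemble <- function(member_scores, mode = c("arith", "geo")) {
  mode <- match.arg(mode)
  R <- length(member_scores)
  if (R == 0L) stop("ensemble needs at least one member", call. = FALSE)
  d <- dim(member_scores[[1]])
  for (s in member_scores) {
    if (!all(dim(s) == d)) {
      stop("member score maps differ in shape", call. = FALSE)
    }
  }
  if (mode == "arith") {
    out <- member_scores[[1]]
    if (R > 1L) for (r in 2:R) out <- out + member_scores[[r]]
    return(out / R)
  }
  logs <- log(pmax(member_scores[[1]], 1e-12))
  if (R > 1L) for (r in 2:R) logs <- logs + log(pmax(member_scores[[r]], 1e-12))
  g <- exp(logs / R)
  dim(g) <- d
  hw <- d[1] * d[2]
  norm <- .rowSums(matrix(g, hw, d[3]), hw, d[3])
  out <- g / as.vector(norm)
  dim(out) <- d
  out
}

#' Stacking-head configuration
#'
#' Named registry configurations: `NAD` (normalized softmax scores, averaged,
#' dense meta-learner) and `TCD` (pre-classification tensors, concatenated,
#' dense meta-learner); both train with Adam at learning rate 0.00033 for 50
#' epochs. The `add` merge is supported but unregistered (known poor).
#'
#' @param id `"NAD"`, `"TCD"`, or `NULL` to configure manually.
#' @param input_kind `"N"` (softmax scores) or `"T"` (pre-classification
#'   feature tensors).
#' @param merge `"average"`, `"concat"` or `"add"`.
#' @param hidden_units Width of the dense ReLU meta-learner (per pixel).
#' @param epochs,learning_rate Training protocol of the head.
#' @export
stacking_config <- function(id = NULL, input_kind = "N", merge = "average",
                            hidden_units = 64L, epochs = 50L,
                            learning_rate = 0.00033) {
  if (!is.null(id)) {
    id <- match.arg(id, c("NAD", "TCD"))
    input_kind <- if (id == "NAD") "N" else "T"
    merge <- if (id == "NAD") "average" else "concat"
  }
  input_kind <- match.arg(input_kind, c("N", "T"))
  merge <- match.arg(merge, c("average", "concat", "add"))
  structure(list(id = id, input_kind = input_kind, merge = merge,
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = "adam"),
            class = "stacking_config")
}

member_tensor <- function(model, x, input_kind) {
  if (input_kind == "N") {
    model_forward(model, x)
  } else {
    out <- model_forward(model, x, features = TRUE)
    if (is.null(out$features)) {
      stop(sprintf("member %s exposes no pre-classification tensor; tensor-input stacking is unavailable for it",
                   model$spec$id), call. = FALSE)
    }
    out$features
  }
}

merge_tensors <- function(tensors, merge) {
  if (merge == "average" || merge == "add") {
    widths <- vapply(tensors, function(t) dims4(t)[3], integer(1))
    if (length(unique(widths)) != 1L) {
      stop("average/add merging requires equal member tensor widths",
           call. = FALSE)
    }
    out <- tensors[[1]]
    if (length(tensors) > 1L) {
      for (r in 2:length(tensors)) out <- out + tensors[[r]]
    }
    if (merge == "average") out <- out / length(tensors)
    out
  } else {
    d <- dims4(tensors[[1]])
    arrs <- lapply(tensors, function(t) { dim(t) <- dims4(t); t })
    ctot <- sum(vapply(arrs, function(t) dim(t)[3], integer(1)))
    out <- array(0, c(d[1], d[2], ctot, d[4]))
    off <- 0L
    for (t in arrs) {
      out[, , off + seq_len(dim(t)[3]), ] <- t
      off <- off + dim(t)[3]
    }
    out
  }
}

#' Build a stacking head over frozen member models
#'
#' The head operates per pixel on the merged member representation: a dense
#' ReLU meta-learner (realized as a 1x1 convolution, the shape-consistent
#' reading of a dense layer applied to an image tensor) followed by a dense
#' softmax prediction layer. Member weights are never touched.
#'
#' @param members List of trained `spineseg_model`s.
#' @param cfg A [stacking_config()].
#' @param num_classes Output classes `K`.
#' @return A `spineseg_stacking` object.
#' @export
build_stacking_head <- function(members, cfg = stacking_config("NAD"),
                                num_classes = 12L) {
  K <- as.integer(num_classes)
  R <- length(members)
  if (R == 0L) stop("ensemble needs at least one member", call. = FALSE)
  widths <- vapply(members, function(m) {
    if (cfg$input_kind == "N") K else {
      if (is.na(m$feat_channels)) {
        stop(sprintf("member %s exposes no pre-classification tensor; use input_kind = 'N'",
                     m$spec$id), call. = FALSE)
      }
      m$feat_channels
    }
  }, integer(1))
  merged_width <- if (cfg$merge == "concat") sum(widths) else {
    if (length(unique(widths)) != 1L) {
      stop("average/add merging requires equal member tensor widths",
           call. = FALSE)
    }
    widths[1]
  }
  layers <- list(dense1 = make_conv(merged_width, cfg$hidden_units, 1L),
                 act = make_act(cfg$hidden_units, "relu"),
                 dense2 = make_conv(cfg$hidden_units, K, 1L))
  fwd <- function(tape, x, training = FALSE) {
    h <- act_node(tape, layers$act, conv_node(tape, layers$dense1, x))
    list(logits = conv_node(tape, layers$dense2, h), feat = NULL)
  }
  structure(list(members = members, cfg = cfg, layers = layers,
                 params = param_list(layers), merged_width = merged_width,
                 num_classes = K, fwd = fwd),
            class = "spineseg_stacking")
}

#' Forward pass of a stacking ensemble
#'
#' Runs every member (frozen, evaluation mode), merges their tensors per the
#' head configuration and applies the trained head.
#'
#' @param head A [build_stacking_head()] result.
#' @param x Input array `(H, W, C)` or `(H, W, C, N)`.
#' @return Normalized score array with `K` channels.
#' @export
stacking_forward <- function(head, x) {
  rank3 <- length(dim(x)) == 3L
  tensors <- lapply(head$members, function(m) {
    t <- member_tensor(m, x, head$cfg$input_kind)
    dim(t) <- dims4(t)
    t
  })
  merged <- merge_tensors(tensors, head$cfg$merge)
  tape <- ag_tape(grad_on = FALSE)
  out <- head$fwd(tape, ag_leaf(tape, merged))
  sc <- softmax_channels(out$logits$value)
  if (rank3) sc <- sc[, , , 1, drop = TRUE]
  sc
}

#' Train a stacking head on patch data
#'
#' Only the two dense layers of the head are trainable; member weights stay
#' frozen (they are not in the optimizer and no gradient reaches them). The
#' best epoch is selected by validation pixel accuracy, mirroring the
#' single-network checkpoint rule.
#'
#' @param head A [build_stacking_head()] result (modified in place).
#' @param train,val Patch datasets from [prepare_patch_dataset()].
#' @param seed RNG seed for shuffling.
#' @param batch_size Mini-batch size.
#' @param augment Optional [augment_config()]: apply the same geometric
#'   jitter protocol used for member training (the frozen members are then
#'   re-run on every augmented batch, which is slower than the default
#'   precomputed path).
#' @param verbose Print one line per epoch.
#' @return `list(head, log, best_epoch)`.
#' @export
train_stacking <- function(head, train, val, seed = 1L, batch_size = 8L,
                           augment = NULL, verbose = FALSE) {
  cfg <- head$cfg
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate)
  N <- dim(train$x)[4]
  # without augmentation the member tensors never change: precompute once
  merged_tr <- if (is.null(augment)) {
    merge_tensors(lapply(head$members, function(m) {
      t <- member_tensor(m, train$x, cfg$input_kind); dim(t) <- dims4(t); t
    }), cfg$merge)
  }
  merged_val <- merge_tensors(lapply(head$members, function(m) {
    t <- member_tensor(m, val$x, cfg$input_kind); dim(t) <- dims4(t); t
  }), cfg$merge)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_accuracy = numeric(0))
  best <- list(acc = -Inf, state = NULL, epoch = NA_integer_)
  head_state <- function() lapply(head$params, function(p) p$value)
  with_seed(seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1L, N, by = batch_size)) {
        idx <- ord[start:min(N, start + batch_size - 1L)]
        if (is.null(augment)) {
          xb <- merged_tr[, , , idx, drop = FALSE]
          yb <- train$y[, , , idx, drop = FALSE]
        } else {
          K <- dim(train$y)[3]
          raw <- train$x[, , , idx, drop = FALSE]
          yb <- train$y[, , , idx, drop = FALSE]
          for (j in seq_along(idx)) {
            aug <- augment_sample(train$x[, , , idx[j]],
                                  train$labels[, , idx[j]], augment)
            raw[, , , j] <- aug$image
            yb[, , , j] <- encode_onehot(aug$labels, K)
          }
          xb <- merge_tensors(lapply(head$members, function(m) {
            t <- member_tensor(m, raw, cfg$input_kind)
            dim(t) <- dims4(t)
            t
          }), cfg$merge)
        }
        tape <- ag_tape()
        out <- head$fwd(tape, ag_leaf(tape, xb))
        loss <- op_softmax_ce(tape, out$logits, yb)
        if (!is.finite(loss$value)) {
          stop(sprintf("stacking training diverged at epoch %d", epoch),
               call. = FALSE)
        }
        ag_backward(tape, loss)
        opt$step(head$params)
        for (p in head$params) p$grad <- NULL
        losses <- c(losses, loss$value)
      }
      # validation accuracy of the head on precomputed merged tensors
      tape <- ag_tape(grad_on = FALSE)
      sc <- softmax_channels(
        head$fwd(tape, ag_leaf(tape, merged_val))$logits$value)
      d <- dims4(sc)
      lab <- max.col(matrix(aperm(sc, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]),
                     ties.method = "first") - 1L
      acc <- mean(lab == as.vector(val$labels))
      log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_accuracy = acc))
      if (acc > best$acc) best <- list(acc = acc, state = head_state(),
                                       epoch = epoch)
      if (verbose) {
        message(sprintf("stacking epoch %3d  loss %.4f  val acc %.4f",
                        epoch, mean(losses), acc))
      }
    }
  })
  for (i in seq_along(head$params)) head$params[[i]]$value <- best$state[[i]]
  list(head = head, log = log, best_epoch = best$epoch)
}

#' Leave-one-out ensemble ablation
#'
#' Rebuilds the averaging ensemble without one member and reports the
#' per-class IoU of the ablated ensemble together with its signed difference
#' from the full ensemble (ablated minus full), over a list of evaluation
#' images. Removing one of several identical members changes nothing;
#' removing one member of a two-member arithmetic ensemble leaves the other
#' member's scores.
#'
#' @param scores_by_member Named list (by member id); each element a list of
#'   `(H, W, K)` score arrays over the same evaluation images.
#' @param truths List of matching ground-truth [label_mask()]s.
#' @param held_out Member id to remove.
#' @param mode `"arith"` or `"geo"`.
#' @param label_fn Pixel labeling criterion applied to combined scores
#'   (default [map_label()]; pass e.g. `function(s) th_label(s, th)`).
#' @return List with `full` and `ablated` [seg_metrics()] and `delta`
#'   (per-class ablated IoU minus full IoU).
#' @export
ablate_ensemble <- function(scores_by_member, truths, held_out,
                            mode = "arith", label_fn = map_label) {
  ids <- names(scores_by_member)
  if (!held_out %in% ids) {
    stop(sprintf("member '%s' is not in the ensemble", held_out),
         call. = FALSE)
  }
  if (length(ids) < 2L) stop("cannot ablate a single-member ensemble",
                             call. = FALSE)
  eval_combo <- function(members) {
    K <- dim(scores_by_member[[1]][[1]])[3]
    agg <- NULL
    for (i in seq_along(truths)) {
      comb <- average_ensemble(lapply(members,
                                      function(mid) scores_by_member[[mid]][[i]]),
                               mode)
      cnt <- confusion_counts(label_fn(comb), truths[[i]], K)
      if (is.null(agg)) {
        agg <- cnt
      } else {
        for (f in c("tp", "fp", "fn", "tc", "mc")) agg[[f]] <- agg[[f]] + cnt[[f]]
      }
    }
    seg_metrics(agg)
  }
  full <- eval_combo(ids)
  ablated <- eval_combo(setdiff(ids, held_out))
  list(full = full, ablated = ablated,
       delta = ablated$per_class$iou - full$per_class$iou)
}
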