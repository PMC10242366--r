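# Patient-level three-fold splitting, on-the-fly geometric augmentation,
# categorical cross-entropy training with best-validation-epoch checkpoint
# selection, and the optimizers used by the topology registry.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not
#' perturb the surrounding random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Patient-level three-fold cross-validation splits
#'
#' Holds out a fixed test set of 20% of patients (floor), shared by all
#' folds; the remaining 80% are dealt round-robin into three validation
#' thirds, and each fold trains on the other two thirds (approximately 53% /
#' 27% / 20% of patients for train / validation / test). All subsets are
#' patient-disjoint, so no slice of one patient can leak across subsets.
#'
#' @param patients Character vector of at least 5 patient ids.
#' @param seed Integer seed controlling the shuffle.
#' @return List of 3 folds, each
#'   `list(fold_id, train_patients, val_patients, test_patients)`.
#' @export
make_patient_splits <- function(patients, seed = 1L) {
  patients <- as.character(patients)
  n <- length(patients)
  if (n < 5L) stop("need at least 5 patients to split", call. = FALSE)
  if (anyDuplicated(patients)) stop("duplicated patient ids", call. = FALSE)
  shuffled <- with_seed(seed, sample(patients))
  n_test <- max(1L, floor(0.2 * n))
  test <- shuffled[seq_len(n_test)]
  rest <- shuffled[-seq_len(n_test)]
  groups <- split(rest, rep_len(1:3, length(rest)))
  lapply(1:3, function(k) {
    list(fold_id = k,
         train_patients = sort(unlist(groups[-k], use.names = FALSE)),
         val_patients = sort(groups[[k]]),
         test_patients = sort(test))
  })
}

#' Augmentation configuration
#'
#' The training-time geometric jitter: rotation up to +/-20 degrees, zoom by
#' a factor in `[0.5, 1.5]`, shifts up to 10% of each extent, and a
#' horizontal flip with probability 1/2.
#'
#' @param max_rotation_deg,zoom_range,max_shift_frac,hflip_prob Override the
#'   defaults above.
#' @export
augment_config <- function(max_rotation_deg = 20, zoom_range = c(0.5, 1.5),
                           max_shift_frac = 0.10, hflip_prob = 0.5) {
  structure(list(max_rotation_deg = max_rotation_deg, zoom_range = zoom_range,
                 max_shift_frac = max_shift_frac, hflip_prob = hflip_prob),
            class = "augment_config")
}

# Inverse-mapped affine warp; bilinear for image channels, nearest for the
# label mask so one-hot structure survives. Out-of-domain pixels fill with 0
# (the z-scored background mean) / background label.
affine_warp <- function(image, labels, rot_deg, zoom, shift_r, shift_c, flip) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  cr <- (H + 1) / 2; ccn <- (W + 1) / 2
  out_r <- matrix(seq_len(H), H, W)
  out_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (flip) out_c <- W + 1 - out_c
  th <- rot_deg * pi / 180
  dr <- out_r - cr - shift_r
  dc <- out_c - ccn - shift_c
  sr <- cr + (cos(th) * dr + sin(th) * dc) / zoom
  sc <- ccn + (-sin(th) * dr + cos(th) * dc) / zoom
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  img_out <- array(0, d)
  gather <- function(ch, ri, ci) {
    v <- numeric(length(ri))
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v[ok] <- ch[cbind(ri[ok], ci[ok])]
    v
  }
  for (k in seq_len(d[3])) {
    ch <- image[, , k]
    v <- gather(ch, r0, c0) * (1 - fr) * (1 - fc) +
      gather(ch, r0 + 1, c0) * fr * (1 - fc) +
      gather(ch, r0, c0 + 1) * (1 - fr) * fc +
      gather(ch, r0 + 1, c0 + 1) * fr * fc
    img_out[, , k] <- v
  }
  rn <- round(sr); cn <- round(sc)
  lab_out <- matrix(0L, H, W)
  ok <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
  lab_out[ok] <- labels[cbind(rn[ok], cn[ok])]
  list(image = img_out, labels = lab_out)
}

#' Randomly augment one image/mask pair
#'
#' Applies one identical geometric transform (rotation, zoom, shift,
#' horizontal flip, in that order) to the image tensor and its label mask,
#' drawing parameters from the current RNG state. The image is bilinearly
#' interpolated, the mask nearest-neighbour resampled, so the re-encoded
#' mask stays exactly one-hot.
#'
#' @param image Numeric array `(H, W, C)`.
#' @param mask A [label_mask()] or integer matrix with matching extents.
#' @param cfg An [augment_config()].
#' @return `list(image, labels)` (labels as integer matrix).
#' @export
augment_sample <- function(image, mask, cfg = augment_config()) {
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  if (!all(dim(image)[1:2] == dim(labels))) {
    stop("image and mask extents differ", call. = FALSE)
  }
  rot <- stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg)
  zoom <- stats::runif(1, cfg$zoom_range[1], cfg$zoom_range[2])
  shift_r <- stats::runif(1, -cfg$max_shift_frac, cfg$max_shift_frac) * dim(image)[1]
  shift_c <- stats::runif(1, -cfg$max_shift_frac, cfg$max_shift_frac) * dim(image)[2]
  flip <- stats::runif(1) < cfg$hflip_prob
  affine_warp(image, labels, rot, zoom, shift_r, shift_c, flip)
}

#' Training configuration
#'
#' @param epochs Training epochs (clinical protocol: 300).
#' @param batch_size Mini-batch size (default 8).
#' @param seed Seed for shuffling, augmentation draws and weight updates.
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @export
train_config <- function(epochs = 300L, batch_size = 8L, seed = 1L,
                         augment = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

make_optimizer <- function(name, lr) {
  name <- match.arg(tolower(name), c("adam", "rmsprop", "adadelta", "sgd"))
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  eps <- 1e-7
  step <- switch(
    name,
    adam = function(params) {
      env$t <- env$t + 1L
      b1 <- 0.9; b2 <- 0.999
      corr <- sqrt(1 - b2^env$t) / (1 - b1^env$t)
      for (p in params) {
        if (is.null(p$grad)) next
        if (is.null(p$.m)) { p$.m <- 0 * p$value; p$.v <- 0 * p$value }
        p$.m <- b1 * p$.m + (1 - b1) * p$grad
        p$.v <- b2 * p$.v + (1 - b2) * p$grad^2
        p$value <- p$value - lr * corr * p$.m / (sqrt(p$.v) + eps)
      }
    },
    rmsprop = function(params) {
      rho <- 0.9
      for (p in params) {
        if (is.null(p$grad)) next
        if (is.null(p$.v)) p$.v <- 0 * p$value
        p$.v <- rho * p$.v + (1 - rho) * p$grad^2
        p$value <- p$value - lr * p$grad / (sqrt(p$.v) + eps)
      }
    },
    adadelta = function(params) {
      rho <- 0.95
      for (p in params) {
        if (is.null(p$grad)) next
        if (is.null(p$.v)) { p$.v <- 0 * p$value; p$.u <- 0 * p$value }
        p$.v <- rho * p$.v + (1 - rho) * p$grad^2
        upd <- -sqrt(p$.u + eps) / sqrt(p$.v + eps) * p$grad
        p$.u <- rho * p$.u + (1 - rho) * upd^2
        p$value <- p$value + lr * upd
      }
    },
    sgd = function(params) {
      for (p in params) {
        if (is.null(p$grad)) next
        p$value <- p$value - lr * p$grad
      }
    }
  )
  list(name = name, lr = lr, step = step, env = env)
}

#' Assemble a fixed-size patch dataset from slices
#'
#' Z-score normalizes each slice, extracts its overlapping patch grid and
#' stacks image and one-hot mask patches into dense batch arrays.
#'
#' @param slices List of `list(image = slice_pair, mask = label_mask)`.
#' @param patch_size,stride Patch geometry (desk default 64/48).
#' @param num_classes `K`.
#' @return List with `x (D,D,C,N)`, `y (D,D,K,N)` one-hot targets,
#'   `labels (D,D,N)` and per-patch `slice` / `patient` vectors.
#' @export
prepare_patch_dataset <- function(slices, patch_size = 64L, stride = 48L,
                                  num_classes = 12L) {
  xs <- list(); ys <- list(); pats <- character(0); sl <- integer(0)
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    norm <- zscore_normalize(s$image)
    grid <- compute_patch_grid(dim(norm$pixels)[1], dim(norm$pixels)[2],
                               patch_size, stride)
    px <- extract_patches(norm$pixels, grid)
    mk <- extract_patches(encode_onehot(label_mask(s$mask$labels, num_classes)),
                          grid)
    for (k in seq_along(px$patches)) {
      xs[[length(xs) + 1L]] <- px$patches[[k]]
      ys[[length(ys) + 1L]] <- mk$patches[[k]]
      pats <- c(pats, s$image$patient_id)
      sl <- c(sl, i)
    }
  }
  D <- patch_size
  N <- length(xs)
  C <- dim(xs[[1]])[3]
  x <- array(0, c(D, D, C, N))
  y <- array(0, c(D, D, num_classes, N))
  labels <- array(0L, c(D, D, N))
  for (k in seq_len(N)) {
    x[, , , k] <- xs[[k]]
    y[, , , k] <- ys[[k]]
    labels[, , k] <- decode_onehot(ys[[k]])$labels
  }
  list(x = x, y = y, labels = labels, patient = pats, slice = sl)
}

dataset_subset <- function(data, idx) {
  list(x = data$x[, , , idx, drop = FALSE], y = data$y[, , , idx, drop = FALSE],
       labels = data$labels[, , idx, drop = FALSE],
       patient = data$patient[idx], slice = data$slice[idx])
}

# Mean per-pixel categorical accuracy of a model over a patch dataset.
pixel_accuracy <- function(model, data, batch_size = 8L) {
  N <- dim(data$x)[4]
  correct <- 0; total <- 0
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(N, start + batch_size - 1L)
    sc <- model_forward(model, data$x[, , , idx, drop = FALSE])
    d <- dims4(sc)
    hw <- d[1] * d[2]
    lab <- max.col(matrix(aperm(sc, c(1, 2, 4, 3)), hw * d[4], d[3]),
                   ties.method = "first") - 1L
    truth <- as.vector(data$labels[, , idx])
    # aperm moved batch before channel, so flatten labels the same way
    correct <- correct + sum(lab == truth)
    total <- total + length(truth)
  }
  correct / total
}

#' Train a model with best-epoch checkpoint selection
#'
#' Minimizes per-pixel categorical cross-entropy with the optimizer and
#' learning rate attached to the model's topology specification. After every
#' epoch the per-pixel categorical accuracy on the validation patches is
#' logged, and on return the model carries the weights of the epoch with the
#' highest validation accuracy (not the last). Training diverging to a
#' non-finite loss raises an error naming the epoch.
#'
#' @param model A `spineseg_model` (modified in place).
#' @param train,val Patch datasets from [prepare_patch_dataset()].
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return `list(model, log, best_epoch)`; `log` is a data.frame with one
#'   row per epoch (`epoch`, `train_loss`, `val_accuracy`).
#' @export
train_model <- function(model, train, val, cfg = train_config(),
                        verbose = FALSE) {
  opt <- make_optimizer(model$spec$optimizer, model$spec$learning_rate)
  N <- dim(train$x)[4]
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_accuracy = numeric(0))
  best <- list(acc = -Inf, state = NULL, epoch = NA_integer_)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[start:min(N, start + cfg$batch_size - 1L)]
        xb <- train$x[, , , idx, drop = FALSE]
        yb <- train$y[, , , idx, drop = FALSE]
        if (!is.null(cfg$augment)) {
          K <- dim(yb)[3]
          for (j in seq_along(idx)) {
            aug <- augment_sample(train$x[, , , idx[j]],
                                  train$labels[, , idx[j]], cfg$augment)
            xb[, , , j] <- aug$image
            yb[, , , j] <- encode_onehot(aug$labels, K)
          }
        }
        tape <- ag_tape()
        out <- model$fwd(tape, ag_leaf(tape, xb), training = TRUE)
        loss <- op_softmax_ce(tape, out$logits, yb)
        if (!is.finite(loss$value)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        }
        ag_backward(tape, loss)
        opt$step(model$params)
        for (p in model$params) p$grad <- NULL
        losses <- c(losses, loss$value)
      }
      acc <- pixel_accuracy(model, val, cfg$batch_size)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_accuracy = acc))
      if (acc > best$acc) {
        best <- list(acc = acc, state = model_state(model), epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val acc %.4f", epoch,
                        mean(losses), acc))
      }
    }
  })
  restore_model_state(model, best$state)
  list(model = model, log = log, best_epoch = best$epoch)
}
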