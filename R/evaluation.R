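# Pixel labeling criteria (MAP argmax and threshold-optimized cascade),
# per-class threshold tuning on validation data, confusion-count metrics
# (IoU, precision, recall, F1) and Wilcoxon signed-rank model comparison.

scores_matrix <- function(scores) {
  d <- dim(scores)
  if (length(d) != 3L) stop("expected an (H, W, K) score array", call. = FALSE)
  list(m = matrix(scores, d[1] * d[2], d[3]), d = d)
}

#' Maximum a-posteriori pixel labeling
#'
#' Assigns every pixel to the class with the highest softmax score; ties
#' break toward the lowest class index.
#'
#' @param scores Normalized score array `(H, W, K)`.
#' @return A [label_mask()].
#' @export
map_label <- function(scores) {
  s <- scores_matrix(scores)
  lab <- max.col(s$m, ties.method = "first") - 1L
  dim(lab) <- s$d[1:2]
  label_mask(lab, s$d[3])
}

#' Threshold vector for cascade labeling
#'
#' @param thresholds Numeric vector of length `K` in `[0, 1]`; entry 1 is
#'   the background class and is forced to 0 (background is never
#'   thresholded).
#' @return A `threshold_vector`.
#' @export
threshold_vector <- function(thresholds) {
  thresholds <- as.numeric(thresholds)
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  thresholds[1] <- 0
  structure(list(thresholds = thresholds, num_classes = length(thresholds)),
            class = "threshold_vector")
}

#' The 19-value tuning grid (0.05 to 0.95 by 0.05)
#' @export
threshold_grid <- function() seq(0.05, 0.95, by = 0.05)

#' Threshold-optimized (TH) pixel labeling
#'
#' Classes are visited in descending score order per pixel; a class is
#' accepted as soon as its score is greater than or equal to its threshold.
#' Background carries threshold 0, so it is always accepted when reached;
#' if every class is rejected the pixel falls back to background.
#' With all thresholds zero this reduces exactly to [map_label()].
#'
#' @param scores Normalized score array `(H, W, K)`.
#' @param th A [threshold_vector()] (or plain numeric vector of length `K`).
#' @return A [label_mask()].
#' @export
th_label <- function(scores, th) {
  if (!inherits(th, "threshold_vector")) th <- threshold_vector(th)
  s <- scores_matrix(scores)
  K <- s$d[3]
  if (th$num_classes != K) {
    stop("threshold vector length does not match the number of classes",
         call. = FALSE)
  }
  m <- s$m
  npix <- nrow(m)
  assigned <- rep.int(0L, npix) # background fallback
  done <- logical(npix)
  work <- m
  for (rank in seq_len(K)) {
    if (all(done)) break
    cls <- max.col(work, ties.method = "first")
    sc <- work[cbind(seq_len(npix), cls)]
    accept <- !done & sc >= th$thresholds[cls]
    assigned[accept] <- cls[accept] - 1L
    done <- done | accept
    work[cbind(seq_len(npix), cls)] <- -Inf
  }
  dim(assigned) <- s$d[1:2]
  label_mask(assigned, K)
}

#' Tune per-class thresholds on validation data
#'
#' For each target class independently, sweeps the 19-value grid and keeps
#' the threshold maximizing the one-vs-rest IoU between the binarized score
#' map (`score >= t`) and the ground-truth class mask, pooling pixels over
#' all validation slices. Ties return the lowest grid value; classes absent
#' from the validation ground truth get 0.05 with a warning. The background
#' threshold is fixed at 0.
#'
#' @param val_scores List of `(H, W, K)` score arrays (or a single array).
#' @param val_masks List of matching [label_mask()]s / integer matrices.
#' @return A [threshold_vector()].
#' @export
tune_thresholds <- function(val_scores, val_masks) {
  if (!is.list(val_scores)) val_scores <- list(val_scores)
  if (!is.list(val_masks) || inherits(val_masks, "label_mask")) {
    val_masks <- list(val_masks)
  }
  if (length(val_scores) == 0L) stop("empty validation set", call. = FALSE)
  if (length(val_scores) != length(val_masks)) {
    stop("scores/masks length mismatch", call. = FALSE)
  }
  K <- dim(val_scores[[1]])[3]
  sc <- do.call(rbind, lapply(val_scores, function(s) scores_matrix(s)$m))
  labs <- unlist(lapply(val_masks, function(mk) {
    as.vector(if (inherits(mk, "label_mask")) mk$labels else mk)
  }))
  if (length(labs) != nrow(sc)) {
    stop("validation masks do not match score dimensions", call. = FALSE)
  }
  grid <- threshold_grid()
  th <- numeric(K)
  for (c in seq_len(K)[-1]) {
    truth <- labs == (c - 1L)
    if (!any(truth)) {
      warning(sprintf("class %d absent from validation ground truth; threshold defaults to 0.05",
                      c - 1L))
      th[c] <- grid[1]
      next
    }
    s_c <- sc[, c]
    ious <- vapply(grid, function(t) {
      pred <- s_c >= t
      inter <- sum(pred & truth)
      union <- sum(pred | truth)
      if (union == 0L) 1 else inter / union
    }, numeric(1))
    th[c] <- grid[which.max(ious)] # which.max takes the first (lowest) tie
  }
  threshold_vector(th)
}

#' Per-class confusion counts between predicted and true label masks
#'
#' @param pred,truth [label_mask()]s or integer matrices of equal shape.
#' @param num_classes `K`; inferred from `label_mask` inputs when omitted.
#' @return A `confusion_counts` object with per-class vectors `tp`, `fp`,
#'   `fn`, plus `tc` (ground-truth pixels) and `mc` (predicted pixels).
#' @export
confusion_counts <- function(pred, truth, num_classes = NULL) {
  get <- function(x) if (inherits(x, "label_mask")) x$labels else x
  p <- get(pred); t <- get(truth)
  if (!all(dim(p) == dim(t))) {
    stop("prediction and ground truth differ in shape", call. = FALSE)
  }
  K <- if (!is.null(num_classes)) as.integer(num_classes)
       else if (inherits(pred, "label_mask")) pred$num_classes
       else max(p, t) + 1L
  joint <- tabulate(as.vector(t) * K + as.vector(p) + 1L, nbins = K * K)
  jm <- matrix(joint, K, K, byrow = TRUE) # rows = truth, cols = predicted
  tp <- diag(jm)
  tc <- rowSums(jm)
  mc <- colSums(jm)
  structure(list(tp = tp, fp = mc - tp, fn = tc - tp, tc = tc, mc = mc,
                 num_classes = K),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Computes per-class IoU `TP / (TP + FP + FN)`, precision, recall and
#' F1 `2 TP / (2 TP + FP + FN)`, plus mean IoU with and without the
#' background class. A class absent from both masks (`tc = mc = 0`) is a
#' vacuous 0/0 case: its metrics are set to 1 and it is excluded from the
#' means; the background-free mean averages only the target classes.
#'
#' @param counts A [confusion_counts()] result.
#' @return A `seg_metrics` object: `$per_class` data.frame (rows = classes
#'   0..K-1) and scalars `$mean_iou` (without background) and
#'   `$mean_iou_with_bg`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  present <- (counts$tc + counts$mc) > 0
  safe <- function(num, den) ifelse(den > 0, num / den, 1)
  iou <- safe(tp, tp + fp + fn)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * tp, 2 * tp + fp + fn)
  K <- counts$num_classes
  per_class <- data.frame(class = 0:(K - 1L), iou = iou,
                          precision = precision, recall = recall, f1 = f1,
                          present = present)
  target <- present & per_class$class != 0L
  structure(list(per_class = per_class,
                 mean_iou = if (any(target)) mean(iou[target]) else NA_real_,
                 mean_iou_with_bg = if (any(present)) mean(iou[present])
                                    else NA_real_),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, digits = 3, ...) {
  cat("<seg_metrics>\n")
  print(format(x$per_class, digits = digits), ...)
  cat(sprintf("mean IoU without background: %.4f\nmean IoU with background: %.4f\n",
              x$mean_iou, x$mean_iou_with_bg))
  invisible(x)
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience wrapper: [confusion_counts()] then [seg_metrics()].
#' @inheritParams confusion_counts
#' @export
evaluate_masks <- function(pred, truth, num_classes = NULL) {
  seg_metrics(confusion_counts(pred, truth, num_classes))
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Two-sided signed-rank test on paired per-image IoU values (one pair per
#' test image). All-tied inputs (every difference zero) are degenerate and
#' report p = 1.
#'
#' @param iou_a,iou_b Paired numeric vectors over the same images.
#' @param alpha Significance level for the reported flag (default 0.05).
#' @return List with `p_value`, `significant`, `n`.
#' @export
wilcoxon_compare <- function(iou_a, iou_b, alpha = 0.05) {
  if (length(iou_a) != length(iou_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- iou_a - iou_b
  if (all(d == 0)) {
    return(list(p_value = 1, significant = FALSE, n = length(d)))
  }
  p <- suppressWarnings(
    stats::wilcox.test(iou_a, iou_b, paired = TRUE, exact = FALSE)$p.value
  )
  list(p_value = p, significant = p < alpha, n = length(d))
}
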