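# Data model: two-channel slice pairs, integer label masks and one-hot
# masks. Channel order is fixed: channel 1 (index 0 in the data layout
# convention) is T2w, channel 2 is T1w. Class 0 is background. Masks are
# persisted as single-channel integer NIfTI volumes; one-hot tensors are
# built in memory only.

#' Construct a two-channel slice pair
#'
#' @param pixels Numeric array `(H, W, 2)`; channel 1 is T2w, channel 2 T1w.
#' @param patient_id Patient identifier string.
#' @param slice_index Zero-based slice index within the acquisition.
#' @param pixel_spacing Optional in-plane spacing in mm, length 2.
#' @return A `slice_pair` object.
#' @export
slice_pair <- function(pixels, patient_id = "unknown", slice_index = 0L,
                       pixel_spacing = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 2L) {
    stop("pixels must be an (H, W, 2) array", call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("empty image", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixels contain missing or non-finite values", call. = FALSE)
  }
  structure(list(pixels = pixels, patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index),
                 pixel_spacing = pixel_spacing),
            class = "slice_pair")
}

#' @export
print.slice_pair <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slice_pair> %dx%d, patient %s, slice %d (ch1 = T2w, ch2 = T1w)\n",
              d[1], d[2], x$patient_id, x$slice_index))
  invisible(x)
}

#' Construct an integer label mask
#'
#' @param labels Integer matrix `(H, W)` with values in `[0, num_classes)`;
#'   0 is background.
#' @param num_classes Number of classes `K` (12 in the lumbar-spine task).
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, num_classes = 12L) {
  num_classes <- as.integer(num_classes)
  if (length(dim(labels)) != 2L) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L) || any(labels >= num_classes)) {
    stop(sprintf("labels must lie in [0, %d]", num_classes - 1L),
         call. = FALSE)
  }
  structure(list(labels = labels, num_classes = num_classes),
            class = "label_mask")
}

#' One-hot encode a label mask
#'
#' Expands `(H, W)` integer labels into the `(H, W, K)` binary tensor used
#' as network target, with exactly one 1 per pixel.
#'
#' @param mask A [label_mask()], or an integer matrix.
#' @param num_classes `K`; taken from the mask when it is a `label_mask`.
#' @return A binary array `(H, W, K)` of class `onehot_mask`.
#' @export
encode_onehot <- function(mask, num_classes = NULL) {
  if (inherits(mask, "label_mask")) {
    labels <- mask$labels
    K <- mask$num_classes
  } else {
    labels <- mask
    storage.mode(labels) <- "integer"
    K <- if (is.null(num_classes)) max(labels) + 1L else as.integer(num_classes)
  }
  if (any(labels < 0L) || any(labels >= K)) {
    stop("label out of range for one-hot encoding", call. = FALSE)
  }
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], K))
  hw <- d[1] * d[2]
  out[seq_len(hw) + hw * as.vector(labels)] <- 1
  structure(out, class = c("onehot_mask", class(out)))
}

#' Decode a one-hot mask back to integer labels
#'
#' Inverse of [encode_onehot()]: takes the per-pixel argmax after verifying
#' the exactly-one-hot invariant.
#'
#' @param mask Binary array `(H, W, K)`.
#' @return A [label_mask()].
#' @export
decode_onehot <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("one-hot mask must be (H, W, K)", call. = FALSE)
  hw <- d[1] * d[2]
  sums <- .rowSums(matrix(mask, hw, d[3]), hw, d[3])
  if (any(sums != 1)) {
    stop("mask is not exactly one-hot: some pixel channel sums differ from 1",
         call. = FALSE)
  }
  lab <- max.col(matrix(mask, hw, d[3]), ties.method = "first") - 1L
  dim(lab) <- d[1:2]
  label_mask(lab, d[3])
}

#' Read an aligned T2w/T1w slice pair from two NIfTI volumes
#'
#' Loads one sagittal slice from each sequence and stacks them in the fixed
#' channel order (T2w first, T1w second). Both volumes must already be
#' pixel-aligned and share their in-plane shape.
#'
#' @param t2_path,t1_path Paths to the T2w and T1w NIfTI volumes.
#' @param slice_index Zero-based slice index (third array dimension).
#' @param patient_id Optional patient id recorded on the result.
#' @return A [slice_pair()].
#' @export
read_slice_pair <- function(t2_path, t1_path, slice_index = 0L,
                            patient_id = "unknown") {
  t2 <- read_nifti(t2_path)
  t1 <- read_nifti(t1_path)
  pick <- function(x, path) {
    d <- dim(x)
    if (length(d) == 2L) {
      if (slice_index != 0L) {
        stop(sprintf("slice %d out of range in %s", slice_index, path),
             call. = FALSE)
      }
      return(x)
    }
    if (slice_index < 0L || slice_index >= d[3]) {
      stop(sprintf("slice %d out of range in %s (volume has %d slices)",
                   slice_index, path, d[3]), call. = FALSE)
    }
    x[, , slice_index + 1L]
  }
  a2 <- pick(t2, t2_path)
  a1 <- pick(t1, t1_path)
  if (!all(dim(a2) == dim(a1))) {
    stop(sprintf("T2w/T1w shape mismatch: %s vs %s",
                 paste(dim(a2), collapse = "x"),
                 paste(dim(a1), collapse = "x")), call. = FALSE)
  }
  px <- attr(t2, "pixdim")
  slice_pair(array(c(a2, a1), c(dim(a2), 2L)), patient_id = patient_id,
             slice_index = slice_index,
             pixel_spacing = if (!is.null(px) && length(px) >= 2) px[1:2])
}

#' Read a label-mask slice from a NIfTI volume
#'
#' @param path Path to an integer-valued NIfTI volume.
#' @param slice_index Zero-based slice index.
#' @param num_classes `K` used to validate the labels.
#' @return A [label_mask()].
#' @export
read_mask_slice <- function(path, slice_index = 0L, num_classes = 12L) {
  x <- read_nifti(path)
  d <- dim(x)
  sl <- if (length(d) == 2L) x else x[, , slice_index + 1L]
  label_mask(round(sl), num_classes)
}
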