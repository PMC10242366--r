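# Per-channel z-score normalization, overlapping patch extraction and
# score-map reconstruction by overlap averaging.
#
# Coordinates are 0-based (row, col); a patch window is half-open
# [r, r+D) x [c, c+D). Start positions advance by the stride S with a final
# clamped start at dim - D whenever S does not tile the image exactly, which
# realizes the "approximately S pixels" shifting rule, guarantees full
# coverage without padding, and for D = 256 / S = 192 reproduces the 1/2/4
# overlap structure on clinical image sizes.

#' Z-score normalize a slice pair per channel
#'
#' Centers and scales each channel independently to zero mean and unit
#' population standard deviation. A constant channel (zero variance) maps to
#' all zeros rather than producing non-finite values.
#'
#' @param image A [slice_pair()] or a numeric array `(H, W, C)`.
#' @return Same type as the input, normalized.
#' @export
zscore_normalize <- function(image) {
  arr <- if (inherits(image, "slice_pair")) image$pixels else image
  d <- dim(arr)
  if (length(d) != 3L) stop("expected an (H, W, C) array", call. = FALSE)
  if (d[1] * d[2] < 2L) stop("image too small to normalize", call. = FALSE)
  hw <- d[1] * d[2]
  m <- matrix(arr, hw, d[3])
  mu <- .colMeans(m, hw, d[3])
  sdev <- sqrt(pmax(.colMeans(m * m, hw, d[3]) - mu^2, 0))
  out <- (m - rep(mu, each = hw)) / rep(pmax(sdev, 1e-8), each = hw)
  out[, sdev < 1e-8] <- 0
  dim(out) <- d
  if (inherits(image, "slice_pair")) {
    image$pixels <- out
    image
  } else {
    out
  }
}

patch_starts <- function(extent, d, s) {
  starts <- seq.int(0L, by = s, length.out = max(1L, (extent - d) %/% s + 1L))
  if (starts[length(starts)] + d < extent) starts <- c(starts, extent - d)
  as.integer(starts)
}

#' Compute an overlapping patch grid
#'
#' Start positions are `0, S, 2S, ...` while a full `D`-wide window fits; if
#' the last window ends before the image border, one clamped start at
#' `dim - D` is appended so the union of windows covers the whole image.
#'
#' @param h,w Image extents in pixels.
#' @param d Patch size `D` (default 256).
#' @param s Stride `S` (default 192).
#' @return A `patch_grid` with 0-based `row_starts`/`col_starts`.
#' @export
compute_patch_grid <- function(h, w, d = 256L, s = 192L) {
  h <- as.integer(h); w <- as.integer(w); d <- as.integer(d); s <- as.integer(s)
  if (d > min(h, w)) {
    stop(sprintf("patch size %d exceeds image extent %dx%d", d, h, w),
         call. = FALSE)
  }
  if (s < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(image_h = h, image_w = w, patch_size = d, stride = s,
                 row_starts = patch_starts(h, d, s),
                 col_starts = patch_starts(w, d, s)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %dx%d image, D=%d S=%d, %d patches (rows {%s} x cols {%s})\n",
              x$image_h, x$image_w, x$patch_size, x$stride,
              length(x$row_starts) * length(x$col_starts),
              paste(x$row_starts, collapse = ","),
              paste(x$col_starts, collapse = ",")))
  invisible(x)
}

grid_origins <- function(grid) {
  expand.grid(row = grid$row_starts, col = grid$col_starts,
              KEEP.OUT.ATTRS = FALSE)
}

#' Extract overlapping patches from an image or mask tensor
#'
#' Copies each `D x D` window bit-exactly; applies identically to image
#' tensors and one-hot mask tensors.
#'
#' @param image Numeric array `(H, W, C)`.
#' @param grid A [compute_patch_grid()] result matching the image extents.
#' @return A `patch_set`: list with `patches` (list of `(D, D, C)` arrays),
#'   `origins` (0-based row/col data.frame) and `grid`.
#' @export
extract_patches <- function(image, grid) {
  d <- dim(image)
  if (length(d) != 3L) stop("expected an (H, W, C) array", call. = FALSE)
  if (d[1] != grid$image_h || d[2] != grid$image_w) {
    stop("grid does not match image dimensions", call. = FALSE)
  }
  D <- grid$patch_size
  org <- grid_origins(grid)
  patches <- vector("list", nrow(org))
  for (k in seq_len(nrow(org))) {
    r <- org$row[k]; cc <- org$col[k]
    patches[[k]] <- image[r + seq_len(D), cc + seq_len(D), , drop = FALSE]
  }
  structure(list(patches = patches, origins = org, grid = grid,
                 channels = d[3]),
            class = "patch_set")
}

#' Per-pixel patch coverage counts of a grid
#'
#' @param grid A [compute_patch_grid()] result.
#' @return Integer matrix `(H, W)` counting how many patch windows cover
#'   each pixel (1, 2 or 4 for the clinical D/S on square images).
#' @export
coverage_map <- function(grid) {
  cov <- matrix(0L, grid$image_h, grid$image_w)
  D <- grid$patch_size
  for (r in grid$row_starts) {
    for (cc in grid$col_starts) {
      idx_r <- r + seq_len(D)
      idx_c <- cc + seq_len(D)
      cov[idx_r, idx_c] <- cov[idx_r, idx_c] + 1L
    }
  }
  cov
}

#' Reconstruct a full-slice score map from patch score maps
#'
#' Places each patch at its origin and averages overlapping contributions
#' per pixel (arithmetic mean over the 1, 2 or 4 covering patches). When all
#' input patches are per-pixel normalized, the reconstruction is too.
#'
#' @param patch_scores A `patch_set` whose patches are `(D, D, K)` score
#'   arrays, or a plain list of such arrays ordered like `grid`'s origins.
#' @param grid The [compute_patch_grid()] the patches came from.
#' @return Numeric array `(H, W, K)`.
#' @export
reconstruct_scores <- function(patch_scores, grid) {
  patches <- if (inherits(patch_scores, "patch_set")) patch_scores$patches
             else patch_scores
  org <- grid_origins(grid)
  if (length(patches) != nrow(org)) {
    stop(sprintf("expected %d patches (one per grid origin), got %d",
                 nrow(org), length(patches)), call. = FALSE)
  }
  K <- dim(patches[[1]])[3]
  D <- grid$patch_size
  acc <- array(0, c(grid$image_h, grid$image_w, K))
  for (k in seq_along(patches)) {
    p <- patches[[k]]
    if (!all(dim(p) == c(D, D, K))) {
      stop("patch dimensions do not match the grid", call. = FALSE)
    }
    r <- org$row[k]; cc <- org$col[k]
    acc[r + seq_len(D), cc + seq_len(D), ] <-
      acc[r + seq_len(D), cc + seq_len(D), , drop = FALSE] + p
  }
  cov <- coverage_map(grid)
  acc / as.vector(cov) # cov recycles over the K score channels
}
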