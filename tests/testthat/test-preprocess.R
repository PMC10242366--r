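test_that("z-score normalization hits zero mean / unit population sd", {
  # hand oracle on {1,2,3,4}: mean 2.5, population sd sqrt(1.25)
  x <- array(0, c(2, 2, 2))
  x[, , 1] <- c(1, 2, 3, 4)
  x[, , 2] <- 5 # constant channel
  out <- zscore_normalize(x)
  expect_equal(as.vector(out[, , 1]), (c(1, 2, 3, 4) - 2.5) / sqrt(1.25),
               tolerance = 1e-12)
  expect_true(all(out[, , 2] == 0))
  expect_equal(mean(out[, , 1]), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(out[, , 1]^2)), 1, tolerance = 1e-6)
  # idempotence on an already-normalized channel
  again <- zscore_normalize(out)
  expect_equal(again[, , 1], out[, , 1], tolerance = 1e-6)
})

test_that("patch grids follow the clamped-final-start rule", {
  g <- compute_patch_grid(512, 512, 256, 192)
  expect_equal(g$row_starts, c(0L, 192L, 256L))
  expect_equal(g$col_starts, c(0L, 192L, 256L))
  expect_equal(length(g$row_starts) * length(g$col_starts), 9L)

  g1 <- compute_patch_grid(256, 256, 256, 192)
  expect_equal(g1$row_starts, 0L)

  g2 <- compute_patch_grid(320, 320, 256, 192)
  expect_equal(g2$row_starts, c(0L, 64L)) # 192 + 256 > 320 => clamp to 64
  expect_equal(length(g2$row_starts) * length(g2$col_starts), 4L)

  expect_error(compute_patch_grid(100, 100, 256, 192), "exceeds")
})

test_that("coverage is complete with counts in {1,2,4} for clinical D/S", {
  for (hw in list(c(256, 256), c(320, 320), c(512, 512), c(320, 512),
                  c(448, 640))) {
    g <- compute_patch_grid(hw[1], hw[2], 256, 192)
    cov <- coverage_map(g)
    expect_true(all(cov >= 1L))
    expect_true(all(cov %in% c(1L, 2L, 4L)))
  }
  # full coverage also holds at desk scale for random extents in [d, 4d]
  for (rep in 1:8) {
    hw <- with_seed(rep, sample(64:256, 2))
    g <- compute_patch_grid(hw[1], hw[2], 64, 48)
    expect_true(all(coverage_map(g) >= 1L))
  }
})

test_that("patch extraction copies windows bit-exactly", {
  img <- with_seed(6, array(rnorm(512 * 512 * 2), c(512, 512, 2)))
  g <- compute_patch_grid(512, 512, 256, 192)
  ps <- extract_patches(img, g)
  expect_length(ps$patches, 9L)
  expect_identical(dim(ps$patches[[1]]), c(256L, 256L, 2L))
  # window copy oracle for a non-trivial origin
  k <- which(ps$origins$row == 192 & ps$origins$col == 256)
  expect_identical(ps$patches[[k]],
                   img[193:448, 257:512, , drop = FALSE])
  expect_error(extract_patches(img[1:100, , , drop = FALSE], g), "match")
})

test_that("extract -> reconstruct is the identity on untouched patches", {
  for (sz in c(64L, 96L)) {
    img <- with_seed(sz, array(rnorm(sz * sz * 3), c(sz, sz, 3)))
    g <- compute_patch_grid(sz, sz, 48, 32)
    rec <- reconstruct_scores(extract_patches(img, g), g)
    expect_equal(rec, img, tolerance = 1e-12)
  }
})

test_that("overlap averaging matches a hand computation", {
  # two horizontally overlapping constant patches on a 1-row strip
  g <- structure(list(image_h = 4L, image_w = 6L, patch_size = 4L,
                      stride = 2L, row_starts = 0L, col_starts = c(0L, 2L)),
                 class = "patch_grid")
  p0 <- array(0, c(4, 4, 2)); p0[, , 1] <- 1
  p1 <- array(0, c(4, 4, 2)); p1[, , 2] <- 1
  rec <- reconstruct_scores(list(p0, p1), g)
  expect_true(all(rec[, 1:2, 1] == 1))          # only patch 0
  expect_true(all(rec[, 3:4, 1] == 0.5))        # overlap: mean of 1 and 0
  expect_true(all(rec[, 3:4, 2] == 0.5))
  expect_true(all(rec[, 5:6, 2] == 1))          # only patch 1
  # per-pixel channel sums stay normalized
  expect_equal(apply(rec, c(1, 2), sum), matrix(1, 4, 6), tolerance = 1e-12)

  # single patch grid is the identity
  g1 <- compute_patch_grid(4, 4, 4, 4)
  p <- with_seed(8, array(runif(4 * 4 * 3), c(4, 4, 3)))
  expect_equal(reconstruct_scores(list(p), g1), p)
  expect_error(reconstruct_scores(list(p), g), "expected 2 patches")
})

test_that("reconstructed score maps stay normalized for random patch scores", {
  g <- compute_patch_grid(96, 80, 48, 32)
  n <- length(g$row_starts) * length(g$col_starts)
  patches <- lapply(seq_len(n), function(i) random_scoremap(48, 48, 5,
                                                            seed = i))
  rec <- reconstruct_scores(patches, g)
  sums <- apply(rec, c(1, 2), sum)
  expect_true(max(abs(sums - 1)) < 1e-5)
})
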