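# Reference helpers: independent per-pixel implementations of the 1x1
# convolution and nearest x2 upsampling used to hand-wire DS graphs.
conv1x1_ref <- function(x, w, b = NULL) {
  d <- dim(x)
  cout <- dim(w)[4]
  out <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    acc <- matrix(if (is.null(b)) 0 else b[co], d[1], d[2])
    for (ci in seq_len(d[3])) acc <- acc + x[, , ci] * w[1, 1, ci, co]
    out[, , co] <- acc
  }
  out
}
up_ref <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3])) {
    out[, , c] <- kronecker(x[, , c], matrix(1, 2, 2))
  }
  out
}
set_conv <- function(conv, w, b = NULL) {
  conv$w$value <- w
  if (!is.null(b)) conv$b$value <- b
  invisible(NULL)
}

test_that("block parameter counts match closed-form oracles", {
  # U-Net block (cin=2, ch=8): two 3x3 convs + two BN (gamma, beta)
  expect_equal(n_params(conv_block("unet", 2, 8)),
               (2 * 3 * 3 * 8 + 8) + (8 * 3 * 3 * 8 + 8) + 2 * (2 * 8))
  expect_equal(n_params(conv_block("unet", 2, 8)), 768)

  # VGG block depth 2/3 with PReLU slopes (one per channel per activation)
  for (depth in 2:3) {
    cin <- 3; ch <- 6
    convs <- (3 * 3 * cin * ch + ch) +
      (depth - 1) * (3 * 3 * ch * ch + ch)
    expect_equal(n_params(conv_block("vgg", cin, ch, depth = depth,
                                     activation = "prelu")),
                 convs + depth * ch)
  }

  # dense block: 3 units of BN + conv(5/3/1), widths cin, cin+64, cin+128
  cin <- 2
  cins <- c(cin, cin + 64, cin + 128)
  ks <- c(5, 3, 1)
  expect_equal(n_params(conv_block("dense", cin)),
               sum(2 * cins + ks^2 * cins * 64 + 64))

  # multi-kernel input: 1/3/5/7 kernels, m/4 channels each
  m <- 16
  expect_equal(n_params(multi_kernel_input(2, m)),
               sum(c(1, 3, 5, 7)^2 * 2 * (m / 4) + m / 4))

  # attention gate: theta/phi to f = enc/2 channels, psi to 1
  f <- 4
  expect_equal(n_params(attention_gate(8, 6)),
               (8 * f + f) + (6 * f + f) + (f + 1))
})

test_that("conv blocks keep spatial extent and contract shapes", {
  for (sz in c(16L, 32L, 48L)) {
    x <- with_seed(sz, array(rnorm(sz * sz * 2), c(sz, sz, 2)))
    expect_identical(dim(module_forward(conv_block("unet", 2, 8), x,
                                        training = TRUE)),
                     c(sz, sz, 8L, 1L))
    expect_identical(dim(module_forward(conv_block("vgg", 2, 4, depth = 3,
                                                   activation = "prelu"), x)),
                     c(sz, sz, 4L, 1L))
    expect_identical(dim(module_forward(conv_block("dense", 2), x,
                                        training = TRUE)),
                     c(sz, sz, 64L, 1L))
  }
  out <- module_forward(conv_block("unet", 2, 8),
                        with_seed(1, array(rnorm(64 * 64 * 2),
                                           c(64, 64, 2))), training = TRUE)
  expect_true(all(is.finite(out)))
  expect_error(conv_block("unet", 2, 0), "channels")
  expect_error(conv_block("vgg", 2, 4, depth = 4), "depth")
})

test_that("dense block concatenation widths follow the dense connections", {
  blk <- conv_block("dense", 2)
  cins <- vapply(blk$layers$units, function(u) u$conv$cin, integer(1))
  expect_equal(cins, c(2L, 66L, 130L))
  ks <- vapply(blk$layers$units, function(u) u$conv$k, integer(1))
  expect_equal(ks, c(5L, 3L, 1L))
  # stacking two dense blocks keeps 64 channels
  x <- with_seed(2, array(rnorm(16 * 16 * 2), c(16, 16, 2)))
  h <- module_forward(blk, x, training = TRUE)
  h2 <- module_forward(conv_block("dense", 64), h, training = TRUE)
  expect_identical(dim(h2)[3], 64L)
})

test_that("multi-kernel input concatenates four scale paths", {
  mk <- multi_kernel_input(2, 64)
  x <- with_seed(3, array(rnorm(32 * 32 * 2), c(32, 32, 2)))
  expect_identical(dim(module_forward(mk, x)), c(32L, 32L, 64L, 1L))
  ks <- vapply(mk$layers$paths, function(p) p$conv$k, integer(1))
  expect_equal(ks, c(1L, 3L, 5L, 7L))
  # zero input with zero biases -> zero output on every path
  expect_true(all(module_forward(mk, array(0, c(16, 16, 2))) == 0))
  expect_error(multi_kernel_input(2, 10), "divisible by 4")
})

test_that("attention gate masks encoder features multiplicatively", {
  ag <- attention_gate(4, 4)
  enc <- with_seed(4, array(rnorm(16 * 16 * 4), c(16, 16, 4)))
  gate <- with_seed(5, array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  # force the sigmoid toward 1: zero psi weights, huge positive bias
  set_conv(ag$layers$psi, array(0, dim(ag$layers$psi$w$value)), b = 100)
  expect_equal(module_forward(ag, enc, gate)[, , , 1], enc, tolerance = 1e-12)
  # force the sigmoid toward 0 (bias low enough that exp underflows exactly)
  set_conv(ag$layers$psi, array(0, dim(ag$layers$psi$w$value)), b = -1000)
  expect_true(all(module_forward(ag, enc, gate) == 0))
  # random init: gating can only attenuate
  ag2 <- with_seed(6, attention_gate(4, 4))
  out <- module_forward(ag2, enc, gate)[, , , 1]
  expect_true(all(abs(out) <= abs(enc) + 1e-12))
})

test_that("DS.v1 signals match a hand-wired two-level reference graph", {
  chans <- c(3L, 5L)
  m <- 2L
  head <- with_seed(7, ds_head(1L, chans, m))
  C1 <- with_seed(8, array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  C2 <- with_seed(9, array(rnorm(4 * 4 * 5), c(4, 4, 5)))
  S <- module_forward(head, list(C1, C2))
  w <- lapply(head$layers$convs, function(cv) cv$w$value)
  b <- lapply(head$layers$convs, function(cv) cv$b$value)
  S2_ref <- conv1x1_ref(C2, w[[2]], b[[2]])
  S1_ref <- conv1x1_ref(C1, w[[1]], b[[1]]) + up_ref(S2_ref)
  expect_equal(S[[2]][, , , 1], S2_ref, tolerance = 1e-12)
  expect_equal(S[[1]][, , , 1], S1_ref, tolerance = 1e-12)
})

test_that("DS.v2 signals follow the prevS recursion and pooled upper signal", {
  chans <- c(3L, 4L, 5L)
  m <- 2L
  head <- with_seed(10, ds_head(2L, chans, m))
  C <- list(with_seed(11, array(rnorm(8 * 8 * 3), c(8, 8, 3))),
            with_seed(12, array(rnorm(4 * 4 * 4), c(4, 4, 4))),
            with_seed(13, array(rnorm(2 * 2 * 5), c(2, 2, 5))))
  S <- module_forward(head, C)
  pw <- lapply(head$layers$pconvs, function(cv) cv$w$value)
  pb <- lapply(head$layers$pconvs, function(cv) cv$b$value)
  sw <- lapply(head$layers$sconvs, function(cv) cv$w$value)
  sb <- lapply(head$layers$sconvs, function(cv) cv$b$value)
  pool_ref <- function(x) {
    d <- dim(x)
    out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
    for (c in seq_len(d[3])) {
      for (i in seq_len(d[1] / 2)) {
        for (j in seq_len(d[2] / 2)) {
          out[i, j, c] <- max(x[2 * i - 1:0, 2 * j - 1:0, c])
        }
      }
    }
    out
  }
  prev3 <- conv1x1_ref(C[[3]], pw[[3]], pb[[3]])
  prev2 <- conv1x1_ref(C[[2]], pw[[2]], pb[[2]]) + up_ref(prev3)
  prev1 <- conv1x1_ref(C[[1]], pw[[1]], pb[[1]]) + up_ref(prev2)
  S1_ref <- prev1
  S2_ref <- conv1x1_ref(C[[2]], sw[[1]], sb[[1]]) + up_ref(prev3) +
    pool_ref(S1_ref)
  expect_equal(S[[1]][, , , 1], S1_ref, tolerance = 1e-12)
  expect_equal(S[[2]][, , , 1], S2_ref, tolerance = 1e-12)
  # extents match level-wise
  expect_identical(dim(S[[1]])[1:2], c(8L, 8L))
  expect_identical(dim(S[[2]])[1:2], c(4L, 4L))
})

test_that("DS.v3 aggregates decoder outputs to full extent", {
  chans <- c(3L, 4L)
  head <- with_seed(14, ds_head(3L, chans, 2L))
  T1 <- with_seed(15, array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  T2 <- with_seed(16, array(rnorm(4 * 4 * 4), c(4, 4, 4)))
  Z1 <- module_forward(head, list(T1, T2))
  w <- lapply(head$layers$convs, function(cv) cv$w$value)
  b <- lapply(head$layers$convs, function(cv) cv$b$value)
  ref <- conv1x1_ref(T1, w[[1]], b[[1]]) +
    up_ref(conv1x1_ref(T2, w[[2]], b[[2]]))
  expect_equal(Z1[, , , 1], ref, tolerance = 1e-12)
  expect_identical(dim(Z1)[1:2], c(8L, 8L))
  expect_identical(dim(Z1)[3], 2L)

  # single-level degenerate case: Z1 = conv1x1(T1)
  h1 <- with_seed(17, ds_head(3L, 3L, 2L))
  z <- module_forward(h1, list(T1))
  expect_equal(z[, , , 1],
               conv1x1_ref(T1, h1$layers$convs[[1]]$w$value,
                           h1$layers$convs[[1]]$b$value),
               tolerance = 1e-12)
})

test_that("DS graphs are linear: zero weights null, doubling doubles", {
  for (version in 1:3) {
    chans <- c(3L, 4L, 5L)
    head <- with_seed(20 + version, ds_head(version, chans, 2L))
    C <- list(with_seed(24, array(rnorm(8 * 8 * 3), c(8, 8, 3))),
              with_seed(25, array(rnorm(4 * 4 * 4), c(4, 4, 4))),
              with_seed(26, array(rnorm(2 * 2 * 5), c(2, 2, 5))))
    base <- module_forward(head, C)
    # zero biases so the graph is homogeneous in the weights
    for (p in head$params) if (is.null(dim(p$value))) p$value <- 0 * p$value
    ref <- module_forward(head, C)
    for (p in head$params) p$value <- 2 * p$value
    doubled <- module_forward(head, C)
    flat <- function(x) if (is.list(x)) unlist(lapply(x, as.vector)) else as.vector(x)
    expect_equal(flat(doubled), 2 * flat(ref), tolerance = 1e-10)
    for (p in head$params) if (!is.null(dim(p$value))) p$value <- 0 * p$value
    nulled <- module_forward(head, C)
    expect_true(all(abs(flat(nulled)) < 1e-15))
  }
})
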