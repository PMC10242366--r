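test_that("the registry holds exactly the 13 configurations with their hyperparameters", {
  reg <- topology_registry()
  expect_length(reg, 13L)
  ids <- vapply(reg, `[[`, character(1), "id")
  expect_setequal(ids, c("UDD2", "UMDD", "UDD", "UQD", "UVDD", "UVMD", "UAMD",
                         "UMD", "UAD", "UD", "UA", "U1", "FCN"))
  expect_equal(topology_spec("UAD")$optimizer, "rmsprop")
  expect_equal(topology_spec("UAD")$learning_rate, 0.001)
  expect_equal(topology_spec("U1")$optimizer, "adadelta")
  expect_equal(topology_spec("U1")$learning_rate, 1.0)
  expect_equal(topology_spec("UVDD")$activation, "prelu")
  others <- setdiff(ids, c("UAD", "U1"))
  for (id in others) {
    sp <- topology_spec(id)
    expect_equal(sp$optimizer, "adam", info = id)
    expect_equal(sp$learning_rate, 0.00033, info = id)
    if (id != "UVDD") expect_equal(sp$activation, "relu", info = id)
  }
  # structural flags
  expect_true(topology_spec("UMD")$multi_kernel)
  expect_equal(topology_spec("UMD")$fusion, "skip")
  expect_true(topology_spec("UMD")$use_ds_v3)
  expect_equal(topology_spec("UDD2")$fusion, "ds_v2")
  expect_equal(topology_spec("UDD")$fusion, "ds_v1")
  expect_equal(topology_spec("UQD")$encoder_block, "Q")
  expect_false(topology_spec("U1")$use_ds_v3)
  expect_error(topology_spec("XYZ"), "unknown topology")
})

test_that("built networks honour their structural specification", {
  m_umd <- with_seed(1, build_topology("UMD", m = 8, num_classes = 4))
  expect_false(is.null(m_umd$layers$mk))
  expect_false(is.null(m_umd$layers$ds3))
  expect_null(m_umd$layers$fusion)
  expect_equal(m_umd$layers$enc[[1]]$kind, "unet_conv")

  m_uvdd <- with_seed(2, build_topology("UVDD", m = 8, num_classes = 4))
  expect_equal(m_uvdd$layers$enc[[1]]$kind, "vgg_conv")
  expect_equal(m_uvdd$layers$dec[[1]]$kind, "unet_conv") # V encoder-only
  depths <- vapply(m_uvdd$layers$enc, function(b) b$depth, integer(1))
  expect_equal(depths, c(2L, 2L, 3L, 3L)) # VGG16 level layout
  expect_equal(m_uvdd$layers$bottleneck$depth, 3L)
  expect_equal(m_uvdd$layers$fusion$kind, "ds_v1")

  m_udd2 <- with_seed(3, build_topology("UDD2", m = 8, num_classes = 4))
  expect_equal(m_udd2$layers$fusion$kind, "ds_v2")

  m_uqd <- with_seed(4, build_topology("UQD", m = 8, num_classes = 4))
  expect_equal(m_uqd$layers$enc[[2]]$kind, "dense_conv")
  expect_equal(m_uqd$layers$dec[[2]]$kind, "dense_conv")
})

test_that("U1 with skip fusion reduces to the original U-Net wiring (S[n] = C[n])", {
  # structural: no fusion module exists, so the decoder concatenates the
  # encoder feature maps themselves
  m <- with_seed(5, build_topology("U1", m = 8, num_classes = 4))
  expect_null(m$layers$fusion)
  expect_equal(m$spec$fusion, "skip")
  expect_null(m$layers$ds3)
  # decoder block input widths equal enc channels + upsampled channels
  cins <- vapply(m$layers$dec, function(b) b$layers$conv1$cin, integer(1))
  expect_equal(cins, c(8L + 8L, 16L + 16L, 32L + 32L, 64L + 64L))
})

test_that("every registry topology emits normalized scores at a small extent", {
  x <- with_seed(6, array(rnorm(32 * 32 * 2), c(32, 32, 2)))
  for (id in vapply(topology_registry(), `[[`, character(1), "id")) {
    model <- with_seed(7, build_topology(id, m = 8, num_classes = 5))
    sc <- model_forward(model, x, training = TRUE)
    expect_identical(dim(sc), c(32L, 32L, 5L), info = id)
    sums <- apply(sc, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_true(all(sc >= 0), info = id)
  }
})

test_that("illegal configurations are rejected", {
  expect_error(build_topology("nope"), "unknown topology")
  # FCN needs extents divisible by 32
  fcn <- with_seed(8, build_fcn8(4, 2, base_filters = 4))
  expect_error(model_forward(fcn, array(0, c(48, 48, 2))), "divisible by 32")
  sc <- model_forward(fcn, with_seed(9, array(rnorm(64 * 64 * 2),
                                              c(64, 64, 2))), training = TRUE)
  expect_identical(dim(sc), c(64L, 64L, 4L))
  expect_lt(max(abs(apply(sc, c(1, 2), sum) - 1)), 1e-6)
})

test_that("one optimizer step changes every trainable parameter group", {
  ss <- asNamespace("spineseg")
  set.seed(10)
  model <- build_topology("UAMD", m = 4, num_classes = 3)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  y <- array(0, c(16, 16, 3, 2)); y[, , 2, ] <- 1
  before <- lapply(model$params, function(p) p$value)
  tape <- ss$ag_tape()
  out <- model$fwd(tape, ss$ag_leaf(tape, x), training = TRUE)
  loss <- ss$op_softmax_ce(tape, out$logits, y)
  ss$ag_backward(tape, loss)
  opt <- ss$make_optimizer("adam", 1e-3)
  opt$step(model$params)
  changed <- mapply(function(p, b) any(p$value != b), model$params, before)
  expect_true(all(changed))
})
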