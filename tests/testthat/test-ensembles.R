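test_that("the ensemble registry matches the published compositions", {
  reg <- ensemble_registry()
  expect_named(reg, paste0("E", 4:13))
  expect_equal(ensemble_registry("E4"), c("UAD", "UMD", "UQD", "UDD"))
  expect_length(ensemble_registry("E13"), 13L)
  sizes <- vapply(reg, length, integer(1))
  expect_equal(unname(sizes), 4:13)
  # FCN appears only in E8 and E13
  has_fcn <- names(reg)[vapply(reg, function(x) "FCN" %in% x, logical(1))]
  expect_setequal(has_fcn, c("E8", "E13"))
  expect_error(ensemble_registry("E99"), "unknown ensemble")
})

test_that("model averaging reproduces the hand-computed two-member example", {
  mk <- function(p) array(rep(p, each = 1), c(1, 1, 2))
  a <- mk(c(0.8, 0.2)); b <- mk(c(0.4, 0.6))
  arith <- average_ensemble(list(a, b), "arith")
  expect_equal(as.vector(arith), c(0.6, 0.4), tolerance = 1e-12)
  geo <- average_ensemble(list(a, b), "geo")
  raw <- c(sqrt(0.8 * 0.4), sqrt(0.2 * 0.6))
  expect_equal(as.vector(geo), raw / sum(raw), tolerance = 1e-12)
  expect_equal(as.vector(geo), c(0.6202, 0.3798), tolerance = 1e-4)
})

test_that("averaging is idempotent, normalized, order-invariant, with AM >= GM", {
  s1 <- random_scoremap(6, 5, 4, seed = 1)
  s2 <- random_scoremap(6, 5, 4, seed = 2)
  s3 <- random_scoremap(6, 5, 4, seed = 3)
  for (mode in c("arith", "geo")) {
    # idempotence on identical members
    expect_equal(average_ensemble(list(s1, s1, s1), mode), s1,
                 tolerance = 1e-9)
    # permutation invariance
    expect_equal(average_ensemble(list(s1, s2, s3), mode),
                 average_ensemble(list(s3, s1, s2), mode), tolerance = 1e-12)
    # normalization preserved
    out <- average_ensemble(list(s1, s2, s3), mode)
    expect_lt(max(abs(apply(out, c(1, 2), sum) - 1)), 1e-9)
  }
  # arithmetic normalization is exact algebraically
  out <- average_ensemble(list(s1, s2), "arith")
  expect_equal(apply(out, c(1, 2), sum), matrix(1, 6, 5), tolerance = 1e-14)
  # AM >= GM before renormalization, per class per pixel
  raw_geo <- (pmax(s1, 1e-12) * pmax(s2, 1e-12) * pmax(s3, 1e-12))^(1 / 3)
  expect_true(all((s1 + s2 + s3) / 3 >= raw_geo - 1e-12))
  # absorbing zero in the geometric mean
  z <- s1; z[1, 1, 2] <- 0; z[1, 1, ] <- z[1, 1, ] / sum(z[1, 1, ])
  geo <- average_ensemble(list(z, s2), "geo")
  expect_lt(geo[1, 1, 2], 1e-5)
  expect_error(average_ensemble(list(), "arith"), "at least one")
  expect_error(average_ensemble(list(s1, random_scoremap(3, 3, 4)), "arith"),
               "shape")
})

test_that("stacking heads have the configured merge widths", {
  members <- with_seed(4, lapply(c("UD", "UMD", "U1"), function(id) {
    build_topology(id, m = 8, num_classes = 4)
  }))
  nad <- build_stacking_head(members, stacking_config("NAD"), num_classes = 4)
  expect_equal(nad$merged_width, 4L)       # average preserves K
  expect_equal(nad$cfg$input_kind, "N")
  ncd <- build_stacking_head(members, stacking_config(input_kind = "N",
                                                      merge = "concat"),
                             num_classes = 4)
  expect_equal(ncd$merged_width, 3L * 4L)  # R * K concat
  tcd <- build_stacking_head(members, stacking_config("TCD"), num_classes = 4)
  expect_equal(tcd$merged_width, 8L + 8L + 8L) # R * m feature tensors
  expect_equal(tcd$cfg$learning_rate, 0.00033)
  expect_equal(tcd$cfg$epochs, 50L)
  # FCN has no pre-classification tensor: T-input stacking is rejected
  fcn <- with_seed(5, build_topology("FCN", m = 4, num_classes = 4))
  expect_error(build_stacking_head(list(members[[1]], fcn),
                                   stacking_config("TCD"), num_classes = 4),
               "pre-classification")
  # untrained head output is still normalized per pixel
  x <- with_seed(6, array(rnorm(32 * 32 * 2), c(32, 32, 2)))
  sc <- stacking_forward(nad, x)
  expect_lt(max(abs(apply(sc, c(1, 2), sum) - 1)), 1e-6)
})

test_that("stacking training leaves member weights bit-identical", {
  members <- with_seed(7, lapply(c("U1", "UD"), function(id) {
    build_topology(id, m = 4, num_classes = 4)
  }))
  data <- tiny_patch_data(n_slices = 2)
  tr <- spineseg:::dataset_subset(data, 1:4)
  va <- spineseg:::dataset_subset(data, 5:6)
  before <- lapply(members, function(m) lapply(m$params, function(p) p$value))
  head <- build_stacking_head(members,
                              stacking_config("NAD", epochs = 2L),
                              num_classes = 4)
  fit <- train_stacking(head, tr, va, seed = 1)
  expect_true(all(is.finite(fit$log$train_loss)))
  expect_equal(nrow(fit$log), 2L)
  after <- lapply(members, function(m) lapply(m$params, function(p) p$value))
  expect_identical(after, before)
  # fixed-seed reproducibility of the loss curve
  head2 <- with_seed(8, build_stacking_head(members,
                                            stacking_config("NAD", epochs = 2L),
                                            num_classes = 4))
  head3 <- with_seed(8, build_stacking_head(members,
                                            stacking_config("NAD", epochs = 2L),
                                            num_classes = 4))
  log2 <- train_stacking(head2, tr, va, seed = 5)$log
  log3 <- train_stacking(head3, tr, va, seed = 5)$log
  expect_identical(log2, log3)
  # augmented stacking training also runs and keeps members frozen
  head4 <- with_seed(9, build_stacking_head(members,
                                            stacking_config("NAD", epochs = 1L),
                                            num_classes = 4))
  fit4 <- train_stacking(head4, tr, va, seed = 2, augment = augment_config())
  expect_true(all(is.finite(fit4$log$train_loss)))
  after4 <- lapply(members, function(m) lapply(m$params, function(p) p$value))
  expect_identical(after4, before)
})

test_that("leave-one-out ablation matches brute-force recomputation", {
  K <- 4L
  truths <- lapply(1:3, function(i) label_mask(random_labels(12, 12, K,
                                                             seed = 20 + i), K))
  ids <- c("A", "B", "C")
  scores <- setNames(lapply(1:3, function(r) {
    lapply(1:3, function(i) random_scoremap(12, 12, K, seed = 10 * r + i))
  }), ids)
  res <- ablate_ensemble(scores, truths, held_out = "B", mode = "arith")
  # brute force: rebuild the ablated ensemble from scratch
  agg <- NULL
  for (i in 1:3) {
    comb <- average_ensemble(list(scores$A[[i]], scores$C[[i]]), "arith")
    cnt <- confusion_counts(map_label(comb), truths[[i]], K)
    if (is.null(agg)) agg <- cnt else {
      for (f in c("tp", "fp", "fn", "tc", "mc")) agg[[f]] <- agg[[f]] + cnt[[f]]
    }
  }
  ref <- seg_metrics(agg)
  expect_equal(res$ablated$per_class$iou, ref$per_class$iou, tolerance = 1e-12)
  expect_equal(res$delta, ref$per_class$iou - res$full$per_class$iou,
               tolerance = 1e-12)

  # identical members: zero delta everywhere
  same <- setNames(lapply(1:3, function(r) scores$A), ids)
  res0 <- ablate_ensemble(same, truths, held_out = "C", mode = "arith")
  expect_true(all(res0$delta == 0))

  # two-member ensemble: removal leaves the remaining single model
  two <- scores[c("A", "B")]
  res2 <- ablate_ensemble(two, truths, held_out = "B", mode = "arith")
  aggA <- NULL
  for (i in 1:3) {
    cnt <- confusion_counts(map_label(scores$A[[i]]), truths[[i]], K)
    if (is.null(aggA)) aggA <- cnt else {
      for (f in c("tp", "fp", "fn", "tc", "mc")) {
        aggA[[f]] <- aggA[[f]] + cnt[[f]]
      }
    }
  }
  expect_equal(res2$ablated$per_class$iou, seg_metrics(aggA)$per_class$iou,
               tolerance = 1e-12)
  expect_error(ablate_ensemble(scores, truths, held_out = "Z"), "not in")
})
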