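test_that("MAP labeling is the per-pixel argmax with lowest-index ties", {
  sc <- array(0, c(1, 2, 3))
  sc[1, 1, ] <- c(0, 0, 1)
  sc[1, 2, ] <- c(0.5, 0.5, 0)
  lab <- map_label(sc)
  expect_equal(lab$labels[1, 1], 2L)
  expect_equal(lab$labels[1, 2], 0L) # tie breaks to the lowest class
  # oracle: brute-force per-pixel max scan on random maps
  for (rep in 1:5) {
    s <- random_scoremap(9, 7, 12, seed = rep)
    got <- map_label(s)$labels
    ref <- matrix(0L, 9, 7)
    for (i in 1:9) for (j in 1:7) ref[i, j] <- which.max(s[i, j, ]) - 1L
    expect_identical(got, ref)
  }
})

test_that("the threshold cascade follows the hand-traced examples", {
  sc <- array(c(0.20, 0.45, 0.35), c(1, 1, 3))
  # c1 rejected (0.45 < 0.50), c2 accepted (0.35 >= 0.30)
  expect_equal(th_label(sc, c(0, 0.50, 0.30))$labels[1, 1], 2L)
  # both rejected -> background
  expect_equal(th_label(sc, c(0, 0.50, 0.40))$labels[1, 1], 0L)
  # acceptance uses >= : threshold exactly at the score accepts
  expect_equal(th_label(sc, c(0, 0.45, 0.90))$labels[1, 1], 1L)
})

test_that("th_label with zero thresholds reduces to map_label", {
  for (rep in 1:50) {
    s <- random_scoremap(8, 6, 5, seed = 100 + rep)
    expect_identical(th_label(s, numeric(5))$labels, map_label(s)$labels)
  }
})

test_that("threshold tuning equals an exhaustive sweep oracle", {
  K <- 4L
  sc <- list(random_scoremap(16, 16, K, seed = 1),
             random_scoremap(16, 16, K, seed = 2))
  masks <- list(label_mask(random_labels(16, 16, K, seed = 3), K),
                label_mask(random_labels(16, 16, K, seed = 4), K))
  tuned <- tune_thresholds(sc, masks)
  expect_equal(tuned$thresholds[1], 0) # background never thresholded
  grid <- threshold_grid()
  expect_length(grid, 19L)
  all_s <- rbind(matrix(sc[[1]], 256, K), matrix(sc[[2]], 256, K))
  all_l <- c(as.vector(masks[[1]]$labels), as.vector(masks[[2]]$labels))
  for (c in 2:K) {
    truth <- all_l == (c - 1L)
    ious <- sapply(grid, function(t) {
      pred <- all_s[, c] >= t
      sum(pred & truth) / sum(pred | truth)
    })
    expect_equal(tuned$thresholds[c], grid[which.max(ious)])
  }
})

test_that("perfect one-hot scores tie every grid value; tie rule returns 0.05", {
  lab <- random_labels(10, 10, 3, seed = 5)
  sc <- encode_onehot(lab, 3L)
  class(sc) <- NULL
  tuned <- tune_thresholds(list(sc), list(label_mask(lab, 3L)))
  expect_equal(tuned$thresholds[-1], c(0.05, 0.05))
  # a constructed one-class toy where t = 0.50 is the unique maximizer
  s <- array(0, c(1, 4, 2))
  s[1, , 2] <- c(0.9, 0.55, 0.45, 0.1)
  s[1, , 1] <- 1 - s[1, , 2]
  m <- label_mask(matrix(c(1L, 1L, 0L, 0L), 1, 4), 2L)
  tuned2 <- tune_thresholds(list(s), list(m))
  expect_equal(tuned2$thresholds[2], 0.50)
  expect_error(tune_thresholds(list(), list()), "empty")
})

test_that("confusion counts match a brute-force double loop", {
  # hand count on the 2x2 toy
  truth <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  pred <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  cnt <- confusion_counts(pred, truth, 2L)
  expect_equal(cnt$tp[2], 2)
  expect_equal(cnt$fn[2], 1)
  expect_equal(cnt$fp[2], 0)
  # identity
  cnt0 <- confusion_counts(truth, truth, 2L)
  expect_true(all(cnt0$fp == 0) && all(cnt0$fn == 0))
  # oracle on random masks
  for (rep in 1:5) {
    K <- 6L
    p <- random_labels(11, 13, K, seed = 200 + rep)
    t <- random_labels(11, 13, K, seed = 300 + rep)
    got <- confusion_counts(p, t, K)
    ref <- brute_confusion(p, t, K)
    for (f in c("tp", "fp", "fn", "tc", "mc")) {
      expect_equal(got[[f]], ref[[f]], info = f)
    }
    expect_equal(sum(got$tc), 11 * 13)
    expect_equal(sum(got$mc), 11 * 13)
  }
  expect_error(confusion_counts(p, t[1:5, ], K), "shape")
})

test_that("metrics follow the confusion-count formulas", {
  cnt <- structure(list(tp = c(10, 3), fp = c(0, 1), fn = c(0, 2),
                        tc = c(10, 5), mc = c(10, 4), num_classes = 2L),
                   class = "confusion_counts")
  m <- seg_metrics(cnt)
  expect_equal(m$per_class$iou[2], 3 / 6)
  expect_equal(m$per_class$precision[2], 0.75)
  expect_equal(m$per_class$recall[2], 0.6)
  expect_equal(m$per_class$f1[2], 6 / 9)
  expect_equal(m$mean_iou, 0.5)            # only the target class
  expect_equal(m$mean_iou_with_bg, 0.75)
  # perfect prediction
  t <- random_labels(8, 8, 4, seed = 6)
  perfect <- seg_metrics(confusion_counts(t, t, 4L))
  expect_equal(perfect$mean_iou, 1)
  expect_true(all(perfect$per_class$f1[perfect$per_class$present] == 1))
  # absent class: vacuous 0/0 -> 1, excluded from means
  small <- seg_metrics(confusion_counts(matrix(0L, 2, 2), matrix(0L, 2, 2),
                                        3L))
  expect_equal(small$per_class$iou, c(1, 1, 1))
  expect_true(is.na(small$mean_iou)) # no target class present
  # IoU <= F1 (IoU <= Dice) on random masks
  for (rep in 1:10) {
    p <- random_labels(10, 10, 5, seed = 400 + rep)
    t <- random_labels(10, 10, 5, seed = 500 + rep)
    m <- seg_metrics(confusion_counts(p, t, 5L))
    expect_true(all(m$per_class$iou <= m$per_class$f1 + 1e-12))
    expect_true(all(m$per_class$iou >= 0 & m$per_class$iou <= 1))
  }
})

test_that("the Wilcoxon comparison behaves like the reference implementation", {
  a <- with_seed(7, runif(20, 0.6, 0.9))
  expect_equal(wilcoxon_compare(a, a)$p_value, 1)
  shifted <- wilcoxon_compare(a + 0.05, a)
  expect_lt(shifted$p_value, 0.05)
  expect_true(shifted$significant)
  b <- with_seed(8, a + rnorm(20, 0, 0.05))
  got <- wilcoxon_compare(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE)$p.value)
  expect_equal(got$p_value, ref, tolerance = 1e-12)
  expect_error(wilcoxon_compare(a, a[1:5]), "equal length")
})
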