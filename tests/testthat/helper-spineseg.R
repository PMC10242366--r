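# Shared fixture builders. Everything is generated in code at test time.

# A random normalized (H, W, K) score map.
random_scoremap <- function(h, w, k, seed = NULL) {
  make <- function() {
    x <- array(stats::rexp(h * w * k), c(h, w, k))
    s <- apply(x, c(1, 2), sum)
    x / as.vector(s)
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

# A random integer label mask.
random_labels <- function(h, w, k, seed = NULL) {
  make <- function() matrix(sample(0:(k - 1), h * w, replace = TRUE), h, w)
  if (is.null(seed)) make() else with_seed(seed, make())
}

# Brute-force per-pixel confusion counting (independent oracle).
brute_confusion <- function(pred, truth, K) {
  tp <- fp <- fn <- tc <- mc <- numeric(K)
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      tc[t + 1] <- tc[t + 1] + 1
      mc[p + 1] <- mc[p + 1] + 1
      if (p == t) tp[p + 1] <- tp[p + 1] + 1 else {
        fp[p + 1] <- fp[p + 1] + 1
        fn[t + 1] <- fn[t + 1] + 1
      }
    }
  }
  list(tp = tp, fp = fp, fn = fn, tc = tc, mc = mc)
}

# Small desk-scale phantom configuration shared by several tests.
desk_phantom <- function(num_classes = 4L, n_patients = 6L, sizes = 128L,
                         seed = 42L, noise_sigma = 0.08) {
  phantom_config(n_patients = n_patients,
                 slices_per_patient = c(3L, 4L),
                 sizes = sizes, num_classes = num_classes,
                 noise_sigma = noise_sigma, seed = seed)
}

# Tiny patch dataset for training smoke tests.
tiny_patch_data <- function(n_slices = 4, num_classes = 4L, seed = 9L,
                            patch = 32L, stride = 24L) {
  cfg <- phantom_config(n_patients = 1, sizes = 64L,
                        num_classes = num_classes, seed = seed)
  slices <- with_seed(seed, lapply(seq_len(n_slices), function(i) {
    generate_phantom_slice(cfg, size = 64L, patient_id = "p1",
                           slice_index = i - 1L)
  }))
  prepare_patch_dataset(slices, patch, stride, num_classes)
}
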