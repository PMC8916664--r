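test_that("subject templates are deterministic, distinct and well-shaped", {
  t1 <- make_subject_template(7, T_len = 50)
  t2 <- make_subject_template(7, T_len = 50)
  expect_identical(t1$signal, t2$signal)
  t3 <- make_subject_template(8, T_len = 50)
  expect_gt(sqrt(sum((t1$signal - t3$signal)^2)), 0)
  expect_identical(dim(t1$signal), c(50L, 28L))
  lay <- modality_layout()
  expect_true(all(t1$signal[, lay$pre] >= 0))
  expect_true(all(t1$signal[t1$swing, lay$pre] == 0))
})

test_that("a noiseless unjittered step is the floored template", {
  tpl <- make_subject_template(3, T_len = 40)
  set.seed(1)
  s <- generate_unit_step(tpl, noise_sd = 0, jitter = 0, delta = 0.01)
  expect_equal(s[, ], apply_pressure_floor(tpl$signal, 0.01)[, ],
               ignore_attr = TRUE)
  # swing-window pressure is exactly delta after zeroing + flooring
  lay <- modality_layout()
  s2 <- withr::with_seed(2, generate_unit_step(tpl, noise_sd = 0.2,
                                               jitter = 0.05))
  expect_true(all(s2[tpl$swing, lay$pre] == 0.01))
})

test_that("the within-subject mean converges to the template (law of large numbers)", {
  tpl <- make_subject_template(5, T_len = 30)
  lay <- modality_layout()
  n <- 1000; sd0 <- 0.1
  set.seed(11)
  acc <- matrix(0, 30, 28)
  for (i in seq_len(n))
    acc <- acc + generate_unit_step(tpl, noise_sd = sd0, jitter = 0)
  m <- acc / n
  tol <- 3 * sd0 / sqrt(n)                 # per-entry 3-sigma band
  # acceleration/rotation channels carry plain additive noise
  dev_ar <- abs(m[, c(lay$acc, lay$rot)] - tpl$signal[, c(lay$acc, lay$rot)])
  idx <- sample(length(dev_ar), 20)
  expect_true(all(dev_ar[idx] < tol))
  # pressure: compare away from the clipping region (template well above 0)
  big <- tpl$signal[, lay$pre] > 3 * sd0
  dev_p <- abs((m[, lay$pre] - tpl$signal[, lay$pre])[big])
  expect_true(all(dev_p[sample(length(dev_p), 20)] < tol))
})

test_that("dataset generation honors counts, layout and byte-level determinism", {
  ds <- tiny_dataset(n_subjects = 2, steps = 3, T_len = 20, seed = 5)
  expect_length(ds$steps, 2)
  expect_true(all(vapply(ds$steps, length, 1L) == 3))
  ds2 <- tiny_dataset(n_subjects = 2, steps = 3, T_len = 20, seed = 5)
  expect_identical(ds$steps, ds2$steps)

  dir <- withr::local_tempdir()
  write_gait_bundle(ds, file.path(dir, "b1"))
  write_gait_bundle(ds2, file.path(dir, "b2"))
  f1 <- list.files(file.path(dir, "b1"), recursive = TRUE)
  expect_length(grep("step_", f1), 6)              # 2 subjects x 3 files
  expect_true("manifest.json" %in% f1)
  for (f in f1)
    expect_identical(readLines(file.path(dir, "b1", f)),
                     readLines(file.path(dir, "b2", f)))
  back <- read_gait_bundle(file.path(dir, "b1"))
  expect_equal(back$steps[["S01"]][[2]][, ], ds$steps[["S01"]][[2]][, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("subjects are separable: between-template distance exceeds step noise", {
  ds <- tiny_dataset(n_subjects = 4, steps = 10, T_len = 40, seed = 21)
  ids <- names(ds$steps)
  within <- c(); between <- c()
  for (a in ids) {
    tpl <- apply_pressure_floor(ds$templates[[a]]$signal, ds$delta)
    within <- c(within, vapply(ds$steps[[a]],
                               function(s) sqrt(sum((s - tpl)^2)), 0))
    for (b in setdiff(ids, a)) {
      tplb <- apply_pressure_floor(ds$templates[[b]]$signal, ds$delta)
      between <- c(between, sqrt(sum((tpl - tplb)^2)))
    }
  }
  expect_gt(min(between), max(within) * 0.9)
  expect_gt(mean(between), mean(within))
})

test_that("synthetic recordings segment back into the expected number of cycles", {
  tpl <- make_subject_template(13, T_len = 50)
  set.seed(3)
  rec <- generate_recording(tpl, n_cycles = 5, noise_sd = 0.02)
  sm <- smooth_pressure(rec, sigma = 2)
  steps <- segment_unit_steps(sm, T_len = 50, swing_threshold = 0.5)
  expect_length(steps, 4)              # 5 onsets close 4 full cycles
})

test_that("optional quantization snaps pressure to three sensor levels", {
  tpl <- make_subject_template(17, T_len = 30)
  lay <- modality_layout()
  set.seed(6)
  s <- generate_unit_step(tpl, noise_sd = 0.1, jitter = 0, delta = 0.01,
                          quantize = TRUE)
  expect_true(all(s[, lay$pre] %in% c(0.01, 0.5, 1)))
  sc <- generate_unit_step(tpl, noise_sd = 0.1, jitter = 0, delta = 0.01)
  expect_gt(length(unique(as.vector(sc[, lay$pre]))), 3)
})
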