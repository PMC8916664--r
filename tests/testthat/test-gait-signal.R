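test_that("Gaussian smoothing preserves constants and matches direct convolution", {
  lay <- modality_layout()
  rec <- matrix(0, 60, 28, dimnames = list(NULL, lay$channels))
  rec[, lay$pre] <- 2
  rec[, lay$acc] <- 5
  sm <- smooth_pressure(rec, sigma = 3)
  expect_equal(sm[, lay$pre], rec[, lay$pre], tolerance = 1e-12)
  expect_identical(sm[, lay$acc], rec[, lay$acc])

  # single-sample spike: peak shrinks to h * (kernel center weight)
  x <- numeric(101); x[51] <- 4
  sm1 <- gaussian_smooth(x, sigma = 2)
  expect_equal(sm1, oracle_gauss_smooth(x, 2), tolerance = 1e-10)
  r <- ceiling(4 * 2)
  k <- dnorm(seq(-r, r), sd = 2); k <- k / sum(k)
  expect_equal(sm1[51], 4 * k[r + 1], tolerance = 1e-10)

  # narrow kernel keeps two bursts separated by a near-zero valley
  x2 <- c(rep(0, 10), rep(1, 15), rep(0, 20), rep(1, 15), rep(0, 10))
  sm2 <- gaussian_smooth(x2, sigma = 0.5)
  expect_equal(sm2, oracle_gauss_smooth(x2, 0.5), tolerance = 1e-10)
  expect_lt(max(sm2[30:40]), 0.05)
  expect_error(smooth_pressure(rec, sigma = 0), "sigma")
})

make_burst_recording <- function(bursts = 3, stance = 30, swing = 30,
                                 lead = 10) {
  lay <- modality_layout()
  n <- lead + bursts * (stance + swing)
  rec <- matrix(0, n, 28, dimnames = list(NULL, lay$channels))
  for (b in seq_len(bursts)) {
    from <- lead + (b - 1) * (stance + swing) + 1
    rec[from:(from + stance - 1), lay$pre] <- 1
  }
  rec
}

test_that("segmentation finds one unit step per full stance-swing cycle", {
  rec <- make_burst_recording(bursts = 3)
  steps <- segment_unit_steps(rec, T_len = 50, swing_threshold = 0.5)
  expect_length(steps, 2)             # third onset terminates the second cycle
  expect_identical(dim(steps[[1]]), c(50L, 28L))

  # constant zero pressure: no stance onset, no steps, no error
  expect_length(segment_unit_steps(matrix(0, 40, 28), T_len = 20), 0)
  expect_error(segment_unit_steps(rec, T_len = 1), "T_len")
})

test_that("sub-threshold swing noise does not change the segmentation count", {
  rec <- make_burst_recording(bursts = 3)
  noisy <- rec
  noisy[55, 3] <- 1                    # sporadic single-sample pressure blip
  sm <- smooth_pressure(noisy, sigma = 3)
  steps <- segment_unit_steps(sm, T_len = 50, swing_threshold = 0.5)
  expect_length(steps, 2)
  # oracle: hand-smoothed summed pressure stays below threshold mid-swing
  p_sm <- oracle_gauss_smooth(rowSums(noisy[, 1:16]), 3)
  expect_lt(max(p_sm[50:60]), 0.5)
})

test_that("pressure floor replaces exact zeros in pressure channels only", {
  lay <- modality_layout()
  s <- matrix(0, 10, 28, dimnames = list(NULL, lay$channels))
  s[3, 1] <- 2
  s[5, lay$acc[1]] <- 0
  f <- apply_pressure_floor(s, 0.01)
  expect_equal(unname(f[1, 1]), 0.01)
  expect_equal(unname(f[3, 1]), 2)                 # non-zero untouched
  expect_equal(unname(f[5, lay$acc[1]]), 0)        # acceleration untouched
  expect_identical(apply_pressure_floor(f, 0.01), f)   # idempotent
  expect_error(apply_pressure_floor(s, 0), "delta")
})

test_that("prototype is the element-wise mean and is permutation invariant", {
  s <- random_step(12, seed = 3)
  expect_equal(unclass(compute_prototype(list(s, s, s)))[, ], s[, ],
               ignore_attr = TRUE)

  a <- matrix(1, 12, 28); b <- matrix(3, 12, 28)
  expect_true(all(compute_prototype(list(a, b)) == 2))

  set.seed(4)
  steps <- lapply(1:5, function(i) random_step(12, seed = 100 + i))
  loop_mean <- matrix(0, 12, 28)
  for (s_i in steps) loop_mean <- loop_mean + s_i / 5
  pr <- compute_prototype(steps)
  expect_equal(unclass(pr)[, ], loop_mean, ignore_attr = TRUE)
  expect_equal(attr(pr, "q"), 5)
  pr2 <- compute_prototype(rev(steps))
  expect_equal(unclass(pr)[, ], unclass(pr2)[, ], ignore_attr = TRUE)

  expect_error(compute_prototype(list()), "non-empty")
  s1 <- s; attr(s1, "subject") <- "A"
  s2 <- s; attr(s2, "subject") <- "B"
  expect_error(compute_prototype(list(s1, s2)), "different subjects")
})

test_that("L2 normalization has unit norm, idempotence and scale invariance", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- l2_normalize(matrix(rnorm(40), 10, 4))
  expect_equal(l2_normalize(u), u)
  x <- matrix(rnorm(40), 10, 4)
  expect_equal(l2_normalize(10 * x), l2_normalize(x))
  for (i in 1:10) {
    set.seed(i)
    expect_equal(sqrt(sum(l2_normalize(rnorm(7))^2)), 1, tolerance = 1e-9)
  }
  expect_error(l2_normalize(matrix(0, 2, 2)), "zero")
})

test_that("row resampling interpolates linearly to the target length", {
  x <- cbind(seq(0, 9), seq(0, 18, by = 2))
  y <- resample_rows(x, 19)
  expect_identical(dim(y), c(19L, 2L))
  expect_equal(y[, 1], seq(0, 9, by = 0.5))       # linear stays linear
  expect_equal(y[1, ], x[1, ]); expect_equal(y[19, ], x[10, ])
})
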