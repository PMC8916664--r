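test_that("sensitivity maps are non-negative gradients matching finite differences", {
  enc <- build_encoder(small_config(T_len = 16, seed = 23))
  s <- random_step(16, seed = 71)
  for (comp in c(1, 64)) {
    A <- sensitivity_map(enc, s, comp)
    expect_identical(dim(A), dim(s))
    expect_true(all(A >= 0))
    set.seed(comp)
    entries <- sample(length(s), 12)
    fd <- abs(oracle_fd_gradient(enc, s, comp, entries))
    expect_equal(A[entries], fd, tolerance = 1e-4)
  }
  expect_error(sensitivity_map(enc, s, 129), "component")
  expect_error(sensitivity_map(enc, s, 0), "component")
})

test_that("LRP conserves relevance layer-wise and matches a per-neuron loop oracle", {
  enc <- build_encoder(small_config(T_len = 16, seed = 24))
  s <- random_step(16, seed = 72)
  v <- encode_steps(enc, s)[1, ]
  # freshly built networks have zero biases: exact conservation at eps = 0
  for (comp in c(5, 100)) {
    A <- lrp_map(enc, s, comp, eps = 0)
    expect_equal(sum(A), v[comp], tolerance = 1e-6)
  }
  A <- lrp_map(enc, s, 9, eps = 1e-7)
  expect_equal(unname(A[, ]), oracle_lrp_map(enc, s, 9, 1e-7),
               tolerance = 1e-6)
  # biased network: the oracle still agrees (bias share absorbed)
  encb <- enc
  set.seed(1)
  for (nm in grep("\\.b$", names(encb$params), value = TRUE))
    encb$params[[nm]] <- rnorm(length(encb$params[[nm]]), 0, 0.05)
  expect_equal(unname(lrp_map(encb, s, 9, 1e-7)[, ]),
               oracle_lrp_map(encb, s, 9, 1e-7), tolerance = 1e-6)
})

test_that("component averaging is the element-wise mean over all 128 maps", {
  base <- matrix(1, 4, 28)
  same <- replicate(128, base * 3, simplify = FALSE)
  expect_equal(average_components(same), base * 3)
  ramp <- lapply(1:128, function(c) base * c)
  expect_true(all(abs(average_components(ramp) - 64.5) < 1e-12))
  set.seed(2)
  rnd <- replicate(128, matrix(rnorm(4 * 28), 4, 28), simplify = FALSE)
  loop <- matrix(0, 4, 28)
  for (m in rnd) loop <- loop + m / 128
  expect_equal(average_components(rnd), loop)
  expect_error(average_components(rnd[1:5]), "128")
})

test_that("the common map is the grand mean over training steps", {
  enc <- build_encoder(small_config(T_len = 16, seed = 25))
  s1 <- random_step(16, seed = 73)
  single <- common_map(list(s1), enc, method = "sa")
  expect_equal(unclass(single)[, ], attribution_map(enc, s1, "sa")[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  dup <- common_map(list(s1, s1), enc, method = "sa")
  expect_equal(unclass(dup)[, ], unclass(single)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  steps <- list(A = lapply(1:2, function(i) random_step(16, seed = 80 + i)),
                B = lapply(1:2, function(i) random_step(16, seed = 90 + i)),
                C = lapply(1:2, function(i) random_step(16, seed = 95 + i)))
  cm <- common_map(steps, enc, method = "lrp", eps = 1e-7)
  loop <- matrix(0, 16, 28)
  for (a in names(steps)) for (s in steps[[a]])
    loop <- loop + attribution_map(enc, s, "lrp", 1e-7) / 6
  expect_equal(unclass(cm)[, ], loop[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(cm, "n_steps"), 6)
  expect_error(common_map(list(), enc), "at least one")
})

test_that("occlusion plans order positions by |relevance| and split into quintiles", {
  map <- matrix(0, 10, 28)                    # L = 280 positions
  map[4, 7] <- 5; map[9, 2] <- -6             # magnitude sorting, signed map
  plan <- make_occlusion_plan(map)
  expect_equal(plan$L, 280)
  expect_equal(unname(plan$order[1, ]), c(9, 2))
  expect_equal(unname(plan$order[2, ]), c(4, 7))
  expect_equal(vapply(plan$quintiles, nrow, 1L),
               c(O1 = 56L, O2 = 56L, O3 = 56L, O4 = 56L, O5 = 56L))
  # all-equal relevances: row-major tie order
  flat <- make_occlusion_plan(matrix(1, 3, 28))
  expect_equal(unname(flat$order[1:3, ]),
               cbind(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(unname(flat$order[29, ]), c(2, 1))
  # non-divisible remainder joins the last quintile
  odd <- make_occlusion_plan(matrix(1, 3, 28))   # 84 = 5*16 + 4
  expect_equal(nrow(odd$quintiles$O5), 84 - 4 * 16)
})

test_that("occlusion zeroes exactly the listed positions and is idempotent", {
  s <- apply_pressure_floor(abs(random_step(12, seed = 74)), 0.01)
  expect_identical(occlude(s, matrix(integer(), 0, 2)), s)
  pos <- cbind(c(1, 5, 12), c(2, 17, 28))
  o <- occlude(s, pos)
  expect_true(all(o[pos] == 0))
  untouched <- s; untouched[pos] <- 0
  expect_identical(o, untouched)
  expect_identical(occlude(o, pos), o)
  all_pos <- as.matrix(expand.grid(1:12, 1:28))
  expect_true(all(occlude(s, all_pos) == 0))
  expect_error(occlude(s, cbind(13, 1)), "bounds")
})
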