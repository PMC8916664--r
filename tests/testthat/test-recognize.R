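test_that("splitting assigns every step to exactly one role with the stated counts", {
  ds <- tiny_dataset(n_subjects = 8, steps = 20, T_len = 16, seed = 41)
  spec <- split_spec(n_train = 4, n_known = 2, n_unknown = 2, n_shots = 5,
                     repetitions = 3, seed = 2)
  sp <- split_dataset(ds, spec, repetition = 1)
  expect_length(sp$training, 4)
  expect_equal(sum(vapply(sp$training, length, 1L)), 80)
  expect_equal(sum(vapply(sp$shots, length, 1L)), 10)
  expect_equal(sum(vapply(sp$known_test, length, 1L)), 2 * (20 - 5))
  expect_equal(sum(vapply(sp$unknown_test, length, 1L)), 40)
  groups <- c(sp$manifest$training, sp$manifest$known, sp$manifest$unknown)
  expect_setequal(groups, names(ds$steps))
  expect_length(unique(groups), 8)                 # disjoint

  sp2 <- split_dataset(ds, spec, repetition = 2)
  expect_false(identical(sp$manifest$training, sp2$manifest$training) &&
               identical(sp$manifest$shot_indices, sp2$manifest$shot_indices))
  expect_identical(split_dataset(ds, spec, 1)$manifest, sp$manifest)

  expect_error(split_dataset(ds, split_spec(10, 5, 5), 1), "subjects")
})

test_that("metric formulas and degenerate denominators behave as defined", {
  m <- metrics_report(TP = 8, FN = 2, TN = 9, FP = 1)
  expect_equal(m$TPR, 0.8); expect_equal(m$TNR, 0.9); expect_equal(m$ACC, 0.85)
  expect_warning(m2 <- metrics_report(5, 5, 0, 0), "TNR")
  expect_true(is.nan(m2$TNR))
})

make_toy_pipeline <- function(seed = 51) {
  ds <- tiny_dataset(n_subjects = 6, steps = 14, T_len = 16, seed = seed)
  spec <- split_spec(n_train = 2, n_known = 2, n_unknown = 2, n_shots = 4,
                     repetitions = 2, seed = 3)
  sp <- split_dataset(ds, spec, 1)
  cfg <- small_config(T_len = 16, seed = 13, epochs = 3, batch_size = 8)
  model <- train_gait_model(sp$training, cfg)
  list(ds = ds, spec = spec, sp = sp, model = model,
       recog = fit_recognizer(model$encoder, sp$shots, gamma = 2.2,
                              nu = 0.25))
}

test_that("recognition picks the nearest centroid and thresholds its OSVM score", {
  pl <- make_toy_pipeline()
  v <- encode_steps(pl$model$encoder, pl$sp$shots[[1]][[1]])[1, ]
  r <- recognize(v, pl$recog, tau = -0.1)
  expect_identical(r$subject, names(pl$sp$shots)[1])
  expect_true(r$accepted)
  # equidistant centroids tie-break to the smallest subject id
  fake <- pl$recog
  fake$centroids <- rbind(A2 = c(1, rep(0, 127)), A1 = c(1, rep(0, 127)))
  fake$centroids <- fake$centroids[order(rownames(fake$centroids)), ]
  fake$models <- list(A1 = pl$recog$models[[1]], A2 = pl$recog$models[[2]])
  r2 <- recognize(c(1, rep(0, 127)), fake, tau = -Inf)
  expect_identical(r2$subject, "A1")
  expect_error(recognize(v, structure(list(centroids = NULL), class = "x")))
})

test_that("raising tau never raises TPR and never lowers TNR", {
  pl <- make_toy_pipeline()
  taus <- c(-0.5, -0.1, -0.02, 0, 0.05)
  res <- lapply(taus, function(tau)
    evaluate_recognition(pl$model$encoder, pl$recog, pl$sp$known_test,
                         pl$sp$unknown_test, tau))
  tpr <- vapply(res, `[[`, 0, "TPR")
  tnr <- vapply(res, `[[`, 0, "TNR")
  expect_true(all(diff(tpr) <= 1e-12))
  expect_true(all(diff(tnr) >= -1e-12))
  # extreme threshold rejects everything
  all_rej <- evaluate_recognition(pl$model$encoder, pl$recog,
                                  pl$sp$known_test, pl$sp$unknown_test,
                                  tau = 2)
  expect_equal(all_rej$TPR, 0); expect_equal(all_rej$TNR, 1)
})

test_that("the repeated protocol aggregates per-repetition metrics", {
  ds <- tiny_dataset(n_subjects = 6, steps = 14, T_len = 16, seed = 52)
  spec <- split_spec(n_train = 2, n_known = 2, n_unknown = 2, n_shots = 4,
                     repetitions = 2, seed = 4)
  cfg <- small_config(T_len = 16, seed = 14, epochs = 2, batch_size = 8)
  res <- run_protocol(ds, spec, cfg, gamma = 2.2, nu = 0.25, tau = -0.1,
                      keep_first_pipeline = TRUE)
  expect_equal(nrow(res$per_repetition), 2)
  expect_equal(res$mean[["ACC"]], mean(res$per_repetition$ACC))
  expect_named(res$pipeline, c("model", "recognizer", "split", "tau"))
  res2 <- run_protocol(ds, spec, cfg, gamma = 2.2, nu = 0.25, tau = -0.1)
  expect_identical(res$per_repetition, res2$per_repetition)
})
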