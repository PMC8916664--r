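#' Split specification for the repeated open-set protocol
#'
#' Subjects are partitioned into a training group (all steps train the
#' encoder), a known group (n shot steps per subject fit the recognizer,
#' the rest form the known test set) and an unknown group (all steps form
#' the unknown test set).
#'
#' @param n_train,n_known,n_unknown subject counts per group
#'   (default 20/10/10).
#' @param n_shots shots per known subject (default 10).
#' @param repetitions number of repeated random splits (default 10).
#' @param seed base seed; each repetition derives its own stream.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(n_train = 20, n_known = 10, n_unknown = 10,
                       n_shots = 10, repetitions = 10, seed = 1) {
  stopifnot(n_train >= 2, n_known >= 1, n_unknown >= 0, n_shots >= 1,
            repetitions >= 1)
  structure(list(n_train = as.integer(n_train), n_known = as.integer(n_known),
                 n_unknown = as.integer(n_unknown),
                 n_shots = as.integer(n_shots),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Randomly split a dataset into training / shot / known-test / unknown-test
#'
#' @param dataset a `gait_dataset` (or any list with a `steps` element:
#'   subject id -> list of unit steps).
#' @param spec a [split_spec()].
#' @param repetition repetition index (>= 1); determines the random stream
#'   together with `spec$seed`.
#' @return List with `training` (subject -> steps), `shots`
#'   (known subject -> n steps), `known_test`, `unknown_test`, and a
#'   `manifest` recording group memberships and shot indices.
#' @export
split_dataset <- function(dataset, spec = split_spec(), repetition = 1) {
  steps <- dataset$steps
  ids <- names(steps)
  need <- spec$n_train + spec$n_known + spec$n_unknown
  if (length(ids) < need)
    stop("dataset has ", length(ids), " subjects but the split needs ", need,
         call. = FALSE)
  if (any(vapply(steps, length, 1L)[seq_len(length(ids))] <= spec$n_shots))
    stop("every subject needs more than n_shots = ", spec$n_shots, " steps",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed((spec$seed * 10007L + as.integer(repetition)) %% .Machine$integer.max)
  perm <- sample(ids, need)
  g_train   <- sort(perm[seq_len(spec$n_train)])
  g_known   <- sort(perm[spec$n_train + seq_len(spec$n_known)])
  g_unknown <- sort(perm[spec$n_train + spec$n_known + seq_len(spec$n_unknown)])
  shots <- list(); known_test <- list()
  shot_idx <- list()
  for (a in g_known) {
    idx <- sample.int(length(steps[[a]]), spec$n_shots)
    shot_idx[[a]] <- sort(idx)
    shots[[a]] <- steps[[a]][sort(idx)]
    known_test[[a]] <- steps[[a]][-idx]
  }
  list(training = steps[g_train],
       shots = shots,
       known_test = known_test,
       unknown_test = steps[g_unknown],
       manifest = list(repetition = repetition, training = g_train,
                       known = g_known, unknown = g_unknown,
                       shot_indices = shot_idx, n_shots = spec$n_shots))
}

#' Fit the few-shot recognizer (centroids + one-class SVMs) from shots
#'
#' @param enc trained `gait_encoder`.
#' @param shots named list: known subject id -> list of n shot unit steps.
#' @param gamma,nu one-class SVM hyper-parameters (defaults 2.2 / 0.06).
#' @return List of class `gait_recognizer` with `centroids` (matrix with
#'   one row per known subject, sorted by id), `models` (named list of
#'   `osvm_model`), `gamma`, `nu`.
#' @export
fit_recognizer <- function(enc, shots, gamma = 2.2, nu = 0.06) {
  if (length(shots) == 0L)
    stop("empty known set: no subjects to recognize", call. = FALSE)
  ids <- sort(names(shots))
  emb <- lapply(shots[ids], function(ss) encode_steps(enc, ss))
  centroids <- do.call(rbind, lapply(emb, compute_centroid))
  rownames(centroids) <- ids
  models <- lapply(emb, fit_osvm, gamma = gamma, nu = nu)
  structure(list(centroids = centroids, models = models, gamma = gamma,
                 nu = nu),
            class = "gait_recognizer")
}

#' Recognize a single embedded query
#'
#' The provisional subject is the nearest centroid in squared Euclidean
#' distance (ties broken toward the smallest subject id); the query is
#' accepted iff the provisional subject's one-class SVM decision value is
#' at least `tau`. Only the provisional subject's model is evaluated.
#'
#' @param v query embedding (length 128).
#' @param recognizer a `gait_recognizer`.
#' @param tau acceptance threshold (default -0.1).
#' @return List: `subject` (provisional id), `h` (decision value),
#'   `accepted` (`h >= tau`), `tau`.
#' @export
recognize <- function(v, recognizer, tau = -0.1) {
  d2 <- colSums((t(recognizer$centroids) - v)^2)
  p <- rownames(recognizer$centroids)[which.min(d2)]  # rows sorted by id
  h <- decision_value(recognizer$models[[p]], v)
  list(subject = p, h = h, accepted = h >= tau, tau = tau)
}

# vectorized recognition of an m x 128 embedding matrix
.recognize_batch <- function(V, recognizer, tau) {
  cents <- recognizer$centroids
  d2 <- outer(rowSums(V^2), rowSums(cents^2), "+") - 2 * tcrossprod(V, cents)
  pi <- max.col(-d2, ties.method = "first")           # smallest id on ties
  p <- rownames(cents)[pi]
  h <- numeric(nrow(V))
  for (a in unique(p)) {
    sel <- p == a
    h[sel] <- decision_value(recognizer$models[[a]],
                             V[sel, , drop = FALSE])
  }
  data.frame(subject = p, h = h, accepted = h >= tau)
}

#' Metrics from open-set confusion counts
#'
#' @param TP,FN,TN,FP confusion counts: a known-test step is TP only when
#'   accepted as its true subject (misidentification and rejection both
#'   count FN); an unknown-test step is TN when rejected, FP when accepted
#'   as any subject.
#' @return Data frame row with counts, TPR, TNR and ACC. Degenerate
#'   denominators give `NaN` with a warning.
#' @export
metrics_report <- function(TP, FN, TN, FP) {
  if (TP + FN == 0) warning("no known-test steps: TPR is NaN")
  if (TN + FP == 0) warning("no unknown-test steps: TNR is NaN")
  data.frame(TP = TP, FN = FN, TN = TN, FP = FP,
             TPR = TP / (TP + FN), TNR = TN / (TN + FP),
             ACC = (TP + TN) / (TP + FN + TN + FP))
}

#' Evaluate a trained pipeline on known and unknown test sets
#'
#' @param enc trained `gait_encoder`.
#' @param recognizer a `gait_recognizer`.
#' @param known_test named list: true subject id -> list of unit steps.
#' @param unknown_test named list: subject id -> list of unit steps.
#' @param tau acceptance threshold.
#' @return One-row data frame of counts and TPR/TNR/ACC.
#' @export
evaluate_recognition <- function(enc, recognizer, known_test, unknown_test,
                                 tau = -0.1) {
  TP <- 0L; FN <- 0L; TN <- 0L; FP <- 0L
  for (a in names(known_test)) {
    V <- encode_steps(enc, known_test[[a]])
    r <- .recognize_batch(V, recognizer, tau)
    ok <- r$accepted & r$subject == a
    TP <- TP + sum(ok); FN <- FN + sum(!ok)
  }
  for (a in names(unknown_test)) {
    V <- encode_steps(enc, unknown_test[[a]])
    r <- .recognize_batch(V, recognizer, tau)
    TN <- TN + sum(!r$accepted); FP <- FP + sum(r$accepted)
  }
  metrics_report(TP, FN, TN, FP)
}

#' Run the full repeated open-set recognition protocol
#'
#' For each repetition: split the dataset, train the encoder-decoder on the
#' training group, fit the few-shot recognizer on the shots, and evaluate
#' on the known/unknown test sets. Deterministic given the seeds in `spec`
#' and `config`.
#'
#' @param dataset a `gait_dataset`.
#' @param spec a [split_spec()].
#' @param config an [encoder_config()]; each repetition trains with seed
#'   `config$seed + repetition`.
#' @param gamma,nu,tau recognizer hyper-parameters
#'   (defaults 2.2 / 0.06 / -0.1).
#' @param retrain if `FALSE`, the encoder trained on the first repetition's
#'   training group is reused for later repetitions (cheaper, but test
#'   groups are then not disjoint from the encoder's training subjects).
#' @param keep_first_pipeline return the first repetition's trained
#'   encoder, recognizer and split (for downstream attribution analysis).
#' @param verbose print progress.
#' @return List of class `protocol_result`: `per_repetition` (data frame),
#'   `mean` (named numeric: TPR, TNR, ACC), and optionally `pipeline`.
#' @export
run_protocol <- function(dataset, spec = split_spec(),
                         config = encoder_config(), gamma = 2.2, nu = 0.06,
                         tau = -0.1, retrain = TRUE,
                         keep_first_pipeline = FALSE, verbose = FALSE) {
  per <- NULL
  pipeline <- NULL
  model <- NULL
  for (rep_i in seq_len(spec$repetitions)) {
    sp <- split_dataset(dataset, spec, rep_i)
    if (retrain || is.null(model)) {
      cfg <- config
      cfg$seed <- (config$seed + rep_i) %% .Machine$integer.max
      model <- train_gait_model(sp$training, cfg)
    }
    recog <- fit_recognizer(model$encoder, sp$shots, gamma, nu)
    m <- evaluate_recognition(model$encoder, recog, sp$known_test,
                              sp$unknown_test, tau)
    m <- cbind(repetition = rep_i, m)
    per <- rbind(per, m)
    if (rep_i == 1L && keep_first_pipeline)
      pipeline <- list(model = model, recognizer = recog, split = sp,
                       tau = tau)
    if (verbose)
      message(sprintf("repetition %d: TPR %.3f TNR %.3f ACC %.3f",
                      rep_i, m$TPR, m$TNR, m$ACC))
  }
  structure(list(per_repetition = per,
                 mean = c(TPR = mean(per$TPR), TNR = mean(per$TNR),
                          ACC = mean(per$ACC)),
                 pipeline = pipeline),
            class = "protocol_result")
}
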