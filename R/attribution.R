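# --- gradient (SA) and relevance (LRP-epsilon) attribution ------------------

# forward a single step replicated n_comp times so batched backward /
# relevance passes can treat output components as the batch dimension
.replicated_cache <- function(enc, step, n_comp) {
  X <- array(0, c(n_comp, nrow(step), ncol(step)))
  for (i in seq_len(n_comp)) X[i, , ] <- step
  encoder_forward(enc, X, keep_cache = TRUE)
}

#' Sensitivity-analysis attribution map
#'
#' The absolute gradient of one embedding component with respect to every
#' input entry: `(A_c)_{tj} = |d f(s)_c / d s_{tj}|`, computed by
#' back-propagation through the whole encoder including the final L2
#' normalization. SA maps are element-wise non-negative.
#'
#' @param enc a `gait_encoder`.
#' @param step T x 28 unit step.
#' @param comp output component index in 1..128.
#' @return T x 28 non-negative matrix.
#' @export
sensitivity_map <- function(enc, step, comp) {
  if (comp < 1 || comp > enc$config$embed_dim)
    stop("component index must be in [1, ", enc$config$embed_dim, "]",
         call. = FALSE)
  fwd <- encoder_forward(enc, step, keep_cache = TRUE)
  dV <- matrix(0, 1, enc$config$embed_dim)
  dV[1, comp] <- 1
  bk <- encoder_backward(enc, fwd$cache, dV, need_dX = TRUE,
                         need_grads = FALSE)
  A <- abs(bk$dX[1, , ])
  dim(A) <- dim(step)
  colnames(A) <- modality_layout()$channels
  A
}

# all 128 SA component maps at once: returns (T, 28, 128) array of |grad|
.sensitivity_all <- function(enc, step) {
  nc <- enc$config$embed_dim
  fwd <- .replicated_cache(enc, step, nc)
  bk <- encoder_backward(enc, fwd$cache, diag(nc), need_dX = TRUE,
                         need_grads = FALSE)
  aperm(abs(bk$dX), c(2, 3, 1))
}

# stabilized denominator: z + eps * sign(z) (sign(0) treated as +1)
.lrp_stab <- function(z, eps) {
  if (eps == 0 && any(z == 0))
    stop("LRP denominator is exactly zero; use a positive epsilon",
         call. = FALSE)
  z + eps * ifelse(z >= 0, 1, -1)
}

# LRP-epsilon through a dense layer: R, z (pre-activation) and x (input
# activation) all batched over components (rows = components)
.lrp_dense <- function(R, z, x, W, eps) {
  (R / .lrp_stab(z, eps)) %*% t(W) * x
}

# LRP-epsilon through a conv layer in the (n_comp*T, C) row layout:
# R/z are (nc*T_out, C_out), x is (nc*T_in, C_in), all replicated per
# component by the batched forward pass
.lrp_conv <- function(R, z, x, W, g, nc, C_in, eps) {
  S <- R / .lrp_stab(z, eps)
  conv_backward_input(S, W, g, nc, C_in) * x   # x_i * sum_j w_ij S_j
}

# full LRP pass on a cache built by .replicated_cache; R0 is the relevance
# at the pre-normalization dense-128 layer, one row per propagated
# component. Returns (n_comp, T, 28).
.lrp_propagate <- function(enc, cache, R0, eps) {
  p <- enc$params; gs <- enc$geoms
  lay <- modality_layout()
  R <- .lrp_dense(R0, cache$z_d2, cache$h1, p$dense2.W, eps)
  R <- .lrp_dense(R, cache$z_d1, cache$Zc, p$dense1.W, eps)
  nc <- nrow(R0)
  out <- array(0, c(nc, enc$config$T_len, 28L))
  ch <- .mod_channels(); mods <- names(ch)
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    cm <- cache[[m]]
    Rm <- R[, (mi - 1L) * enc$flat_per_mod + seq_len(enc$flat_per_mod),
            drop = FALSE]
    dim(Rm) <- c(nc * gs$g3$T_out, enc$config$filters[3])
    Rm <- .lrp_conv(Rm, cm$z3, cm$a2, p[[paste0(m, ".conv3.W")]], gs$g3,
                    nc, enc$config$filters[2], eps)
    Rm <- .lrp_conv(Rm, cm$z2, cm$a1, p[[paste0(m, ".conv2.W")]], gs$g2,
                    nc, enc$config$filters[1], eps)
    Rm <- .lrp_conv(Rm, cm$z1, cm$Xm, p[[paste0(m, ".conv1.W")]], gs$g1,
                    nc, ch[[m]], eps)
    dim(Rm) <- c(nc, enc$config$T_len, ch[[m]])
    out[, , lay[[m]]] <- Rm
  }
  out
}

#' LRP-epsilon attribution map for one embedding component
#'
#' Relevance is initialized one-hot at component `comp` of the
#' (pre-normalization) 128-unit output layer with the component's output
#' value, then redistributed layer by layer: neuron i in layer h-1 receives
#' `x_i w_ij / (sum_i x_i w_ij + eps * sign(.))` of neuron j's relevance,
#' with convolutions treated as their equivalent sparse dense connections.
#' Bias terms enter the denominator (their relevance share is absorbed).
#' The final L2 normalization is not a weighted layer and is bypassed.
#'
#' @param enc a `gait_encoder`.
#' @param step T x 28 unit step.
#' @param comp output component index in 1..128.
#' @param eps stabilizer added to each denominator (default 1e-7).
#' @return T x 28 signed relevance matrix.
#' @export
lrp_map <- function(enc, step, comp, eps = 1e-7) {
  if (comp < 1 || comp > enc$config$embed_dim)
    stop("component index must be in [1, ", enc$config$embed_dim, "]",
         call. = FALSE)
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  fwd <- encoder_forward(enc, step, keep_cache = TRUE)
  R0 <- matrix(0, 1, enc$config$embed_dim)
  R0[1, comp] <- fwd$V[1, comp]
  A <- .lrp_propagate(enc, fwd$cache, R0, eps)[1, , ]
  dim(A) <- dim(step)
  colnames(A) <- modality_layout()$channels
  A
}

# all 128 LRP component maps: (T, 28, 128)
.lrp_all <- function(enc, step, eps) {
  nc <- enc$config$embed_dim
  fwd <- .replicated_cache(enc, step, nc)
  R0 <- diag(fwd$V[1, ])
  aperm(.lrp_propagate(enc, fwd$cache, R0, eps), c(2, 3, 1))
}

#' Average attribution maps over all 128 embedding components
#'
#' @param maps list of exactly 128 T x 28 maps (one per component), or a
#'   (T, 28, 128) array.
#' @return T x 28 element-wise mean map.
#' @export
average_components <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3L) {
    if (dim(maps)[3] != 128L)
      stop("expected 128 component maps, got ", dim(maps)[3], call. = FALSE)
    return(apply(maps, c(1, 2), mean))
  }
  if (length(maps) != 128L)
    stop("expected 128 component maps, got ", length(maps), call. = FALSE)
  Reduce(`+`, maps) / length(maps)
}

#' Component-averaged attribution map of one unit step
#'
#' `A(s)`: the mean over the 128 per-component maps, using either
#' sensitivity analysis (`"sa"`) or LRP-epsilon (`"lrp"`).
#'
#' @param enc a `gait_encoder`.
#' @param step T x 28 unit step.
#' @param method `"sa"` or `"lrp"`.
#' @param eps LRP stabilizer.
#' @return T x 28 map (non-negative for SA, signed for LRP).
#' @export
attribution_map <- function(enc, step, method = c("sa", "lrp"), eps = 1e-7) {
  method <- match.arg(method)
  maps <- if (method == "sa") .sensitivity_all(enc, step)
          else .lrp_all(enc, step, eps)
  A <- average_components(maps)
  colnames(A) <- modality_layout()$channels
  A
}

#' Common attribution map over a set of training unit steps
#'
#' The grand mean of the component-averaged maps `A(s)` over all supplied
#' unit steps of all subjects, each step weighted equally.
#'
#' @param steps named list (subject -> list of unit steps) or flat list of
#'   unit steps.
#' @param enc a `gait_encoder`.
#' @param method `"sa"` or `"lrp"`.
#' @param eps LRP stabilizer.
#' @return T x 28 matrix of class `common_attribution_map` with attributes
#'   `method`, `eps`, `n_steps`, `n_subjects`.
#' @export
common_map <- function(steps, enc, method = c("sa", "lrp"), eps = 1e-7) {
  method <- match.arg(method)
  nested <- is.list(steps) && length(steps) > 0 && is.list(steps[[1L]])
  flat <- if (nested) unlist(steps, recursive = FALSE) else steps
  if (length(flat) == 0L)
    stop("need at least one unit step", call. = FALSE)
  acc <- NULL
  for (s in flat) {
    A <- attribution_map(enc, s, method, eps)
    acc <- if (is.null(acc)) A else acc + A
  }
  structure(acc / length(flat),
            class = c("common_attribution_map", "matrix", "array"),
            method = method, eps = if (method == "lrp") eps else NA_real_,
            n_steps = length(flat),
            n_subjects = if (nested) length(steps) else NA_integer_)
}

# --- region perturbation -----------------------------------------------------

#' Order map positions by relevance magnitude and split into quintiles
#'
#' Positions of the T x 28 map are sorted by `|relevance|` descending
#' (ties in row-major order, i.e. by time stamp then channel) giving the
#' occlusion sequence O; O is split into five equal sub-sequences O1..O5
#' (any remainder joins O5), so O1 holds the top 20% most relevant
#' positions.
#'
#' @param map T x 28 attribution map (typically a common map).
#' @return List of class `occlusion_plan`: `order` (L x 2 matrix of
#'   row/col indices, most relevant first), `quintiles` (list O1..O5 of
#'   index matrices), `L`.
#' @export
make_occlusion_plan <- function(map) {
  Tn <- nrow(map); Cn <- ncol(map)
  L <- Tn * Cn
  rows <- rep(seq_len(Tn), each = Cn)      # row-major enumeration
  cols <- rep(seq_len(Cn), times = Tn)
  mag <- abs(map[cbind(rows, cols)])
  o <- order(-mag)                         # stable: ties keep row-major order
  ord <- cbind(row = rows[o], col = cols[o])
  per <- L %/% 5L
  quint <- lapply(1:5, function(k) {
    from <- (k - 1L) * per + 1L
    to <- if (k == 5L) L else k * per
    ord[from:to, , drop = FALSE]
  })
  names(quint) <- paste0("O", 1:5)
  structure(list(order = ord, quintiles = quint, L = L),
            class = "occlusion_plan")
}

#' Occlude positions of a unit step
#'
#' Listed entries are set to exactly 0 -- distinguishable from live
#' pressure, which is at least the pressure floor delta. Idempotent.
#'
#' @param step T x 28 unit step.
#' @param positions m x 2 matrix of (row, col) indices.
#' @return The occluded step.
#' @export
occlude <- function(step, positions) {
  if (length(positions) == 0L || nrow(positions) == 0L) return(step)
  if (any(positions[, 1] < 1 | positions[, 1] > nrow(step) |
          positions[, 2] < 1 | positions[, 2] > ncol(step)))
    stop("occlusion position out of bounds", call. = FALSE)
  step[positions] <- 0
  step
}

# evaluate with every test step occluded by a fixed position set, or by a
# fresh random draw of `n_random` positions per step when positions = NULL
.evaluate_occluded <- function(enc, recognizer, known_test, unknown_test,
                               tau, positions = NULL, n_random = 0L) {
  occ <- function(s) {
    if (!is.null(positions)) return(occlude(s, positions))
    L <- length(s)
    idx <- sample.int(L, n_random)
    pos <- cbind(((idx - 1L) %% nrow(s)) + 1L, ((idx - 1L) %/% nrow(s)) + 1L)
    occlude(s, pos)
  }
  evaluate_recognition(enc, recognizer,
                       lapply(known_test, function(ss) lapply(ss, occ)),
                       lapply(unknown_test, function(ss) lapply(ss, occ)),
                       tau)
}

#' Region-perturbation curve for an occlusion plan
#'
#' For each quintile O1..O5 of the plan, every known-test and unknown-test
#' step is occluded at those positions and re-evaluated end to end with
#' the encoder, centroids and one-class SVMs held fixed. A random baseline
#' occludes the same number of positions, drawn uniformly and freshly for
#' every step (seeded).
#'
#' @param plan an [make_occlusion_plan()] result.
#' @param enc trained `gait_encoder`.
#' @param recognizer fitted `gait_recognizer`.
#' @param known_test,unknown_test named lists of test unit steps.
#' @param tau acceptance threshold.
#' @param seed seed for the random baseline.
#' @return Data frame with 6 rows (O1..O5 and `random`): subset, occluded
#'   position count, TPR, TNR, ACC and a baseline flag.
#' @export
perturbation_curve <- function(plan, enc, recognizer, known_test,
                               unknown_test, tau = -0.1, seed = 1) {
  out <- NULL
  for (k in 1:5) {
    m <- .evaluate_occluded(enc, recognizer, known_test, unknown_test, tau,
                            positions = plan$quintiles[[k]])
    out <- rbind(out, data.frame(subset = paste0("O", k),
                                 n_occluded = nrow(plan$quintiles[[k]]),
                                 TPR = m$TPR, TNR = m$TNR, ACC = m$ACC,
                                 baseline = FALSE))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nr <- nrow(plan$quintiles[[1L]])
  m <- .evaluate_occluded(enc, recognizer, known_test, unknown_test, tau,
                          positions = NULL, n_random = nr)
  rbind(out, data.frame(subset = "random", n_occluded = nr, TPR = m$TPR,
                        TNR = m$TNR, ACC = m$ACC, baseline = TRUE))
}
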