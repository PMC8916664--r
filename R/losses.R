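#' Multimodal triplet loss
#'
#' `max(0, ||v_a - v_p||^2 - ||v_a - v_n||^2 + alpha)`: pulls two
#' embeddings of the same subject together and pushes an embedding of a
#' different subject away by at least the margin `alpha`. The hinge at zero
#' follows the standard metric-learning formulation.
#'
#' @param v_anchor,v_pos,v_neg unit-norm embedding vectors; anchor and
#'   positive from one subject, negative from another.
#' @param alpha non-negative margin (default 1.25).
#' @return Non-negative scalar.
#' @export
triplet_loss <- function(v_anchor, v_pos, v_neg, alpha = 1.25) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  max(0, sum((v_anchor - v_pos)^2) - sum((v_anchor - v_neg)^2) + alpha)
}

#' Prototype reconstruction loss
#'
#' Mean over the 28 channel-modalities of the squared L2 distance between
#' the decoded reconstruction of a unit step and the subject's prototype,
#' both normalized to unit L2 norm per channel (length-T vectors) before
#' differencing. Bounded in `[0, 4]`.
#'
#' @param step T x 28 unit-step matrix.
#' @param prototype T x 28 prototype of the step's subject (training-split
#'   prototype).
#' @param enc,dec trained (or untrained) `gait_encoder` / `gait_decoder`.
#' @return Non-negative scalar.
#' @export
prototype_loss <- function(step, prototype, enc, dec) {
  v <- encode_steps(enc, step)
  recon <- decode_embedding(dec, v[1, ], normalize = TRUE)
  proto_blocks <- split_modalities(prototype)
  tot <- 0
  for (m in names(recon)) {
    cn <- normalize_channels(proto_blocks[[m]])
    tot <- tot + sum((recon[[m]] - cn)^2)
  }
  tot / 28
}

#' Combined training loss
#'
#' `L = L_triplet + lambda * L_proto`.
#'
#' @param triplet_term triplet-loss value.
#' @param proto_term prototype-loss value.
#' @param lambda non-negative weight (default 1.0).
#' @return Scalar.
#' @export
combined_loss <- function(triplet_term, proto_term, lambda = 1.0) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  triplet_term + lambda * proto_term
}

# loss + gradient of the per-channel-normalized squared distance, batched:
# R raw reconstructions and Cn normalized prototype channels, both (B*T, k)
# with row index b + B*(t-1). Returns the sum over samples/channels of
# ||u - c||^2 and dLoss/dR (not yet divided by |M| or batch size).
.proto_block_loss_grad <- function(R, Cn, B) {
  Tn <- nrow(R) / B
  gb <- rep.int(seq_len(B), Tn)                      # sample id per row
  nrm <- sqrt(rowsum(R^2, gb, reorder = FALSE))      # (B, k) channel norms
  nrm <- pmax(nrm, 1e-12)
  U <- R / nrm[gb, , drop = FALSE]
  D <- U - Cn
  loss <- sum(D^2)
  dot <- rowsum(D * U, gb, reorder = FALSE)          # <d, u> per (B, k)
  dR <- 2 * (D - U * dot[gb, , drop = FALSE]) / nrm[gb, , drop = FALSE]
  list(loss = loss, dR = dR)
}

#' Train the prototyping encoder-decoder
#'
#' Mini-batch Adam training of the combined triplet + prototype loss.
#' Each batch samples `batch_size` anchors; positives are a different step
#' of the anchor's subject, negatives a random step of a random other
#' subject. Per-subject prototypes are computed once from the training
#' split. Deterministic given `config$seed`.
#'
#' @param steps named list: subject id -> list of T x 28 unit steps
#'   (training split). Needs >= 2 subjects and >= 2 steps per subject.
#' @param config an [encoder_config()].
#' @param verbose print per-epoch losses.
#' @return List of class `gait_model`: `encoder`, `decoder`, `history`
#'   (data.frame epoch/triplet/proto/total), `config`.
#' @export
train_gait_model <- function(steps, config = encoder_config(),
                             verbose = FALSE) {
  if (!is.list(steps) || length(steps) < 2L)
    stop("training split needs at least 2 subjects to form triplets",
         call. = FALSE)
  if (any(vapply(steps, length, 1L) < 2L))
    stop("each training subject needs >= 2 unit steps", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  enc <- build_encoder(config)
  dec <- build_decoder(config)
  lay <- modality_layout()
  subjects <- names(steps)
  n_steps <- vapply(steps, length, 1L)
  # normalized per-channel prototypes, stacked as (T, 28) per subject
  protos <- lapply(steps, function(ss) {
    pr <- compute_prototype(ss)
    cbind(normalize_channels(pr[, lay$pre, drop = FALSE]),
          normalize_channels(pr[, lay$acc, drop = FALSE]),
          normalize_channels(pr[, lay$rot, drop = FALSE]))
  })
  anchors <- do.call(rbind, lapply(seq_along(subjects), function(si)
    cbind(si, seq_len(n_steps[si]))))
  n_anchor <- nrow(anchors)
  bs <- config$batch_size
  opt_e <- adam_init(enc$params)
  opt_d <- adam_init(dec$params)
  hist <- data.frame(epoch = integer(), triplet = numeric(),
                     proto = numeric(), total = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_anchor)
    ep_tri <- 0; ep_pro <- 0; nb <- 0L
    for (start in seq(1L, n_anchor, by = bs)) {
      idx <- ord[start:min(n_anchor, start + bs - 1L)]
      B <- length(idx)
      a_si <- anchors[idx, 1L]; a_st <- anchors[idx, 2L]
      p_st <- vapply(seq_len(B), function(i) {
        cand <- seq_len(n_steps[a_si[i]])[-a_st[i]]
        cand[sample.int(length(cand), 1L)]
      }, 1L)
      n_si <- vapply(a_si, function(s) {
        cand <- seq_along(subjects)[-s]
        cand[sample.int(length(cand), 1L)]
      }, 1L)
      n_st <- vapply(n_si, function(s) sample.int(n_steps[s], 1L), 1L)
      X <- array(0, c(3L * B, config$T_len, 28L))
      for (i in seq_len(B)) {
        X[i, , ]          <- steps[[a_si[i]]][[a_st[i]]]
        X[B + i, , ]      <- steps[[a_si[i]]][[p_st[i]]]
        X[2L * B + i, , ] <- steps[[n_si[i]]][[n_st[i]]]
      }
      fwd <- encoder_forward(enc, X, keep_cache = TRUE)
      V <- fwd$V
      Va <- V[seq_len(B), , drop = FALSE]
      Vp <- V[B + seq_len(B), , drop = FALSE]
      Vn <- V[2L * B + seq_len(B), , drop = FALSE]
      d_ap <- rowSums((Va - Vp)^2)
      d_an <- rowSums((Va - Vn)^2)
      lt <- d_ap - d_an + config$alpha
      active <- lt > 0
      tri <- sum(pmax(lt, 0)) / B
      dV <- matrix(0, 3L * B, config$embed_dim)
      if (any(active)) {
        w <- as.numeric(active) * (2 / B)
        dV[seq_len(B), ]          <- w * (Vn - Vp)
        dV[B + seq_len(B), ]      <- w * (Vp - Va)
        dV[2L * B + seq_len(B), ] <- w * (Va - Vn)
      }
      # prototype term on the anchors
      pro <- 0
      if (config$lambda > 0) {
        dfwd <- decoder_forward(dec, Va, keep_cache = TRUE)
        dOut <- list()
        scl <- config$lambda / (28 * B)
        for (m in names(dfwd$out)) {
          cols_m <- lay[[m]]
          Cn <- array(0, c(B, config$T_len, length(cols_m)))
          for (i in seq_len(B))
            Cn[i, , ] <- protos[[a_si[i]]][, cols_m]
          dim(Cn) <- dim(dfwd$out[[m]])
          lg <- .proto_block_loss_grad(dfwd$out[[m]], Cn, B)
          pro <- pro + lg$loss
          dOut[[m]] <- lg$dR * scl
        }
        pro <- pro / (28 * B)
        dbk <- decoder_backward(dec, dfwd$cache, dOut)
        dV[seq_len(B), ] <- dV[seq_len(B), ] + dbk$dV
        up_d <- adam_step(dec$params, dbk$grads, opt_d, config$lr)
        dec$params <- up_d$params; opt_d <- up_d$state
      }
      ebk <- encoder_backward(enc, fwd$cache, dV)
      up_e <- adam_step(enc$params, ebk$grads, opt_e, config$lr)
      enc$params <- up_e$params; opt_e <- up_e$state
      ep_tri <- ep_tri + tri; ep_pro <- ep_pro + pro; nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, triplet = ep_tri / nb, proto = ep_pro / nb,
                      total = combined_loss(ep_tri / nb, ep_pro / nb,
                                            config$lambda))
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %d: triplet %.4f proto %.4f total %.4f",
                      ep, row$triplet, row$proto, row$total))
  }
  structure(list(encoder = enc, decoder = dec, history = hist,
                 config = config),
            class = "gait_model")
}
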