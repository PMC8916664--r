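#' Encoder-decoder configuration
#'
#' The encoder runs three parallel sub-encoders (one per sensing modality:
#' pressure, acceleration, rotation), each a stack of three 1D convolutions
#' with 32, 64 and 128 filters, whose flattened outputs are concatenated and
#' passed through dense layers of 256 and 128 units; the 128-unit output is
#' L2-normalized to give the embedding. The decoder mirrors this: a 256-unit
#' dense layer followed by three sub-decoders of transposed convolutions
#' (128, 64 filters and a final stride-2 projection to the modality's
#' channel count).
#'
#' @param T_len unit-step length in rows (default 100).
#' @param alpha triplet-loss margin (default 1.25).
#' @param lambda weight of the prototype loss in the combined loss
#'   (default 1.0).
#' @param kernel convolution kernel size (default 5).
#' @param strides per-layer convolution strides (default `c(2, 2, 2)`,
#'   halving the time axis at each stage).
#' @param lr Adam learning rate.
#' @param epochs training epochs; one epoch is a full pass over the
#'   training anchors.
#' @param batch_size triplets per mini-batch.
#' @param seed integer seed for weight initialization and triplet sampling.
#' @return List of class `encoder_config`. Filter counts (32, 64, 128),
#'   dense widths (256, 128) and the 128-dimensional embedding are fixed
#'   architectural constants.
#' @export
encoder_config <- function(T_len = 100, alpha = 1.25, lambda = 1.0,
                           kernel = 5, strides = c(2, 2, 2), lr = 1e-3,
                           epochs = 2, batch_size = 64, seed = 1) {
  stopifnot(T_len >= 8, alpha >= 0, lambda >= 0, kernel >= 1,
            length(strides) == 3, all(strides >= 1), epochs >= 1,
            batch_size >= 1)
  structure(list(T_len = as.integer(T_len), filters = c(32L, 64L, 128L),
                 dense = c(256L, 128L), embed_dim = 128L,
                 kernel = as.integer(kernel), strides = as.integer(strides),
                 alpha = alpha, lambda = lambda, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

# per-modality channel counts, in block order
.mod_channels <- function() c(pre = 16L, acc = 6L, rot = 6L)

# conv geometries shared by the three sub-encoders (time axis is common)
.enc_geoms <- function(config) {
  k <- config$kernel; s <- config$strides
  g1 <- conv_geom(config$T_len, k, s[1])
  g2 <- conv_geom(g1$T_out, k, s[2])
  g3 <- conv_geom(g2$T_out, k, s[3])
  list(g1 = g1, g2 = g2, g3 = g3)
}

#' Build an (untrained) multimodal encoder
#'
#' @param config an [encoder_config()].
#' @return List of class `gait_encoder` with the flat parameter list, the
#'   conv geometries and the config. Use [encode_steps()] to map unit steps
#'   to embeddings.
#' @export
build_encoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  gs <- .enc_geoms(config)
  fl <- config$filters; k <- config$kernel
  ch <- .mod_channels()
  params <- list()
  for (m in names(ch)) {
    cin <- ch[[m]]
    params[[paste0(m, ".conv1.W")]] <- he_init(k * cin, fl[1], k * cin)
    params[[paste0(m, ".conv1.b")]] <- numeric(fl[1])
    params[[paste0(m, ".conv2.W")]] <- he_init(k * fl[1], fl[2], k * fl[1])
    params[[paste0(m, ".conv2.b")]] <- numeric(fl[2])
    params[[paste0(m, ".conv3.W")]] <- he_init(k * fl[2], fl[3], k * fl[2])
    params[[paste0(m, ".conv3.b")]] <- numeric(fl[3])
  }
  flat <- gs$g3$T_out * fl[3]
  params[["dense1.W"]] <- he_init(3L * flat, config$dense[1], 3L * flat)
  params[["dense1.b"]] <- numeric(config$dense[1])
  params[["dense2.W"]] <- glorot_init(config$dense[1], config$dense[2],
                                      config$dense[1], config$dense[2])
  params[["dense2.b"]] <- numeric(config$dense[2])
  structure(list(params = params, geoms = gs, config = config,
                 flat_per_mod = flat),
            class = "gait_encoder")
}

# full forward pass; cache holds everything backprop and LRP need.
# Per-modality activations are (B*T, C) matrices, row index b + B*(t-1).
encoder_forward <- function(enc, X, keep_cache = FALSE) {
  if (is.matrix(X) || is.list(X)) X <- steps_to_array(X)
  if (dim(X)[2] != enc$config$T_len || dim(X)[3] != 28L)
    stop("input must be (batch x ", enc$config$T_len, " x 28); got (",
         paste(dim(X), collapse = " x "), ")", call. = FALSE)
  lay <- modality_layout()
  p <- enc$params; gs <- enc$geoms
  B <- dim(X)[1]
  cache <- list(X = X, B = B)
  flats <- vector("list", 3L)
  mods <- names(.mod_channels())
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    Xm <- X[, , lay[[m]], drop = FALSE]
    dim(Xm) <- c(B * enc$config$T_len, length(lay[[m]]))
    z1 <- conv_forward(Xm, p[[paste0(m, ".conv1.W")]],
                       p[[paste0(m, ".conv1.b")]], gs$g1, B)
    a1 <- relu(z1)
    z2 <- conv_forward(a1, p[[paste0(m, ".conv2.W")]],
                       p[[paste0(m, ".conv2.b")]], gs$g2, B)
    a2 <- relu(z2)
    z3 <- conv_forward(a2, p[[paste0(m, ".conv3.W")]],
                       p[[paste0(m, ".conv3.b")]], gs$g3, B)
    a3 <- relu(z3)
    fm <- a3
    dim(fm) <- c(B, enc$flat_per_mod)
    flats[[mi]] <- fm
    if (keep_cache)
      cache[[m]] <- list(Xm = Xm, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                         z3 = z3)
  }
  Zc <- do.call(cbind, flats)
  z_d1 <- sweep(Zc %*% p$dense1.W, 2, p$dense1.b, "+")
  h1 <- relu(z_d1)
  z_d2 <- sweep(h1 %*% p$dense2.W, 2, p$dense2.b, "+")
  nrm <- sqrt(rowSums(z_d2^2))
  if (any(nrm == 0))
    stop("zero-norm pre-embedding; cannot L2-normalize", call. = FALSE)
  V <- z_d2 / nrm
  if (keep_cache) {
    cache$Zc <- Zc; cache$z_d1 <- z_d1; cache$h1 <- h1
    cache$z_d2 <- z_d2; cache$nrm <- nrm; cache$V <- V
  }
  list(V = V, cache = if (keep_cache) cache else NULL)
}

# backprop from a cotangent dV at the normalized embedding.
# Returns parameter gradients and (optionally) input gradients dX.
encoder_backward <- function(enc, cache, dV, need_dX = FALSE,
                             need_grads = TRUE) {
  lay <- modality_layout()
  p <- enc$params; gs <- enc$geoms
  B <- nrow(dV)
  # through v = z/||z||:  dz = (dv - v <dv,v>) / ||z||
  dz2 <- (dV - cache$V * rowSums(dV * cache$V)) / cache$nrm
  grads <- list()
  if (need_grads) {
    grads$dense2.W <- crossprod(cache$h1, dz2)
    grads$dense2.b <- colSums(dz2)
  }
  dh1 <- dz2 %*% t(p$dense2.W)
  dzd1 <- relu_backward(dh1, cache$z_d1)
  if (need_grads) {
    grads$dense1.W <- crossprod(cache$Zc, dzd1)
    grads$dense1.b <- colSums(dzd1)
  }
  dZc <- dzd1 %*% t(p$dense1.W)
  ch <- .mod_channels()
  mods <- names(ch)
  dX <- if (need_dX) array(0, dim(cache$X)) else NULL
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    cm <- cache[[m]]
    da3 <- dZc[, (mi - 1L) * enc$flat_per_mod + seq_len(enc$flat_per_mod),
               drop = FALSE]
    dim(da3) <- c(B * gs$g3$T_out, enc$config$filters[3])
    dz3 <- relu_backward(da3, cm$z3)
    b3 <- conv_backward(dz3, cm$a2, p[[paste0(m, ".conv3.W")]], gs$g3,
                        B, enc$config$filters[2], need_dX = TRUE)
    dz2c <- relu_backward(b3$dX, cm$z2)
    b2 <- conv_backward(dz2c, cm$a1, p[[paste0(m, ".conv2.W")]], gs$g2,
                        B, enc$config$filters[1], need_dX = TRUE)
    dz1c <- relu_backward(b2$dX, cm$z1)
    b1 <- conv_backward(dz1c, cm$Xm, p[[paste0(m, ".conv1.W")]], gs$g1,
                        B, ch[[m]], need_dX = need_dX)
    if (need_grads) {
      grads[[paste0(m, ".conv3.W")]] <- b3$dW
      grads[[paste0(m, ".conv3.b")]] <- b3$db
      grads[[paste0(m, ".conv2.W")]] <- b2$dW
      grads[[paste0(m, ".conv2.b")]] <- b2$db
      grads[[paste0(m, ".conv1.W")]] <- b1$dW
      grads[[paste0(m, ".conv1.b")]] <- b1$db
    }
    if (need_dX) {
      dXm <- b1$dX
      dim(dXm) <- c(B, enc$config$T_len, ch[[m]])
      dX[, , lay[[m]]] <- dXm
    }
  }
  list(grads = grads, dX = dX)
}

#' Encode unit steps into 128-dimensional unit-norm embeddings
#'
#' @param enc a `gait_encoder`.
#' @param steps a unit-step matrix, a list of them, or a (B, T, 28) array.
#' @param chunk forward-pass batch size.
#' @return B x 128 matrix of embeddings, each row with L2 norm 1.
#' @export
encode_steps <- function(enc, steps, chunk = 512L) {
  X <- if (is.matrix(steps) || is.list(steps)) steps_to_array(steps) else steps
  B <- dim(X)[1]
  out <- matrix(0, B, enc$config$embed_dim)
  i <- 1L
  while (i <= B) {
    j <- min(B, i + chunk - 1L)
    Xi <- X[i:j, , , drop = FALSE]
    out[i:j, ] <- encoder_forward(enc, Xi)$V
    i <- j + 1L
  }
  out
}

#' Build an (untrained) multimodal decoder
#'
#' Maps a 128-dimensional embedding back to the three modality blocks via a
#' 256-unit dense layer and three sub-decoders of stride-2 transposed
#' convolutions mirroring the encoder's filter counts (128, 64) with a
#' final transposed-conv projection to the modality's channel count.
#' Outputs are raw signals; [prototype_loss()] normalizes per channel.
#'
#' @param config an [encoder_config()].
#' @return List of class `gait_decoder`.
#' @export
build_decoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  gs <- .enc_geoms(config)
  fl <- config$filters; k <- config$kernel; s <- config$strides
  ch <- .mod_channels()
  T3 <- gs$g3$T_out; T2 <- gs$g2$T_out; T1 <- gs$g1$T_out
  flat <- T3 * fl[3]
  tg1 <- tconv_geom(T3, T2, k, s[3])
  tg2 <- tconv_geom(T2, T1, k, s[2])
  tg3 <- tconv_geom(T1, config$T_len, k, s[1])
  params <- list(
    dense1.W = he_init(config$dense[2], config$dense[1], config$dense[2]),
    dense1.b = numeric(config$dense[1]))
  for (m in names(ch)) {
    params[[paste0(m, ".dense2.W")]] <- he_init(config$dense[1], flat,
                                                config$dense[1])
    params[[paste0(m, ".dense2.b")]] <- numeric(flat)
    params[[paste0(m, ".tconv1.W")]] <- he_init(k * fl[3], fl[2], k * fl[3])
    params[[paste0(m, ".tconv1.b")]] <- numeric(fl[2])
    params[[paste0(m, ".tconv2.W")]] <- he_init(k * fl[2], fl[1], k * fl[2])
    params[[paste0(m, ".tconv2.b")]] <- numeric(fl[1])
    params[[paste0(m, ".tconv3.W")]] <- glorot_init(k * fl[1], ch[[m]],
                                                    k * fl[1], ch[[m]])
    params[[paste0(m, ".tconv3.b")]] <- numeric(ch[[m]])
  }
  structure(list(params = params, geoms = list(tg1 = tg1, tg2 = tg2,
                                               tg3 = tg3),
                 T3 = T3, flat = flat, config = config),
            class = "gait_decoder")
}

decoder_forward <- function(dec, V, keep_cache = FALSE) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  if (ncol(V) != dec$config$embed_dim)
    stop("embedding must have length ", dec$config$embed_dim, call. = FALSE)
  p <- dec$params
  B <- nrow(V)
  fl <- dec$config$filters
  z_d1 <- sweep(V %*% p$dense1.W, 2, p$dense1.b, "+")
  h1 <- relu(z_d1)
  ch <- .mod_channels()
  out <- list(); cache <- list(V = V, z_d1 = z_d1, h1 = h1)
  for (m in names(ch)) {
    z_f <- sweep(h1 %*% p[[paste0(m, ".dense2.W")]], 2,
                 p[[paste0(m, ".dense2.b")]], "+")
    a_f <- relu(z_f)
    A <- a_f
    dim(A) <- c(B * dec$T3, fl[3])
    z1 <- tconv_forward(A, p[[paste0(m, ".tconv1.W")]],
                        p[[paste0(m, ".tconv1.b")]], dec$geoms$tg1, B)
    a1 <- relu(z1)
    z2 <- tconv_forward(a1, p[[paste0(m, ".tconv2.W")]],
                        p[[paste0(m, ".tconv2.b")]], dec$geoms$tg2, B)
    a2 <- relu(z2)
    z3 <- tconv_forward(a2, p[[paste0(m, ".tconv3.W")]],
                        p[[paste0(m, ".tconv3.b")]], dec$geoms$tg3, B)
    out[[m]] <- z3                         # (B*T, ch[m]) rows b + B*(t-1)
    if (keep_cache)
      cache[[m]] <- list(z_f = z_f, a_f = a_f, A = A, z1 = z1, a1 = a1,
                         z2 = z2, a2 = a2)
  }
  list(out = out, cache = if (keep_cache) cache else NULL)
}

# backprop through the decoder from per-modality cotangents dOut
decoder_backward <- function(dec, cache, dOut) {
  p <- dec$params
  fl <- dec$config$filters
  ch <- .mod_channels()
  B <- nrow(cache$V)
  grads <- list()
  dh1 <- matrix(0, B, dec$config$dense[1])
  for (m in names(ch)) {
    cm <- cache[[m]]
    b3 <- tconv_backward(dOut[[m]], cm$a2, p[[paste0(m, ".tconv3.W")]],
                         dec$geoms$tg3, B, fl[1])
    grads[[paste0(m, ".tconv3.W")]] <- b3$dW
    grads[[paste0(m, ".tconv3.b")]] <- b3$db
    dz2 <- relu_backward(b3$dX, cm$z2)
    b2 <- tconv_backward(dz2, cm$a1, p[[paste0(m, ".tconv2.W")]],
                         dec$geoms$tg2, B, fl[2])
    grads[[paste0(m, ".tconv2.W")]] <- b2$dW
    grads[[paste0(m, ".tconv2.b")]] <- b2$db
    dz1 <- relu_backward(b2$dX, cm$z1)
    b1 <- tconv_backward(dz1, cm$A, p[[paste0(m, ".tconv1.W")]],
                         dec$geoms$tg1, B, fl[3])
    grads[[paste0(m, ".tconv1.W")]] <- b1$dW
    grads[[paste0(m, ".tconv1.b")]] <- b1$db
    da_f <- b1$dX
    dim(da_f) <- c(B, dec$flat)
    dz_f <- relu_backward(da_f, cm$z_f)
    grads[[paste0(m, ".dense2.W")]] <- crossprod(cache$h1, dz_f)
    grads[[paste0(m, ".dense2.b")]] <- colSums(dz_f)
    dh1 <- dh1 + dz_f %*% t(p[[paste0(m, ".dense2.W")]])
  }
  dzd1 <- relu_backward(dh1, cache$z_d1)
  grads$dense1.W <- crossprod(cache$V, dzd1)
  grads$dense1.b <- colSums(dzd1)
  dV <- dzd1 %*% t(p$dense1.W)
  list(grads = grads, dV = dV)
}

#' Reconstruct the modality blocks of a unit step through the decoder
#'
#' @param dec a `gait_decoder`.
#' @param v a single 128-dimensional embedding.
#' @param normalize if `TRUE` (default) each channel column is normalized
#'   to unit L2 norm, the form in which the prototype loss compares
#'   reconstructions.
#' @return List with T x k matrices `pre`, `acc`, `rot`.
#' @export
decode_embedding <- function(dec, v, normalize = TRUE) {
  o <- decoder_forward(dec, matrix(v, nrow = 1))$out
  lapply(o, function(a) {       # B = 1: rows are already time stamps
    if (normalize) normalize_channels(a) else a
  })
}
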