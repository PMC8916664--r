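# Minimal 1D conv-net machinery.
#
# Batched activations are stored as 2D matrices of shape (B*T, C) with row
# index b + B*(t-1) (batch fastest); this is the column-major flattening of
# the (B, T, C) array, so conversions are zero-copy via dim<-. The heavy
# kernels (per-tap gathered GEMMs, ReLU) live in src/conv1d.cpp. Conv
# weights W are (k*C_in) x C_out with row index c + C_in*(j-1) for input
# channel c of tap j; b has length C_out.

# geometry of a stride-s "same" convolution: T_out = ceil(T_in / s)
conv_geom <- function(T_in, k, stride) {
  T_out <- as.integer(ceiling(T_in / stride))
  pad_total <- max(0L, (T_out - 1L) * stride + k - T_in)
  pad_l <- pad_total %/% 2L
  # input time feeding output t through tap j (may fall outside 1..T_in)
  it <- outer((seq_len(T_out) - 1L) * stride - pad_l, seq_len(k), `+`) + 1L
  list(T_in = as.integer(T_in), T_out = T_out, k = as.integer(k),
       stride = as.integer(stride), it = it,
       key = paste0("c", T_in, "_", k, "_", stride))
}

conv_forward <- function(X2, W, b, g, B) {
  conv1d_fwd_cpp(X2, W, b, g$it, B)
}

# gradient w.r.t. the input only; dZ2 is (B*T_out, C_out)
conv_backward_input <- function(dZ2, W, g, B, C_in) {
  conv1d_bwd_input_cpp(dZ2, W, g$it, B, g$T_in, C_in)
}

# full backward: weight/bias gradients (re-gathering the cached layer
# input X2) and optionally the input gradient
conv_backward <- function(dZ2, X2, W, g, B, C_in, need_dX = TRUE) {
  list(dW = conv1d_bwd_dw_cpp(dZ2, X2, g$it, B),
       db = colSums(dZ2),
       dX = if (need_dX) conv_backward_input(dZ2, W, g, B, C_in) else NULL)
}

relu <- function(x) relu_cpp(x)
relu_backward <- function(dY, Z) relu_bwd_cpp(dY, Z)   # Z = pre-activation

# transposed convolution realized as zero-stuffing + stride-1 same conv,
# right-padded so the output length is exactly T_out
tconv_geom <- function(T_in, T_out, k, stride) {
  T_stuff <- (T_in - 1L) * stride + 1L
  if (T_out < T_stuff || T_out - T_stuff > stride)
    stop("incompatible transposed-conv geometry", call. = FALSE)
  g <- conv_geom(T_out, k, 1L)                 # stride-1 conv on stuffed input
  g$T_in_orig <- as.integer(T_in)
  g$stuff_pos <- (seq_len(T_in) - 1L) * stride + 1L
  g$key <- paste0("t", T_in, "_", T_out, "_", k, "_", stride)
  g
}

.rx_cache <- new.env(parent = emptyenv())
.stuff_rowidx <- function(g, B) {
  key <- paste0(g$key, "_S", B)
  hit <- .rx_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- as.vector(outer(seq_len(B), (g$stuff_pos - 1L) * B, `+`))
  assign(key, out, envir = .rx_cache)
  out
}

tconv_stuff <- function(X2, g, B) {
  Xs <- matrix(0, B * g$T_in, ncol(X2))
  Xs[.stuff_rowidx(g, B), ] <- X2
  Xs
}

tconv_forward <- function(X2, W, b, g, B) {
  conv_forward(tconv_stuff(X2, g, B), W, b, g, B)
}

# X2 is the (unstuffed) cached layer input
tconv_backward <- function(dZ2, X2, W, g, B, C_in, need_dX = TRUE) {
  bk <- conv_backward(dZ2, tconv_stuff(X2, g, B), W, g, B, C_in, need_dX)
  if (need_dX) bk$dX <- bk$dX[.stuff_rowidx(g, B), , drop = FALSE]
  bk
}

# parameter initializers -----------------------------------------------------
he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}
glorot_init <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Adam ------------------------------------------------------------------------
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

# updates params and the moment estimates in place (they are uniquely
# owned by the training loop); only the step counter lives in the R state
adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    ggrad <- grads[[nm]]
    if (is.null(ggrad)) next
    adam_update_cpp(params[[nm]], state$m[[nm]], state$v[[nm]], ggrad,
                    lr, state$beta1, state$beta2, c1, c2, state$eps)
  }
  list(params = params, state = state)
}

# stack a list of T x C matrices into a (B, T, C) batch array
steps_to_array <- function(steps) {
  if (is.matrix(steps)) steps <- list(steps)
  B <- length(steps)
  d <- dim(steps[[1L]])
  X <- array(0, c(B, d[1], d[2]))
  for (i in seq_len(B)) X[i, , ] <- steps[[i]]
  X
}
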