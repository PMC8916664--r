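# Shared fixtures and independent oracles for the test suite.

# a small encoder configuration: short unit steps keep every network tiny
small_config <- function(T_len = 16, seed = 42, ...) {
  encoder_config(T_len = T_len, seed = seed, ...)
}

# a tiny synthetic dataset: n subjects x m steps of length T_len
tiny_dataset <- function(n_subjects = 4, steps = 8, T_len = 16, seed = 9,
                         noise_sd = 0.1, jitter = 0.05) {
  generate_dataset(generation_config(
    n_subjects = n_subjects, steps_per_subject = steps, T_len = T_len,
    noise_sd = noise_sd, jitter = jitter, seed = seed))
}

random_step <- function(T_len = 16, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(T_len * 28), T_len, 28)
  colnames(m) <- modality_layout()$channels
  m
}

# brute-force discrete Gaussian convolution with reflected boundaries
oracle_gauss_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  ref <- function(i) {                   # reflect index into 1..n
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  vapply(seq_len(n), function(t)
    sum(vapply(seq(-r, r), function(o) k[o + r + 1] * x[ref(t + o)], 0)),
    0)
}

# materialize a conv layer as its equivalent dense weight matrix acting on
# the column-major flattening of a (T, C) activation (index t + T*(c-1))
conv_as_dense <- function(W, b, g, C_in) {
  C_out <- ncol(W)
  Wd <- matrix(0, g$T_in * C_in, g$T_out * C_out)
  bd <- numeric(g$T_out * C_out)
  for (t_out in seq_len(g$T_out)) {
    for (co in seq_len(C_out)) {
      j_out <- t_out + g$T_out * (co - 1)
      bd[j_out] <- b[co]
      for (j in seq_len(g$k)) {
        t_in <- g$it[t_out, j]
        if (t_in < 1 || t_in > g$T_in) next
        for (ci in seq_len(C_in)) {
          Wd[t_in + g$T_in * (ci - 1), j_out] <-
            W[ci + C_in * (j - 1), co]
        }
      }
    }
  }
  list(W = Wd, b = bd)
}

# naive per-neuron LRP-epsilon redistribution through one dense layer:
# x input activations, z cached pre-activations, R relevance at the output
oracle_lrp_layer <- function(R, x, z, Wd, eps) {
  n_in <- length(x)
  R_prev <- numeric(n_in)
  for (i in seq_len(n_in)) {
    acc <- 0
    for (j in seq_along(z)) {
      if (R[j] == 0 || Wd[i, j] == 0) next
      den <- z[j] + eps * (if (z[j] >= 0) 1 else -1)
      acc <- acc + x[i] * Wd[i, j] / den * R[j]
    }
    R_prev[i] <- acc
  }
  R_prev
}

# full naive LRP pass for one component on a small encoder, treating each
# convolution as its equivalent sparse dense layer
oracle_lrp_map <- function(enc, step, comp, eps) {
  lay <- modality_layout()
  fwd <- encoder_forward(enc, step, keep_cache = TRUE)
  cc <- fwd$cache
  p <- enc$params; gs <- enc$geoms
  R <- numeric(enc$config$embed_dim)
  R[comp] <- fwd$V[1, comp]
  R <- oracle_lrp_layer(R, as.vector(cc$h1), as.vector(cc$z_d2),
                        p$dense2.W, eps)
  R <- oracle_lrp_layer(R, as.vector(cc$Zc), as.vector(cc$z_d1),
                        p$dense1.W, eps)
  Tn <- enc$config$T_len
  out <- matrix(0, Tn, 28)
  ch <- c(pre = 16L, acc = 6L, rot = 6L)
  for (mi in seq_along(names(ch))) {
    m <- names(ch)[mi]
    cm <- cc[[m]]
    Rm <- R[(mi - 1) * enc$flat_per_mod + seq_len(enc$flat_per_mod)]
    d3 <- conv_as_dense(p[[paste0(m, ".conv3.W")]],
                        p[[paste0(m, ".conv3.b")]], gs$g3, 64L)
    Rm <- oracle_lrp_layer(Rm, as.vector(cm$a2), as.vector(cm$z3),
                           d3$W, eps)
    d2 <- conv_as_dense(p[[paste0(m, ".conv2.W")]],
                        p[[paste0(m, ".conv2.b")]], gs$g2, 32L)
    Rm <- oracle_lrp_layer(Rm, as.vector(cm$a1), as.vector(cm$z2),
                           d2$W, eps)
    d1 <- conv_as_dense(p[[paste0(m, ".conv1.W")]],
                        p[[paste0(m, ".conv1.b")]], gs$g1, ch[[m]])
    Rm <- oracle_lrp_layer(Rm, as.vector(cm$Xm), as.vector(cm$z1),
                           d1$W, eps)
    out[, lay[[m]]] <- matrix(Rm, Tn, ch[[m]])
  }
  out
}

# central finite differences of one embedding component w.r.t. selected
# input entries
oracle_fd_gradient <- function(enc, step, comp, entries, h = 1e-5) {
  vapply(entries, function(i) {
    s1 <- step; s1[i] <- s1[i] + h
    s2 <- step; s2[i] <- s2[i] - h
    (encoder_forward(enc, s1)$V[1, comp] -
       encoder_forward(enc, s2)$V[1, comp]) / (2 * h)
  }, 0)
}
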