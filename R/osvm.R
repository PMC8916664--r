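#' RBF kernel between embedding sets
#'
#' `K(v, v') = exp(-gamma * ||v - v'||^2)`.
#'
#' @param A n x d matrix of embeddings.
#' @param B m x d matrix of embeddings.
#' @param gamma positive kernel width.
#' @return n x m kernel matrix.
#' @export
rbf_kernel <- function(A, B, gamma) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a per-subject one-class SVM on its shot embeddings
#'
#' Solves the dual program `min_alpha 1/2 alpha' K alpha` subject to
#' `0 <= alpha_i <= 1/(nu*n)` and `sum(alpha) = 1` with an RBF kernel, by a
#' pairwise (SMO-style) coordinate solver to KKT tolerance `tol`. The
#' offset `delta_p` is the kernel expansion evaluated at a margin support
#' vector (a shot with `0 < alpha_h < 1/(nu*n)`); if no strictly interior
#' multiplier exists, it falls back to the mean expansion over all support
#' vectors.
#'
#' @param shots n x 128 matrix of one subject's shot embeddings.
#' @param gamma RBF width (> 0), default 2.2.
#' @param nu regularization in (0, 1], default 0.06.
#' @param tol KKT tolerance (default 1e-10).
#' @return List of class `osvm_model`: `alpha`, `shots`, `gamma`, `nu`,
#'   `delta_p`, `upper` (box bound), `margin_sv` (indices), `objective`.
#' @export
fit_osvm <- function(shots, gamma = 2.2, nu = 0.06, tol = 1e-10) {
  if (is.null(dim(shots))) shots <- matrix(shots, nrow = 1)
  n <- nrow(shots)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (nu <= 0 || nu > 1)
    stop("nu must be in (0, 1]: the box constraint 0 <= alpha <= 1/(nu*n) ",
         "is otherwise infeasible with sum(alpha) = 1", call. = FALSE)
  upper <- 1 / (nu * n)
  K <- rbf_kernel(shots, shots, gamma)
  alpha <- rep(1 / n, n)
  if (n > 1L) {
    g <- as.numeric(K %*% alpha)             # gradient of 1/2 a'Ka
    for (it in seq_len(200L * n * n)) {
      up  <- which(alpha < upper - 1e-14)    # can increase
      dn  <- which(alpha > 1e-14)            # can decrease
      i <- up[which.min(g[up])]
      j <- dn[which.max(g[dn])]
      if (g[j] - g[i] <= tol) break
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      s <- alpha[i] + alpha[j]
      t_new <- if (eta > 1e-14) alpha[i] + (g[j] - g[i]) / eta else s
      t_new <- min(max(t_new, max(0, s - upper)), min(upper, s))
      da <- t_new - alpha[i]
      if (abs(da) < 1e-16) break
      alpha[i] <- t_new
      alpha[j] <- s - t_new
      g <- g + da * (K[, i] - K[, j])
    }
  }
  g <- as.numeric(K %*% alpha)
  band <- 1e-8 * upper
  margin <- which(alpha > band & alpha < upper - band)
  delta_p <- if (length(margin) > 0) mean(g[margin])
             else mean(g[alpha > band])      # fallback: all support vectors
  structure(list(alpha = alpha, shots = shots, gamma = gamma, nu = nu,
                 delta_p = delta_p, upper = upper, margin_sv = margin,
                 objective = 0.5 * sum(alpha * g)),
            class = "osvm_model")
}

#' One-class SVM decision value
#'
#' `h_p(v) = sum_i alpha_i K(v_i, v) - delta_p`; non-negative values lie
#' inside the subject's boundary.
#'
#' @param model an `osvm_model`.
#' @param v a single embedding or an m x 128 matrix of embeddings.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  as.numeric(rbf_kernel(v, model$shots, model$gamma) %*% model$alpha) -
    model$delta_p
}

#' Centroid of a subject's shot embeddings
#'
#' Plain arithmetic mean of the n shots (not re-normalized).
#'
#' @param shots n x 128 matrix of one subject's embeddings.
#' @return Length-128 centroid vector.
#' @export
compute_centroid <- function(shots) {
  if (is.null(dim(shots))) shots <- matrix(shots, nrow = 1)
  colMeans(shots)
}
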