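# k-SVD sparse dictionary learning with a one-atom-per-sample sparsity
# constraint (T0 = 1), as used by the window-less dFC method: each time
# point's activity vector is represented by exactly one dictionary atom.

#' Fit a k-SVD dictionary with one-sparse coding
#'
#' Alternates (i) sparse coding: each sample is assigned to the atom
#' maximizing the absolute inner product, with coefficient equal to that
#' inner product; and (ii) dictionary update: each atom is replaced by the
#' leading left singular vector of its assigned samples (which jointly
#' updates the coefficients). Dead atoms are re-initialized from the
#' worst-represented sample. The squared reconstruction error is
#' non-increasing across iterations; the fit is deterministic given `seed`.
#' Atoms are stored with their largest-magnitude element positive (outer
#' products are sign-invariant).
#'
#' @param X N x R matrix of samples (rows = observations).
#' @param K Number of dictionary atoms.
#' @param seed Integer seed (atom initialization draws random samples).
#' @param max_iter Iteration cap (default 50).
#' @param tol Relative objective-decrease convergence tolerance.
#' @return Object of class `sparse_dictionary`: `D` (R x K, unit-norm
#'   columns), `labels` (length N atom index), `coefs` (length N),
#'   `objective` (per-iteration squared error), `converged`.
#' @export
ksvd_fit <- function(X, K, seed = 1L, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  N <- nrow(X)
  R <- ncol(X)
  if (!is_count(K) || K < 1) stop_fmt("K must be a positive integer")
  if (K > N) stop_fmt("more atoms (%d) than samples (%d)", K, N)
  set.seed(as.integer(seed))
  norms <- sqrt(rowSums(X^2))
  ok <- which(norms > 0)
  if (length(ok) < K) stop_fmt("not enough nonzero samples for %d atoms", K)
  picks <- sample(ok, K)
  D <- t(X[picks, , drop = FALSE] / norms[picks])

  objective <- numeric(0)
  labels <- integer(N)
  coefs <- numeric(N)
  converged <- FALSE
  total_sq <- sum(X^2)
  for (iter in seq_len(max_iter)) {
    # Sparse coding: P[n, k] = <x_n, d_k>
    P <- X %*% D
    labels <- max.col(abs(P), ties.method = "first")
    coefs <- P[cbind(seq_len(N), labels)]
    # ||x - c d||^2 = ||x||^2 - c^2 for unit-norm d and optimal c
    obj <- total_sq - sum(coefs^2)
    objective <- c(objective, obj)
    if (iter > 1 && objective[iter - 1] - obj < tol * (1 + obj)) {
      converged <- TRUE
      break
    }
    # Dictionary update: rank-1 SVD of each atom's sample block.
    resid <- (rowSums(X^2) - coefs^2)
    for (k in seq_len(K)) {
      rows <- which(labels == k)
      if (!length(rows)) {
        worst <- which.max(resid)
        D[, k] <- X[worst, ] / sqrt(sum(X[worst, ]^2))
        resid[worst] <- 0
        next
      }
      block <- X[rows, , drop = FALSE]
      sv <- svd(block, nu = 0, nv = 1)
      D[, k] <- sv$v[, 1]
    }
    # Sign convention: largest-magnitude element positive.
    for (k in seq_len(K)) {
      j <- which.max(abs(D[, k]))
      if (D[j, k] < 0) D[, k] <- -D[, k]
    }
  }
  structure(
    list(D = D, labels = labels, coefs = coefs, objective = objective,
         converged = converged, K = as.integer(K), seed = as.integer(seed)),
    class = "sparse_dictionary"
  )
}

# One-sparse coding of new samples against a fitted dictionary.
ksvd_assign <- function(D, X) {
  P <- as.matrix(X) %*% D
  labels <- max.col(abs(P), ties.method = "first")
  list(labels = labels, coefs = P[cbind(seq_len(nrow(P)), labels)])
}
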