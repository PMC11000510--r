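# Hidden Markov models fit by Baum-Welch EM with scaled forward-backward
# recursions, supporting multiple observation sequences (one per subject;
# the chain restarts at every subject boundary, so no transition is counted
# across subjects). Decoding uses the Viterbi algorithm (hard path).

# Scaled forward-backward from a T x K log-density matrix.
forward_backward <- function(logB, init, A) {
  T <- nrow(logB)
  K <- ncol(logB)
  mx <- apply(logB, 1, max)
  B <- exp(logB - mx)
  alpha <- matrix(0, T, K)
  cvec <- numeric(T)
  a <- init * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:T) {
    a <- as.vector(alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, T, K)
  beta[T, ] <- 1
  xi_sum <- matrix(0, K, K)
  for (t in (T - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    xi_sum <- xi_sum + A * outer(alpha[t, ], bb / cvec[t + 1])
    beta[t, ] <- as.vector(A %*% bb) / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cvec)) + sum(mx))
}

viterbi_path <- function(logB, init, A) {
  T <- nrow(logB)
  K <- ncol(logB)
  logA <- log(pmax(A, 1e-300))
  delta <- log(pmax(init, 1e-300)) + logB[1, ]
  back <- matrix(0L, T, K)
  for (t in 2:T) {
    cand <- delta + logA  # cand[i, j] = delta[i] + logA[i, j]
    back[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(back[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(T)
  path[T] <- which.max(delta)
  for (t in (T - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

# T x K matrix of log multivariate-normal densities.
mvn_logdens <- function(X, means, chols) {
  K <- nrow(means)
  T <- nrow(X)
  R <- ncol(X)
  out <- matrix(0, T, K)
  for (k in seq_len(K)) {
    U <- chols[[k]]
    logdet <- 2 * sum(log(diag(U)))
    Xc <- sweep(X, 2, means[k, ])
    Y <- forwardsolve(t(U), t(Xc))
    out[, k] <- -0.5 * (R * log(2 * pi) + logdet + colSums(Y^2))
  }
  out
}

chol_with_ridge <- function(S, ridge = 1e-6, max_tries = 8) {
  add <- 0
  for (i in seq_len(max_tries)) {
    U <- tryCatch(chol(S + add * diag(nrow(S))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, ridge = add))
    add <- if (add == 0) ridge else add * 10
  }
  stop_fmt("covariance not positive definite after %d ridge restarts", max_tries)
}

#' Fit a Gaussian hidden Markov model (Baum-Welch EM)
#'
#' Full-covariance Gaussian observation model; multiple sequences are
#' supported and the chain is re-initialized at each sequence boundary.
#' Initialization uses seeded k-means on the pooled observations; covariance
#' matrices receive an escalating diagonal ridge whenever a Cholesky
#' factorization fails. The EM log-likelihood is non-decreasing; fitting is
#' deterministic given `seed`.
#'
#' @param X_list List of T_i x R observation matrices (one per sequence).
#' @param K Number of hidden states.
#' @param seed Integer seed.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ridge Base diagonal regularization (default 1e-6).
#' @param n_restarts Number of independently initialized EM runs; the fit
#'   with the best final log-likelihood is kept (default 5). EM is prone to
#'   local optima from any single initialization.
#' @return Object of class `gaussian_hmm`: `means` (K x R), `covariances`
#'   (K x R x R), `transition`, `initial`, `loglik` trace, `converged`.
#' @export
gaussian_hmm_fit <- function(X_list, K, seed = 1L, max_iter = 100,
                             tol = 1e-6, ridge = 1e-6, n_restarts = 5) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # restart 1 initializes from k-means on the frames (sensitive to mean
    # structure); later restarts from random contiguous-segment covariance
    # estimates (sensitive to covariance structure, diverse across seeds)
    init_method <- if (r == 1) "kmeans" else "segments"
    fit <- gaussian_hmm_em(X_list, K, derive_seed(seed, r - 1), max_iter,
                           tol, ridge, init_method)
    if (is.null(best) ||
        fit$loglik[length(fit$loglik)] > best$loglik[length(best$loglik)]) {
      best <- fit
    }
  }
  best$seed <- as.integer(seed)
  best
}

gaussian_hmm_em <- function(X_list, K, seed, max_iter, tol, ridge,
                            init_method = "kmeans") {
  stopifnot(is.list(X_list), length(X_list) >= 1, is_count(K))
  X_list <- lapply(X_list, as.matrix)
  R <- ncol(X_list[[1]])
  Xall <- do.call(rbind, X_list)
  lens <- vapply(X_list, nrow, integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))

  set.seed(as.integer(seed))
  pooled <- stats::cov(Xall) + ridge * diag(R)
  if (init_method == "kmeans") {
    km <- kmeans_seeded(Xall, K)
    K <- km$k
    assign_vec <- km$cluster
    means <- km$centers
  } else {
    # random contiguous segments (~50 frames) assigned to random states
    assign_vec <- integer(nrow(Xall))
    for (s in seq_along(X_list)) {
      n_seg <- max(K, ceiling(lens[s] / 50))
      cuts <- sort(sample.int(lens[s] - 1, min(n_seg - 1, lens[s] - 1)))
      seg_id <- findInterval(seq_len(lens[s]), c(0, cuts) + 1)
      seg_state <- sample(rep_len(seq_len(K), max(seg_id)))
      assign_vec[offsets[s] + seq_len(lens[s])] <- seg_state[seg_id]
    }
    means <- t(vapply(seq_len(K), function(k) {
      rows <- assign_vec == k
      if (any(rows)) colMeans(Xall[rows, , drop = FALSE]) else numeric(R)
    }, numeric(R)))
  }
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- assign_vec == k
    covs[[k]] <- if (sum(rows) > R) {
      stats::cov(Xall[rows, , drop = FALSE]) + ridge * diag(R)
    } else pooled
  }
  A <- matrix(0.1 / max(1, K - 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  init <- rep(1 / K, K)

  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    chols <- lapply(covs, function(S) chol_with_ridge(S, ridge)$U)
    logB_all <- mvn_logdens(Xall, means, chols)
    Nk <- rep(1e-10, K)
    xk <- matrix(0, K, R)
    xi_tot <- matrix(0, K, K)
    init_tot <- rep(0, K)
    ll <- 0
    gam_all <- matrix(0, nrow(Xall), K)
    for (s in seq_along(X_list)) {
      rows <- offsets[s] + seq_len(lens[s])
      fb <- forward_backward(logB_all[rows, , drop = FALSE], init, A)
      gam_all[rows, ] <- fb$gamma
      Nk <- Nk + colSums(fb$gamma)
      xk <- xk + crossprod(fb$gamma, Xall[rows, , drop = FALSE])
      xi_tot <- xi_tot + fb$xi_sum
      init_tot <- init_tot + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    ll_trace <- c(ll_trace, ll)
    means <- xk / Nk
    for (k in seq_len(K)) {
      Xc <- sweep(Xall, 2, means[k, ])
      covs[[k]] <- crossprod(Xc * gam_all[, k], Xc) / Nk[k] + ridge * diag(R)
    }
    rs <- rowSums(xi_tot)
    A <- xi_tot / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    init <- init_tot / sum(init_tot)
    if (iter > 1 &&
        abs(ll - ll_trace[iter - 1]) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
  }
  cov_arr <- array(0, c(K, R, R))
  for (k in seq_len(K)) cov_arr[k, , ] <- (covs[[k]] + t(covs[[k]])) / 2
  structure(
    list(K = K, means = means, covariances = cov_arr, transition = A,
         initial = init, loglik = ll_trace, converged = converged,
         seed = as.integer(seed)),
    class = "gaussian_hmm"
  )
}

#' Decode the most likely state path of a Gaussian HMM
#'
#' @param model A [gaussian_hmm_fit()] result.
#' @param X T x R observation matrix.
#' @return Integer state sequence of length T.
#' @export
gaussian_hmm_viterbi <- function(model, X) {
  stopifnot(inherits(model, "gaussian_hmm"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$means)) {
    stop_fmt("observation dimension (%d) does not match the model (%d)",
             ncol(X), ncol(model$means))
  }
  chols <- lapply(seq_len(model$K), function(k) {
    chol_with_ridge(model$covariances[k, , ])$U
  })
  viterbi_path(mvn_logdens(X, model$means, chols), model$initial,
               model$transition)
}

#' Fit a categorical (discrete-observation) hidden Markov model
#'
#' EM fit of a K-state HMM with a categorical emission distribution over
#' `n_obs` symbols; multiple sequences supported with chain restarts at
#' boundaries. Deterministic given `seed`.
#'
#' @param obs_list List of integer observation sequences (symbols in
#'   `1..n_obs`).
#' @param K Number of hidden states.
#' @param n_obs Number of observation symbols.
#' @param seed,max_iter,tol,n_restarts As in [gaussian_hmm_fit()].
#' @return Object of class `categorical_hmm`: `emission` (K x n_obs),
#'   `transition`, `initial`, `loglik`, `converged`.
#' @export
categorical_hmm_fit <- function(obs_list, K, n_obs, seed = 1L,
                                max_iter = 200, tol = 1e-8, n_restarts = 5) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- categorical_hmm_em(obs_list, K, n_obs, derive_seed(seed, r - 1),
                              max_iter, tol)
    if (is.null(best) ||
        fit$loglik[length(fit$loglik)] > best$loglik[length(best$loglik)]) {
      best <- fit
    }
  }
  best$seed <- as.integer(seed)
  best
}

categorical_hmm_em <- function(obs_list, K, n_obs, seed, max_iter, tol) {
  stopifnot(is.list(obs_list), is_count(K), is_count(n_obs))
  obs_list <- lapply(obs_list, as.integer)
  for (o in obs_list) {
    if (any(o < 1 | o > n_obs)) stop_fmt("observation symbol out of 1..%d", n_obs)
  }
  set.seed(as.integer(seed))
  E <- matrix(stats::runif(K * n_obs) + 0.5, K, n_obs)
  E <- E / rowSums(E)
  # near-uniform transition init with a small random perturbation: avoids
  # committing to slow dynamics before the emissions differentiate
  A <- matrix(1, K, K) + 0.1 * matrix(stats::runif(K * K), K, K)
  A <- A / rowSums(A)
  init <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logE <- log(pmax(E, 1e-300))
    Nk <- rep(1e-10, K)
    emis <- matrix(1e-10, K, n_obs)
    xi_tot <- matrix(0, K, K)
    init_tot <- rep(0, K)
    ll <- 0
    for (s in seq_along(obs_list)) {
      o <- obs_list[[s]]
      logB <- t(logE[, o, drop = FALSE])
      fb <- forward_backward(logB, init, A)
      Nk <- Nk + colSums(fb$gamma)
      for (v in seq_len(n_obs)) {
        rows <- o == v
        if (any(rows)) {
          emis[, v] <- emis[, v] + colSums(fb$gamma[rows, , drop = FALSE])
        }
      }
      xi_tot <- xi_tot + fb$xi_sum
      init_tot <- init_tot + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    ll_trace <- c(ll_trace, ll)
    E <- emis / rowSums(emis)
    rs <- rowSums(xi_tot)
    A <- xi_tot / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    init <- init_tot / sum(init_tot)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(K = K, n_obs = as.integer(n_obs), emission = E, transition = A,
         initial = init, loglik = ll_trace, converged = converged,
         seed = as.integer(seed)),
    class = "categorical_hmm"
  )
}

#' Decode the most likely hidden path of a categorical HMM
#'
#' @param model A [categorical_hmm_fit()] result.
#' @param obs Integer observation sequence.
#' @return Integer hidden-state sequence.
#' @export
categorical_hmm_viterbi <- function(model, obs) {
  stopifnot(inherits(model, "categorical_hmm"))
  obs <- as.integer(obs)
  if (any(obs < 1 | obs > model$n_obs)) {
    stop_fmt("observation symbol out of 1..%d", model$n_obs)
  }
  logE <- log(pmax(model$emission, 1e-300))
  viterbi_path(t(logE[, obs, drop = FALSE]), model$initial, model$transition)
}
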