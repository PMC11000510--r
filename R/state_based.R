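# The five state-based dFC estimators under a common group-fit /
# subject-apply contract: models are fit once on all subjects (time series
# concatenated, no transitions counted across subject boundaries), then
# applied to each subject to produce a state time course; the dFC matrix
# places each state's FC matrix at the time points assigned to it.

new_state_set <- function(method_id, state_fc, fit_seed, meta = list()) {
  K <- dim(state_fc)[1]
  for (k in seq_len(K)) {
    check_symmetric(state_fc[k, , ], tol = 1e-8,
                    what = sprintf("state FC %d", k))
  }
  structure(list(method_id = method_id, K = K, state_fc = state_fc,
                 fit_seed = as.integer(fit_seed), meta = meta),
            class = "state_set")
}

new_state_timecourse <- function(subject_id, labels, K, time_stamps) {
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > K)) stop_fmt("state label out of 1..%d", K)
  structure(list(subject_id = subject_id, labels = labels,
                 fractional_occupancy = fractional_occupancy(labels, K),
                 time_stamps = as.numeric(time_stamps)),
            class = "state_timecourse")
}

#' Fractional occupancy of a state label sequence
#'
#' `FO[k]` is the fraction of time points assigned to state k; the vector
#' sums to 1.
#'
#' @param labels Integer vector with values in `1..K`.
#' @param K Number of states.
#' @return Numeric vector of length K.
#' @export
fractional_occupancy <- function(labels, K) {
  labels <- as.integer(labels)
  if (!is_count(K)) stop_fmt("K must be a positive integer")
  if (any(labels < 1 | labels > K)) {
    stop_fmt("label out of range 1..%d", K)
  }
  tabulate(labels, nbins = K) / length(labels)
}

states_to_dfc <- function(fit, labels, time_stamps, ts) {
  vals <- fit$state_set$state_fc[labels, , , drop = FALSE]
  dfc_matrix(vals, time_stamps, ts$subject_id, fit$method_id,
             ts$roi_labels, ts$rsn_labels)
}

outer_states <- function(centers) {
  K <- nrow(centers)
  R <- ncol(centers)
  out <- array(0, c(K, R, R))
  for (k in seq_len(K)) out[k, , ] <- tcrossprod(centers[k, ])
  out
}

finish_fit <- function(fit, ts_list, labels_list, stamps_list) {
  fit$timecourses <- vector("list", length(ts_list))
  fit$dfc <- vector("list", length(ts_list))
  for (s in seq_along(ts_list)) {
    fit$timecourses[[s]] <- new_state_timecourse(
      ts_list[[s]]$subject_id, labels_list[[s]], fit$state_set$K,
      stamps_list[[s]])
    fit$dfc[[s]] <- states_to_dfc(fit, labels_list[[s]], stamps_list[[s]],
                                  ts_list[[s]])
  }
  names(fit$timecourses) <- vapply(ts_list, `[[`, "", "subject_id")
  names(fit$dfc) <- names(fit$timecourses)
  class(fit) <- "dfc_fit"
  fit
}

#' @export
print.dfc_fit <- function(x, ...) {
  cat(sprintf("<dfc_fit> method %s: K = %d states, %d subjects\n",
              x$method_id, x$state_set$K, length(x$timecourses)))
  invisible(x)
}

#' Coactivation patterns (method CAP)
#'
#' Two-stage k-means on the per-TR BOLD activity vectors (length R): each
#' subject's frames are clustered into `k_subject` centroids, the pooled
#' centroids into K group centroids. Each state's FC matrix is the outer
#' product of its centroid with itself (rank 1); the per-TR cluster labels
#' form the state time course.
#'
#' @param ts_list List of z-standardized [parcellated_ts()].
#' @param K Number of FC states (default 12).
#' @param k_subject Subject-level cluster count (default 20).
#' @param seed Integer seed.
#' @return A `dfc_fit` with state set, per-subject state time courses and
#'   per-TR dFC matrices.
#' @export
cap_fit <- function(ts_list, K = 12, k_subject = 20, seed = 1L) {
  samples <- lapply(ts_list, `[[`, "values")
  km <- two_level_kmeans(samples, k_subject = k_subject, k_group = K,
                         seed = seed)
  fit <- list(method_id = "CAP",
              state_set = new_state_set("CAP", outer_states(km$centers), seed),
              centers = km$centers)
  stamps <- lapply(ts_list, function(ts) seq_len(nrow(ts$values)))
  finish_fit(fit, ts_list, km$labels, stamps)
}

#' Sliding-window clustering (method SWC)
#'
#' Computes the sliding-window dFC of each subject, vectorizes every window
#' FC matrix to its R(R-1)/2 lower triangle, and clusters these feature
#' vectors with the two-stage k-means into K FC states. State FC matrices
#' are the devectorized group centroids (unit diagonal); labels live on the
#' 38-point window grid.
#'
#' @inheritParams cap_fit
#' @param window A [make_tapered_window()].
#' @return A `dfc_fit`.
#' @export
swc_fit <- function(ts_list, K = 12, k_subject = 20,
                    window = make_tapered_window(), seed = 1L) {
  sw <- lapply(ts_list, sliding_window_dfc, window = window)
  feats <- lapply(sw, vectorize_dfc)
  km <- two_level_kmeans(feats, k_subject = k_subject, k_group = K,
                         seed = seed)
  K_eff <- nrow(km$centers)
  R <- ncol(ts_list[[1]]$values)
  state_fc <- array(0, c(K_eff, R, R))
  for (k in seq_len(K_eff)) {
    state_fc[k, , ] <- devectorize_lower_triangle(km$centers[k, ], diag = 1)
  }
  fit <- list(method_id = "SWC",
              state_set = new_state_set("SWC", state_fc, seed),
              centers = km$centers, window = window)
  stamps <- lapply(sw, `[[`, "time_stamps")
  finish_fit(fit, ts_list, km$labels, stamps)
}

#' Continuous HMM (method CHMM)
#'
#' Fits a K-state Gaussian hidden Markov model to the concatenated BOLD
#' series of all subjects (chain restarting at subject boundaries); each
#' hidden state's covariance matrix is its state FC matrix, and per-subject
#' Viterbi decoding yields the per-TR state time course.
#'
#' @inheritParams cap_fit
#' @param ... Passed to [gaussian_hmm_fit()] (`max_iter`, `tol`, `ridge`).
#' @return A `dfc_fit` carrying the fitted [gaussian_hmm_fit()] model.
#' @export
chmm_fit <- function(ts_list, K = 12, seed = 1L, ...) {
  X_list <- lapply(ts_list, `[[`, "values")
  model <- gaussian_hmm_fit(X_list, K, seed = seed, ...)
  labels <- lapply(X_list, function(X) gaussian_hmm_viterbi(model, X))
  fit <- list(method_id = "CHMM",
              state_set = new_state_set("CHMM", model$covariances, seed,
                                        meta = list(converged = model$converged,
                                                    iterations = length(model$loglik))),
              model = model)
  stamps <- lapply(X_list, function(X) seq_len(nrow(X)))
  finish_fit(fit, ts_list, labels, stamps)
}

#' Discrete HMM (method DHMM)
#'
#' First runs [swc_fit()] with `n_obs = round(K * obs_to_state_ratio)`
#' clusters; the resulting window state time courses become the discrete
#' observation sequences of a K-state categorical HMM. Hidden labels come
#' from Viterbi decoding; the FC matrix of each hidden state is the average
#' of all window FC matrices (from the clustering-stage dFC) assigned to it.
#' Hidden states left without any window are dropped with a warning and the
#' remaining states renumbered (recorded in `state_set$meta`).
#'
#' @inheritParams swc_fit
#' @param obs_to_state_ratio Ratio of observation symbols to hidden states
#'   (default 16/24).
#' @return A `dfc_fit` carrying both the categorical HMM and the
#'   clustering-stage fit.
#' @export
dhmm_fit <- function(ts_list, K = 12, obs_to_state_ratio = 16 / 24,
                     k_subject = 20, window = make_tapered_window(),
                     seed = 1L) {
  n_obs <- max(2L, as.integer(round(K * obs_to_state_ratio)))
  swc <- swc_fit(ts_list, K = n_obs, k_subject = k_subject,
                 window = window, seed = derive_seed(seed, 1))
  obs_list <- lapply(swc$timecourses, `[[`, "labels")
  n_obs_eff <- swc$state_set$K
  model <- categorical_hmm_fit(obs_list, K, n_obs_eff, seed = seed)
  hidden <- lapply(obs_list, function(o) categorical_hmm_viterbi(model, o))

  # State FC = mean of the clustering-stage FC slices assigned to each
  # hidden state.
  R <- ncol(ts_list[[1]]$values)
  sums <- array(0, c(K, R, R))
  counts <- integer(K)
  for (s in seq_along(hidden)) {
    for (t in seq_along(hidden[[s]])) {
      k <- hidden[[s]][t]
      sums[k, , ] <- sums[k, , ] + swc$dfc[[s]]$values[t, , ]
      counts[k] <- counts[k] + 1L
    }
  }
  occupied <- which(counts > 0)
  if (length(occupied) < K) {
    warn_fmt("dropping %d empty hidden state(s); %d states remain",
             K - length(occupied), length(occupied))
  }
  K_eff <- length(occupied)
  state_fc <- array(0, c(K_eff, R, R))
  for (i in seq_along(occupied)) {
    k <- occupied[i]
    state_fc[i, , ] <- sums[k, , ] / counts[k]
  }
  relabel <- match(seq_len(K), occupied)
  hidden <- lapply(hidden, function(h) relabel[h])
  fit <- list(method_id = "DHMM",
              state_set = new_state_set("DHMM", state_fc, seed,
                                        meta = list(n_obs = n_obs_eff,
                                                    dropped_states = K - K_eff,
                                                    converged = model$converged)),
              model = model, swc = swc, window = window)
  stamps <- lapply(swc$timecourses, `[[`, "time_stamps")
  finish_fit(fit, ts_list, hidden, stamps)
}

#' Window-less k-SVD (method WL)
#'
#' Applies one-sparse k-SVD dictionary learning to the concatenated per-TR
#' BOLD activity vectors of all subjects: each time point is represented by
#' exactly one unit-norm dictionary atom. State FC matrices are the atoms'
#' outer products (rank 1, trace 1); the per-TR atom assignments are the
#' state time course.
#'
#' @inheritParams cap_fit
#' @param ... Passed to [ksvd_fit()].
#' @return A `dfc_fit` carrying the fitted [ksvd_fit()] dictionary.
#' @export
wl_fit <- function(ts_list, K = 12, seed = 1L, ...) {
  X_list <- lapply(ts_list, `[[`, "values")
  Xall <- do.call(rbind, X_list)
  dict <- ksvd_fit(Xall, K, seed = seed, ...)
  lens <- vapply(X_list, nrow, integer(1))
  splits <- rep(seq_along(X_list), lens)
  labels <- split(dict$labels, splits)
  fit <- list(method_id = "WL",
              state_set = new_state_set("WL", outer_states(t(dict$D)), seed,
                                        meta = list(converged = dict$converged,
                                                    iterations = length(dict$objective))),
              model = dict)
  stamps <- lapply(X_list, function(X) seq_len(nrow(X)))
  finish_fit(fit, ts_list, labels, stamps)
}

#' Apply a fitted group-level state model to one subject
#'
#' Assigns each of the subject's time points to a group-level FC state with
#' the method's native rule — nearest centroid (Euclidean) for CAP and SWC,
#' Viterbi decoding for CHMM and DHMM, maximum absolute inner product with
#' the dictionary atoms for WL — and builds the subject's dFC matrix by
#' placing each state's FC matrix at the time points assigned to it. The
#' subject must be preprocessed identically to the fitting data.
#'
#' @param fit A `dfc_fit` from one of the `*_fit()` functions.
#' @param ts The subject's [parcellated_ts()].
#' @return List with `timecourse` (a state time course) and `dfc`
#'   (a [dfc_matrix()] with at most K distinct slices).
#' @export
apply_states <- function(fit, ts) {
  stopifnot(inherits(fit, "dfc_fit"), inherits(ts, "parcellated_ts"))
  R_model <- dim(fit$state_set$state_fc)[2]
  if (ncol(ts$values) != R_model) {
    stop_fmt("subject has %d ROIs but the model was fit on %d",
             ncol(ts$values), R_model)
  }
  X <- ts$values
  per_tr <- seq_len(nrow(X))
  res <- switch(
    fit$method_id,
    CAP = list(labels = nearest_center(X, fit$centers), stamps = per_tr),
    WL = list(labels = ksvd_assign(fit$model$D, X)$labels, stamps = per_tr),
    CHMM = list(labels = gaussian_hmm_viterbi(fit$model, X), stamps = per_tr),
    SWC = {
      sw <- sliding_window_dfc(ts, fit$window)
      list(labels = nearest_center(vectorize_dfc(sw), fit$centers),
           stamps = sw$time_stamps)
    },
    DHMM = {
      if (fit$state_set$meta$dropped_states > 0) {
        stop_fmt("cannot apply a DHMM fit with dropped states to new subjects; refit")
      }
      sw <- sliding_window_dfc(ts, fit$window)
      obs <- nearest_center(vectorize_dfc(sw), fit$swc$centers)
      list(labels = categorical_hmm_viterbi(fit$model, obs),
           stamps = sw$time_stamps)
    },
    stop_fmt("apply_states does not support method %s", fit$method_id)
  )
  tc <- new_state_timecourse(ts$subject_id, res$labels, fit$state_set$K,
                             res$stamps)
  list(timecourse = tc,
       dfc = states_to_dfc(fit, res$labels, res$stamps, ts))
}
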