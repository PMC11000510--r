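# Synthetic BOLD generator: multi-subject Markov-switching Gaussian series
# with planted connectivity states, a stationary (single-state) null, and a
# planted-block method fixture for the comparison framework. All generators
# are pure functions of (spec, seed).

#' Build a correlation matrix with RSN block structure
#'
#' Within-network pairs get correlation `within_r`, between-network pairs
#' `between_r`, unit diagonal. If the result is not positive definite it is
#' repaired by flooring eigenvalues at 1e-6 and renormalizing to unit
#' diagonal; an unrepairable matrix is an error.
#'
#' @param rsn_partition List of integer vectors partitioning `1..R` into
#'   networks, or a length-R vector of block labels.
#' @param within_r,between_r Correlations with `|r| < 1` and
#'   `within_r > between_r`.
#' @return R x R SPD correlation matrix.
#' @export
make_block_covariance <- function(rsn_partition, within_r, between_r = 0) {
  if (!is.list(rsn_partition)) {
    rsn_partition <- split(seq_along(rsn_partition), rsn_partition)
  }
  idx <- sort(as.integer(unlist(rsn_partition, use.names = FALSE)))
  R <- length(idx)
  if (!identical(idx, seq_len(R))) {
    stop_fmt("rsn_partition must cover 1..R exactly once")
  }
  if (abs(within_r) >= 1 || abs(between_r) >= 1 || within_r < between_r) {
    stop_fmt("need |r| < 1 and within_r >= between_r")
  }
  m <- matrix(between_r, R, R)
  for (block in rsn_partition) m[block, block] <- within_r
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    m <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    m <- stats::cov2cor(m)
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop_fmt("block covariance not SPD after eigenvalue repair")
    }
  }
  (m + t(m)) / 2
}

default_partition <- function(R, n_blocks) {
  split(seq_len(R), rep(seq_len(n_blocks), each = ceiling(R / n_blocks),
                        length.out = R))
}

# Default planted covariance states: three mutually near-orthogonal block
# partitions (contiguous, interleaved, and a Latin-square mix), so the
# states are well separated in connection space (pairwise lower-triangle
# correlations below 0.15 in magnitude at R = 12).
default_state_covariances <- function(R, K, seed) {
  covs <- array(0, c(K, R, R))
  part1 <- default_partition(R, 3)
  if (K >= 1) covs[1, , ] <- make_block_covariance(part1, 0.8, 0)
  if (K >= 2) {
    interleaved <- split(seq_len(R), rep_len(seq_len(3), R))
    covs[2, , ] <- make_block_covariance(interleaved, 0.8, 0)
  }
  if (K >= 3) {
    q <- (seq_len(R) - 1) %/% 3
    r <- (seq_len(R) - 1) %% 3
    covs[3, , ] <- make_block_covariance(split(seq_len(R), (q + r) %% 3),
                                         0.8, 0)
  }
  if (K > 3) {
    set.seed(derive_seed(seed, 77))
    for (k in 4:K) {
      part <- split(seq_len(R), sample(rep_len(seq_len(3), R)))
      covs[k, , ] <- make_block_covariance(part, 0.8, 0)
    }
  }
  covs
}

# Orthogonal-plane activation patterns with zero sum over states: unit sign
# vectors u, v span a plane; state means sit at equal angles on its circle.
activation_patterns <- function(R, K) {
  if (R %% 4 != 0) stop_fmt("activation patterns need R divisible by 4")
  u <- rep(c(1, 1, -1, -1), R / 4) / sqrt(R)
  v <- rep(c(1, -1, 1, -1), R / 4) / sqrt(R)
  theta <- 2 * pi * (seq_len(K) - 1) / K
  t(vapply(theta, function(a) cos(a) * u + sin(a) * v, numeric(R)))
}

#' Specify a synthetic Markov-switching BOLD dataset
#'
#' Defines a multi-subject generative model: a K-state Markov chain (default
#' self-transition 0.95, uniform off-diagonal) switching between
#' multivariate Gaussian regimes with per-state covariance (default: three
#' contrasting RSN block structures) and optional per-state mean activation
#' patterns, sampled at TR = 0.72 s. Defaults mirror a resting-state fMRI
#' regime of 1200 time points per subject; the default test-scale
#' parcellation has R = 12 ROIs in 3 RSNs with alternating hemispheres.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_timepoints Time points per subject (default 1200).
#' @param n_rois Number of ROIs (default 12).
#' @param tr_seconds Sampling interval (default 0.72).
#' @param K Number of planted states (default 3).
#' @param transition Optional K x K row-stochastic matrix; default has 0.95
#'   self-transition.
#' @param state_covariances Optional K x R x R array of SPD state
#'   covariances.
#' @param state_means Optional K x R matrix of state means (default 0:
#'   covariance-only regimes).
#' @param observation_noise_sd Isotropic observation noise sd added on top
#'   of the state draw (default 0).
#' @param rsn_partition List of ROI index vectors per network (default 3
#'   equal networks).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10, n_timepoints = 1200, n_rois = 12,
                           tr_seconds = 0.72, K = 3, transition = NULL,
                           state_covariances = NULL, state_means = NULL,
                           observation_noise_sd = 0, rsn_partition = NULL,
                           seed = 1L) {
  stopifnot(is_count(n_subjects), is_count(n_timepoints), is_count(n_rois),
            is_count(K))
  if (is.null(transition)) {
    transition <- matrix(if (K > 1) 0.05 / (K - 1) else 0, K, K)
    diag(transition) <- if (K > 1) 0.95 else 1
  }
  transition <- as.matrix(transition)
  if (nrow(transition) != K || ncol(transition) != K ||
      any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-10)) {
    stop_fmt("transition must be a K x K row-stochastic matrix")
  }
  if (is.null(state_covariances)) {
    state_covariances <- default_state_covariances(n_rois, K, seed)
  }
  if (!identical(dim(state_covariances), as.integer(c(K, n_rois, n_rois)))) {
    stop_fmt("state_covariances must be K x R x R")
  }
  for (k in seq_len(K)) {
    ev <- eigen(state_covariances[k, , ], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0) stop_fmt("state covariance %d is not SPD", k)
  }
  if (is.null(state_means)) state_means <- matrix(0, K, n_rois)
  state_means <- as.matrix(state_means)
  if (!all(dim(state_means) == c(K, n_rois))) {
    stop_fmt("state_means must be K x R")
  }
  if (observation_noise_sd < 0) stop_fmt("observation_noise_sd must be >= 0")
  rsn_partition <- rsn_partition %||% default_partition(n_rois, 3)
  idx <- sort(as.integer(unlist(rsn_partition, use.names = FALSE)))
  if (!identical(idx, seq_len(n_rois))) {
    stop_fmt("rsn_partition must cover all ROIs exactly once")
  }
  structure(
    list(n_subjects = n_subjects, n_timepoints = n_timepoints,
         n_rois = n_rois, tr_seconds = tr_seconds, K = K,
         transition = transition, state_covariances = state_covariances,
         state_means = state_means,
         observation_noise_sd = observation_noise_sd,
         rsn_partition = rsn_partition, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Activation-pattern variant of the synthetic spec
#'
#' States differ by mean activity patterns (first-order structure, as
#' captured by CAP and the window-less method) rather than covariance:
#' state means are `amplitude` times K unit patterns at equal angles in an
#' orthogonal sign-vector plane (so they sum to ~0 and survive
#' z-standardization), with identity covariance.
#'
#' @inheritParams synthetic_spec
#' @param amplitude Activation amplitude in noise-sd units (default 3).
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_activation <- function(n_subjects = 10, n_timepoints = 1200,
                                      n_rois = 12, K = 3, amplitude = 3,
                                      seed = 1L, ...) {
  patterns <- activation_patterns(n_rois, K)
  covs <- array(0, c(K, n_rois, n_rois))
  for (k in seq_len(K)) covs[k, , ] <- diag(n_rois)
  synthetic_spec(n_subjects = n_subjects, n_timepoints = n_timepoints,
                 n_rois = n_rois, K = K,
                 state_covariances = covs,
                 state_means = amplitude * patterns, seed = seed, ...)
}

stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

simulate_chain <- function(Tn, P, init) {
  K <- nrow(P)
  labels <- integer(Tn)
  labels[1] <- sample.int(K, 1, prob = init)
  for (t in 2:Tn) {
    labels[t] <- sample.int(K, 1, prob = P[labels[t - 1], ])
  }
  labels
}

spec_labels <- function(spec) {
  R <- spec$n_rois
  rsn <- character(R)
  for (i in seq_along(spec$rsn_partition)) {
    rsn[spec$rsn_partition[[i]]] <- paste0("RSN", i)
  }
  list(roi = sprintf("ROI%03d", seq_len(R)), rsn = rsn,
       hemi = rep(c("L", "R"), length.out = R))
}

#' Generate Markov-switching multi-subject BOLD data
#'
#' For each subject, simulates the planted state chain from its stationary
#' distribution and draws each TR from the active state's Gaussian (mean,
#' covariance), plus optional isotropic observation noise. Deterministic
#' given `spec$seed`; the hidden state sequences are returned as ground
#' truth.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ts_list` (list of [parcellated_ts()]), `labels_list`
#'   (list of integer state sequences), and `spec`.
#' @export
generate_markov_bold <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$K
  R <- spec$n_rois
  Tn <- spec$n_timepoints
  init <- stationary_distribution(spec$transition)
  chols <- lapply(seq_len(K), function(k) chol(spec$state_covariances[k, , ]))
  lab <- spec_labels(spec)
  ts_list <- vector("list", spec$n_subjects)
  labels_list <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, s))
    labels <- simulate_chain(Tn, spec$transition, init)
    Z <- matrix(stats::rnorm(Tn * R), Tn, R)
    X <- matrix(0, Tn, R)
    for (k in seq_len(K)) {
      rows <- labels == k
      if (!any(rows)) next
      X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[k]]
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                         spec$state_means[k, ], "+")
    }
    if (spec$observation_noise_sd > 0) {
      X <- X + spec$observation_noise_sd * matrix(stats::rnorm(Tn * R), Tn, R)
    }
    ts_list[[s]] <- parcellated_ts(X, spec$tr_seconds,
                                   subject_id = sprintf("sub%03d", s),
                                   roi_labels = lab$roi,
                                   rsn_labels = lab$rsn,
                                   hemisphere = lab$hemi)
    labels_list[[s]] <- labels
  }
  list(ts_list = ts_list, labels_list = labels_list, spec = spec)
}

#' Generate stationary (single-state) BOLD data
#'
#' The stationarity null: a single Gaussian regime throughout, used to
#' check that state-free dFC estimates fluctuate only within sampling error
#' and that state-based methods see no recurring structure.
#'
#' @param spec A [synthetic_spec()]; only its first state is used.
#' @return As [generate_markov_bold()]; all ground-truth labels are 1.
#' @export
generate_stationary_bold <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec1 <- synthetic_spec(
    n_subjects = spec$n_subjects, n_timepoints = spec$n_timepoints,
    n_rois = spec$n_rois, tr_seconds = spec$tr_seconds, K = 1,
    transition = matrix(1, 1, 1),
    state_covariances = spec$state_covariances[1, , , drop = FALSE],
    state_means = spec$state_means[1, , drop = FALSE],
    observation_noise_sd = spec$observation_noise_sd,
    rsn_partition = spec$rsn_partition, seed = spec$seed)
  generate_markov_bold(spec1)
}

#' Synthetic seven-method dFC array with planted method groups
#'
#' Builds a dFC array whose seven "methods" share block-wise latent dFC
#' signals in a planted \{3, 2, 2\} partition plus independent noise, for
#' end-to-end testing of the similarity and grouping pipeline. The planted
#' partition is attached as attribute `planted_groups`.
#'
#' @param seed Integer seed.
#' @param n_subjects,n_timepoints,n_rois Array dimensions (defaults 5, 38,
#'   12).
#' @param noise_sd Independent per-method noise sd relative to the
#'   unit-variance latent signal (default 0.2).
#' @return A [dfc_array()] with 7 methods.
#' @export
make_method_group_fixture <- function(seed = 1L, n_subjects = 5,
                                      n_timepoints = 38, n_rois = 12,
                                      noise_sd = 0.2) {
  set.seed(as.integer(seed))
  S <- n_subjects; Tn <- n_timepoints; R <- n_rois
  C <- R * (R - 1) / 2
  blocks <- list(c(1L, 2L, 3L), c(4L, 5L), c(6L, 7L))
  vals <- array(0, c(S, 7, Tn, R, R))
  for (s in seq_len(S)) {
    latent <- lapply(blocks, function(b) matrix(stats::rnorm(Tn * C), Tn, C))
    for (bi in seq_along(blocks)) {
      for (m in blocks[[bi]]) {
        v <- latent[[bi]] + noise_sd * matrix(stats::rnorm(Tn * C), Tn, C)
        for (t in seq_len(Tn)) {
          vals[s, m, t, , ] <- devectorize_lower_triangle(v[t, ], diag = 1)
        }
      }
    }
  }
  lab <- spec_labels(synthetic_spec(n_subjects = S, n_timepoints = Tn,
                                    n_rois = R, seed = seed))
  arr <- dfc_array(vals, sprintf("sub%03d", seq_len(S)), DFC_METHODS,
                   seq_len(Tn), lab$roi, lab$rsn, check_symmetry = FALSE)
  attr(arr, "planted_groups") <- rep(seq_along(blocks),
                                     lengths(blocks))[order(unlist(blocks))]
  arr
}
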