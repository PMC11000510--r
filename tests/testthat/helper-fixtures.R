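# Shared fixtures and independent oracles for the test suite. All fixtures
# are built in code; nothing is read from disk except roundtrip temp files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- small atlas / time-series builders --------------------------------------

make_test_atlas <- function(R = 6, rsns = NULL) {
  rsns <- rsns %||% rep(paste0("RSN", seq_len(max(1, R %/% 4))),
                        length.out = R)
  atlas_table(sprintf("ROI%03d", seq_len(R)), rsns,
              rep(c("L", "R"), length.out = R))
}

# Atlas emulating a 333-parcel whole-brain parcellation: 12 networks
# totalling 286 assigned ROIs (hemisphere-balanced) plus 47 unassigned.
make_parcellation_atlas <- function() {
  pair_sizes <- c(30, 24, 20, 18, 16, 12, 8, 6, 4, 3, 1, 1)  # pairs per RSN
  stopifnot(sum(pair_sizes) * 2 == 286)
  rsn <- character(0)
  hemi <- character(0)
  for (i in seq_along(pair_sizes)) {
    rsn <- c(rsn, rep(paste0("RSN", i), 2 * pair_sizes[i]))
    hemi <- c(hemi, rep(c("L", "R"), pair_sizes[i]))
  }
  rsn <- c(rsn, rep("None", 47))
  hemi <- c(hemi, rep(c("L", "R"), length.out = 47))
  atlas_table(sprintf("ROI%03d", seq_along(rsn)), rsn, hemi)
}

make_test_ts <- function(T = 100, R = 6, seed = 1, tr = 0.72) {
  set.seed(seed)
  at <- make_test_atlas(R)
  parcellated_ts(matrix(rnorm(T * R), T, R), tr,
                 subject_id = sprintf("sub%02d", seed),
                 roi_labels = at$roi_id, rsn_labels = at$rsn_label,
                 hemisphere = at$hemisphere)
}

# -- oracles -----------------------------------------------------------------

# Brute-force plain Pearson correlation of one window segment.
oracle_segment_corr <- function(X, start, W) {
  stats::cor(X[start:(start + W - 1), , drop = FALSE])
}

# Stationary distribution of a row-stochastic matrix via eigen-decomposition.
oracle_stationary <- function(P) {
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v / sum(v)
}

# Hungarian-matched mean lower-triangle correlation between estimated and
# planted state FC arrays; returns the permutation too.
match_state_fc <- function(est_fc, true_fc) {
  K <- dim(est_fc)[1]
  cmat <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      cmat[i, j] <- stats::cor(vectorize_lower_triangle(est_fc[i, , ]),
                               vectorize_lower_triangle(true_fc[j, , ]))
    }
  }
  p <- match_states(1 - cmat)
  list(perm = p, mean_corr = mean(cmat[cbind(seq_len(K), p)]))
}

# Hungarian-matched mean |cosine| between row-vector sets.
match_cosine <- function(est, ref) {
  est <- est / sqrt(rowSums(est^2))
  ref <- ref / sqrt(rowSums(ref^2))
  cm <- abs(est %*% t(ref))
  p <- match_states(1 - cm)
  list(perm = p, mean_cos = mean(cm[cbind(seq_len(nrow(cm)), p)]))
}

label_accuracy <- function(est_labels, true_labels, perm) {
  mean(perm[est_labels] == true_labels)
}

# Planted state of each sliding window: the state with the largest
# taper-weighted occupancy inside the window (the taper defines each TR's
# contribution to the window estimate).
window_true_labels <- function(labels, window, K) {
  W <- length(window$weights)
  step <- window$step_tr
  nw <- (length(labels) - W) %/% step + 1
  vapply(seq_len(nw), function(i) {
    seg <- labels[(1 + (i - 1) * step):((i - 1) * step + W)]
    occ <- vapply(seq_len(K), function(k) sum(window$weights[seg == k]),
                  numeric(1))
    which.max(occ)
  }, integer(1))
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
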