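# The five state-based estimators and the group-fit / subject-apply contract.

test_that("two-level k-means recovers planted point clouds", {
  for (seed in 1:5) {
    set.seed(1000 + seed)
    mu1 <- c(5, 0, 0); mu2 <- c(-5, 0, 0)
    mk_subject <- function() {
      n <- 40
      lab <- rep(1:2, each = n / 2)
      X <- rbind(matrix(rnorm(n / 2 * 3, sd = 0.3), ncol = 3),
                 matrix(rnorm(n / 2 * 3, sd = 0.3), ncol = 3))
      X[lab == 1, ] <- sweep(X[lab == 1, ], 2, mu1, "+")
      X[lab == 2, ] <- sweep(X[lab == 2, ], 2, mu2, "+")
      list(X = X, lab = lab)
    }
    subs <- list(mk_subject(), mk_subject())
    km <- two_level_kmeans(lapply(subs, `[[`, "X"), k_subject = 2,
                           k_group = 2, seed = seed)
    mc <- match_cosine(km$centers, rbind(mu1, mu2))
    d <- km$centers[order(km$centers[, 1], decreasing = TRUE), ]
    expect_lt(max(abs(d - rbind(mu1, mu2))), 0.1)
    # labels match planted membership after permutation matching
    for (s in 1:2) {
      acc <- max(mean(km$labels[[s]] == subs[[s]]$lab),
                 mean(3 - km$labels[[s]] == subs[[s]]$lab))
      expect_gt(acc, 0.99)
    }
  }

  # degenerate input: all samples identical -> one occupied group label
  same <- matrix(1, 30, 3)
  km0 <- two_level_kmeans(list(same, same), k_subject = 3, k_group = 2,
                          seed = 1)
  expect_length(unique(unlist(km0$labels)), 1)

  expect_error(two_level_kmeans(list(matrix(rnorm(9), 3, 3)),
                                k_subject = 2, k_group = 5, seed = 1),
               "exceeds")
})

test_that("CAP states are rank-1 outer products that recover planted patterns", {
  spec <- synthetic_spec_activation(n_subjects = 4, n_timepoints = 400,
                                    n_rois = 12, K = 2, amplitude = 3,
                                    seed = 21)
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  fit <- cap_fit(tsl, K = 2, k_subject = 10, seed = 31)

  for (k in seq_len(fit$state_set$K)) {
    S <- fit$state_set$state_fc[k, , ]
    expect_symmetric(S)
    expect_equal(qr(S)$rank, 1)
    expect_equal(sum(diag(S)), sum(fit$centers[k, ]^2), tolerance = 1e-10)
  }
  mc <- match_cosine(fit$centers, spec$state_means)
  expect_gt(mc$mean_cos, 0.95)
})

test_that("SWC clusters window FC features of the expected length", {
  spec <- synthetic_spec(n_subjects = 3, n_timepoints = 300, n_rois = 8,
                         seed = 22)
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  win <- make_tapered_window(40, 3, 20)
  fit <- swc_fit(tsl, K = 3, k_subject = 5, window = win, seed = 32)
  expect_equal(ncol(fit$centers), 8 * 7 / 2)
  expect_equal(diag(fit$state_set$state_fc[1, , ]), rep(1, 8))
  # labels live on the window grid
  expect_equal(fit$timecourses[[1]]$time_stamps,
               sliding_window_grid(300, win))

  # degenerate case: period == step makes every window identical -> one
  # occupied state
  periodic <- rep(sin(2 * pi * seq_len(20) / 20), 15)  # bitwise periodic
  const <- parcellated_ts(matrix(rep(periodic, 4), 300, 4), 0.72)
  fitc <- swc_fit(list(z_standardize(const)), K = 2, k_subject = 3,
                  window = win, seed = 33)
  fo <- fitc$timecourses[[1]]$fractional_occupancy
  expect_gt(max(fo), 0.99)
})

test_that("Gaussian HMM recovers a planted 2-state chain and its covariances", {
  spec <- synthetic_spec(n_subjects = 2, n_timepoints = 800, n_rois = 6,
                         K = 2, seed = 23,
                         state_covariances = local({
                           a <- array(0, c(2, 6, 6))
                           a[1, , ] <- make_block_covariance(
                             list(1:3, 4:6), 0.8, 0)
                           a[2, , ] <- make_block_covariance(
                             list(c(1, 4), c(2, 5), c(3, 6)), 0.8, 0)
                           a
                         }))
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  fit <- chmm_fit(tsl, K = 2, seed = 41)
  expect_true(all(abs(rowSums(fit$model$transition) - 1) < 1e-10))
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit$model$loglik) > -1e-6))

  ms <- match_state_fc(fit$state_set$state_fc, spec$state_covariances)
  expect_gt(ms$mean_corr, 0.9)
  acc <- label_accuracy(unlist(lapply(fit$timecourses, `[[`, "labels")),
                        unlist(sim$labels_list), ms$perm)
  expect_gt(acc, 0.9)
})

test_that("Gaussian HMM on single-regime data pools toward the sample covariance", {
  spec1 <- synthetic_spec(n_subjects = 2, n_timepoints = 600, n_rois = 5,
                          K = 1, transition = matrix(1, 1, 1),
                          state_covariances = local({
                            a <- array(0, c(1, 5, 5))
                            a[1, , ] <- make_block_covariance(
                              list(1:2, 3:5), 0.6, 0.1)
                            a
                          }), seed = 24)
  sim <- generate_stationary_bold(spec1)
  Xl <- lapply(sim$ts_list, `[[`, "values")
  Xall <- do.call(rbind, Xl)
  n <- nrow(Xall)
  S <- stats::cov(Xall) * (n - 1) / n
  fit <- gaussian_hmm_fit(Xl, K = 2, seed = 42)
  # law of total covariance at the EM stationary point: the
  # occupancy-weighted mixture moment reproduces the sample covariance
  vit <- unlist(lapply(Xl, function(X) gaussian_hmm_viterbi(fit, X)))
  w <- tabulate(vit, 2) / length(vit)
  mu_bar <- colSums(fit$means * w)
  mix <- Reduce(`+`, lapply(1:2, function(k) {
    w[k] * (fit$covariances[k, , ] + tcrossprod(fit$means[k, ]))
  })) - tcrossprod(mu_bar)
  expect_lt(norm(mix - S, "F"), 0.05 * norm(S, "F"))
  # and neither redundant state wanders far from the shared covariance
  for (k in 1:2) {
    expect_lt(norm(fit$covariances[k, , ] - S, "F"), 0.35 * norm(S, "F"))
  }
})

test_that("categorical HMM decodes deterministic structure", {
  # period-2 observation sequence, K = 2 -> period-2 hidden path
  obs <- rep(c(1L, 2L), 60)
  fit <- categorical_hmm_fit(list(obs), K = 2, n_obs = 2, seed = 51)
  expect_true(all(abs(rowSums(fit$transition) - 1) < 1e-10))
  expect_true(all(abs(rowSums(fit$emission) - 1) < 1e-10))
  path <- categorical_hmm_viterbi(fit, obs)
  expect_length(unique(path[seq(1, 120, 2)]), 1)
  expect_length(unique(path[seq(2, 120, 2)]), 1)
  expect_false(path[1] == path[2])
})

test_that("DHMM state FC matrices average their assigned window slices", {
  spec <- synthetic_spec(n_subjects = 3, n_timepoints = 300, n_rois = 6,
                         seed = 25)
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  win <- make_tapered_window(40, 3, 20)
  fit <- dhmm_fit(tsl, K = 3, k_subject = 5, window = win, seed = 52)
  expect_equal(fit$state_set$meta$n_obs, 2)  # round(3 * 16/24)

  # defining property: each state FC equals the mean of the
  # clustering-stage dFC slices assigned to that hidden state (a state
  # holding a single window equals that window's FC exactly)
  K <- fit$state_set$K
  R <- 6
  sums <- array(0, c(K, R, R)); counts <- integer(K)
  for (s in seq_along(tsl)) {
    h <- fit$timecourses[[s]]$labels
    for (t in seq_along(h)) {
      sums[h[t], , ] <- sums[h[t], , ] + fit$swc$dfc[[s]]$values[t, , ]
      counts[h[t]] <- counts[h[t]] + 1L
    }
  }
  for (k in seq_len(K)) {
    if (counts[k] == 0) next
    expect_equal(fit$state_set$state_fc[k, , ], sums[k, , ] / counts[k],
                 tolerance = 1e-12)
  }
  # labels on the window grid
  expect_equal(fit$timecourses[[1]]$time_stamps,
               sliding_window_grid(300, win))
})

test_that("k-SVD learns unit-norm atoms with monotone objective", {
  set.seed(26)
  # planted dictionary: two orthogonal atoms, samples = +/- atom + noise
  d1 <- c(1, 1, 1, 1, 0, 0, 0, 0) / 2
  d2 <- c(0, 0, 0, 0, 1, -1, 1, -1) / 2
  n <- 200
  lab <- sample(1:2, n, replace = TRUE)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  X <- t(vapply(seq_len(n), function(i) {
    3 * sgn[i] * (if (lab[i] == 1) d1 else d2) + 0.1 * rnorm(8)
  }, numeric(8)))
  fit <- ksvd_fit(X, K = 2, seed = 61)
  expect_true(all(abs(sqrt(colSums(fit$D^2)) - 1) < 1e-10))
  expect_true(all(diff(fit$objective) <= 1e-8))
  mc <- match_cosine(t(fit$D), rbind(d1, d2))
  expect_gt(mc$mean_cos, 0.99)
  # recovered labels match the planted atom assignment
  acc <- max(mean(mc$perm[fit$labels] == lab))
  expect_gt(acc, 0.99)
})

test_that("WL states are unit-trace rank-1 matrices", {
  spec <- synthetic_spec_activation(n_subjects = 2, n_timepoints = 300,
                                    n_rois = 12, K = 2, seed = 27)
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  fit <- wl_fit(tsl, K = 2, seed = 62)
  for (k in 1:2) {
    S <- fit$state_set$state_fc[k, , ]
    expect_equal(sum(diag(S)), 1, tolerance = 1e-10)
    expect_equal(qr(S)$rank, 1)
  }
})

test_that("apply_states reproduces fit-time labels and builds state dFC", {
  spec <- synthetic_spec(n_subjects = 3, n_timepoints = 300, n_rois = 6,
                         seed = 28)
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  win <- make_tapered_window(40, 3, 20)

  fits <- list(cap = cap_fit(tsl, K = 3, k_subject = 5, seed = 71),
               swc = swc_fit(tsl, K = 3, k_subject = 5, window = win,
                             seed = 71),
               wl = wl_fit(tsl, K = 3, seed = 71),
               chmm = chmm_fit(tsl, K = 3, seed = 71),
               dhmm = dhmm_fit(tsl, K = 3, k_subject = 5, window = win,
                               seed = 71))
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    app <- apply_states(fit, tsl[[2]])
    if (nm %in% c("cap", "swc", "wl")) {
      # centroid/atom assignment is exactly reproducible
      expect_identical(app$timecourse$labels, fit$timecourses[[2]]$labels)
    }
    # the dFC holds at most K distinct slices, each equal to one state FC
    flat <- vectorize_dfc(app$dfc)
    expect_lte(nrow(unique(flat)), fit$state_set$K)
    for (t in c(1, nrow(flat))) {
      k <- app$timecourse$labels[t]
      expect_equal(app$dfc$values[t, , ], fit$state_set$state_fc[k, , ])
    }
    # per-TR grids for CAP/CHMM/WL; window grid for SWC/DHMM
    expected_T <- if (nm %in% c("swc", "dhmm")) {
      length(sliding_window_grid(300, win))
    } else 300
    expect_equal(dim(app$dfc$values)[1], expected_T)
  }

  wrong_R <- make_test_ts(T = 300, R = 9, seed = 1)
  expect_error(apply_states(fits$cap, z_standardize(wrong_R)), "ROIs")
})

test_that("fractional occupancy matches counts and chain stationarity", {
  expect_equal(fractional_occupancy(c(1, 1, 2, 2), 2), c(0.5, 0.5))
  expect_equal(fractional_occupancy(rep(3, 6), 4), c(0, 0, 1, 0))
  expect_error(fractional_occupancy(c(1, 5), 4), "out of range")

  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  spec <- synthetic_spec(n_subjects = 1, n_timepoints = 10000, n_rois = 4,
                         K = 2, transition = P,
                         state_covariances = local({
                           a <- array(0, c(2, 4, 4))
                           a[1, , ] <- diag(4)
                           a[2, , ] <- make_block_covariance(list(1:2, 3:4),
                                                             0.8, 0)
                           a
                         }), seed = 29)
  sim <- generate_markov_bold(spec)
  fo <- fractional_occupancy(sim$labels_list[[1]], 2)
  expect_equal(sum(fo), 1, tolerance = 1e-12)
  expect_lt(max(abs(fo - oracle_stationary(P))), 0.05)
})

test_that("state-based fits are bit-reproducible under a fixed seed", {
  spec <- synthetic_spec(n_subjects = 2, n_timepoints = 200, n_rois = 6,
                         seed = 30)
  sim <- generate_markov_bold(spec)
  tsl <- lapply(sim$ts_list, z_standardize)
  win <- make_tapered_window(40, 3, 20)
  a <- swc_fit(tsl, K = 2, k_subject = 4, window = win, seed = 81)
  b <- swc_fit(tsl, K = 2, k_subject = 4, window = win, seed = 81)
  expect_identical(a$state_set$state_fc, b$state_set$state_fc)
  expect_identical(lapply(a$timecourses, `[[`, "labels"),
                   lapply(b$timecourses, `[[`, "labels"))
})
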