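# Similarity levels, metrics, method grouping, variance decomposition, and
# the time-shuffled null.

# small helper: dFC array from a list-of-lists of T x C feature matrices
arr_from_features <- function(feats, R) {
  S <- length(feats); M <- length(feats[[1]]); Tn <- nrow(feats[[1]][[1]])
  vals <- array(0, c(S, M, Tn, R, R))
  for (s in seq_len(S)) {
    for (m in seq_len(M)) {
      for (t in seq_len(Tn)) {
        vals[s, m, t, , ] <- devectorize_lower_triangle(feats[[s]][[m]][t, ],
                                                        diag = 1)
      }
    }
  }
  dfc_array(vals, paste0("s", seq_len(S)), DFC_METHODS[seq_len(M)],
            seq_len(Tn), check_symmetry = FALSE)
}

test_that("similarity identities: self = 1, symmetry, monotone invariance", {
  set.seed(40)
  R <- 6; C <- R * (R - 1) / 2; Tn <- 10
  base <- lapply(1:3, function(s) {
    X <- matrix(rnorm(Tn * C), Tn, C)
    list(X, exp(X), matrix(rnorm(Tn * C), Tn, C))  # m2 = monotone(m1)
  })
  arr <- arr_from_features(base, R)
  for (fun in list(overall_similarity, spatial_similarity,
                   temporal_similarity)) {
    for (metric in c("spearman", "pearson")) {
      sim <- fun(arr, metric)
      expect_equal(diag(sim$matrix), rep(1, 3), ignore_attr = TRUE)
      expect_symmetric(sim$matrix, tol = 1e-12)
      expect_true(all(sim$matrix >= -1 - 1e-12 & sim$matrix <= 1 + 1e-12))
    }
  }
  # Spearman is blind to the monotone transform, Pearson is not
  ov_s <- overall_similarity(arr, "spearman")
  expect_equal(ov_s$matrix[1, 2], 1)
  ov_p <- overall_similarity(arr, "pearson")
  expect_lt(ov_p$matrix[1, 2], 1)
  # euclidean: zero diagonal, nonnegative entries
  ov_e <- overall_similarity(arr, "euclidean")
  expect_equal(diag(ov_e$matrix), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(ov_e$matrix >= 0))
})

test_that("independent noise methods show near-zero overall similarity", {
  set.seed(41)
  R <- 8; C <- R * (R - 1) / 2
  feats <- lapply(1:4, function(s) {
    lapply(1:3, function(m) matrix(runif(38 * C), 38, C))
  })
  arr <- arr_from_features(feats, R)
  ov <- overall_similarity(arr, "spearman")
  off <- ov$matrix[upper.tri(ov$matrix)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("spatial similarity sees sign flips and per-slice agreement", {
  set.seed(42)
  R <- 5; C <- 10; Tn <- 6
  X <- matrix(rnorm(Tn * C), Tn, C)
  arr <- arr_from_features(list(list(X, -X)), R)
  sp <- spatial_similarity(arr, "pearson")
  expect_equal(sp$matrix[1, 2], -1, tolerance = 1e-12)
  sp2 <- spatial_similarity(arr_from_features(list(list(X, X)), R), "spearman")
  expect_equal(sp2$matrix[1, 2], 1, tolerance = 1e-12)
})

test_that("temporal similarity detects reversal and excludes flat connections", {
  Tn <- 9; C <- 6; R <- 4
  mono <- matrix(rep(seq_len(Tn), C), Tn, C) * rep(1:C, each = Tn)
  rev_mono <- mono[Tn:1, ]
  arr <- arr_from_features(list(list(mono, rev_mono)), R)
  tm <- suppressWarnings(temporal_similarity(arr, "spearman"))
  expect_equal(tm$matrix[1, 2], -1, tolerance = 1e-12)

  # a zero-variance connection is excluded, not imputed
  flat <- mono
  flat[, 3] <- 5
  arr2 <- arr_from_features(list(list(mono, flat)), R)
  tm2 <- suppressWarnings(temporal_similarity(arr2, "spearman"))
  expect_gt(tm2$n_excluded, 0)
  expect_equal(tm2$matrix[1, 2], 1, tolerance = 1e-12)  # remaining connections agree
})

test_that("spatial and temporal similarity dissociate under slice shuffling", {
  set.seed(43)
  R <- 8; C <- R * (R - 1) / 2; Tn <- 30
  A <- matrix(rnorm(Tn * C), Tn, C)
  B <- t(apply(A, 1, sample))  # same values per slice, shuffled over connections
  arr <- arr_from_features(list(list(A, B)), R)
  tm <- suppressWarnings(temporal_similarity(arr, "spearman"))
  expect_lt(abs(tm$matrix[1, 2]), 0.15)
  # the per-slice value multisets are identical: sorted slices match exactly
  for (t in seq_len(Tn)) expect_equal(sort(A[t, ]), sort(B[t, ]))
})

test_that("intersubject similarity compares intersubject-correlation vectors", {
  set.seed(44)
  R <- 6; C <- 15; Tn <- 8; S <- 5
  feats <- lapply(seq_len(S), function(s) {
    X <- matrix(rnorm(Tn * C), Tn, C)
    list(X, X + 1e-8 * matrix(rnorm(Tn * C), Tn, C))
  })
  arr <- arr_from_features(feats, R)
  is_sim <- intersubject_similarity(arr, "spearman")
  expect_equal(ncol(is_sim$intersubj), S * (S - 1) / 2)
  expect_equal(is_sim$matrix[1, 2], 1, tolerance = 1e-6)
  # full-scale count follows the same formula
  expect_equal(choose(395, 2), 77815)
  expect_error(intersubject_similarity(arr_from_features(
    feats[1:2], R), "spearman"), "3 subjects")

  # methods with independent intersubject structure: similarity near zero
  set.seed(45)
  S2 <- 30
  fo_feats <- lapply(1:3, function(m) matrix(runif(S2 * 40), S2, 40))
  arr_small <- arr_from_features(lapply(seq_len(S2), function(s) {
    lapply(1:3, function(m) matrix(0.5 + 1e-6 * rnorm(2 * C), 2, C))
  }), R)
  is2 <- intersubject_similarity(arr_small, "spearman", features = fo_feats)
  expect_lt(max(abs(is2$matrix[upper.tri(is2$matrix)])), 0.1)
})

test_that("mutual information metric has the analytic identity and null behavior", {
  set.seed(46)
  x <- rnorm(1000)
  expect_equal(mutual_information_metric(x, x), log2(10), tolerance = 1e-9)
  y <- rnorm(1000)
  expect_equal(mutual_information_metric(x, y),
               mutual_information_metric(y, x))
  big_x <- rnorm(10000)
  big_y <- rnorm(10000)
  expect_lt(mutual_information_metric(big_x, big_y), 0.02)
  expect_warning(mutual_information_metric(rnorm(20), rnorm(20)), "unstable")
})

test_that("Ward grouping at the 0.7 cutoff recovers planted blocks", {
  blocks <- rep(1:3, c(3, 2, 2))
  sim <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0.2))
  diag(sim) <- 1
  dimnames(sim) <- list(DFC_METHODS, DFC_METHODS)
  g <- group_methods(sim, metric = "spearman")
  expect_equal(g$n_groups, 3)
  expect_equal(unname(g$groups[1:3]), rep(g$groups[[1]], 3))
  expect_equal(length(unique(g$groups[4:5])), 1)
  expect_equal(length(unique(g$groups[6:7])), 1)
  expect_equal(g$cutoff, 0.7 * max(g$tree$height))

  # all similarities equal -> a single group
  flat <- matrix(0.5, 7, 7); diag(flat) <- 1
  g1 <- group_methods(flat, metric = "spearman")
  expect_equal(g1$n_groups, 1)

  # planted partitions with identifiable (size >= 2) blocks are recovered
  set.seed(47)
  for (sizes in list(c(5, 2), c(2, 2, 3), c(4, 3), c(3, 2, 2))) {
    bl <- rep(seq_along(sizes), sizes)
    m <- outer(bl, bl, function(a, b) ifelse(a == b, 0.9, 0.1))
    diag(m) <- 1
    gg <- group_methods(m, metric = "spearman")
    expect_equal(gg$n_groups, length(sizes))
  }

  bad <- sim; bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(group_methods(bad, metric = "spearman"), "NaN")
})

test_that("variance decomposition: degenerate and exchangeable nulls", {
  set.seed(48)
  R <- 6; C <- 15; Tn <- 12
  # all methods identical -> var over method is exactly 0
  X <- matrix(rnorm(Tn * C), Tn, C)
  arr_same <- arr_from_features(list(list(X, X, X)), R)
  vd <- variance_decomposition(arr_same)
  expect_true(all(vd$var_method == 0))
  expect_equal(vd$mean_var_ratio_method_time, 0)

  # methods as independent permutations of one multiset per connection:
  # variance over methods matches variance over time in expectation
  ratios <- vapply(1:5, function(seed) {
    set.seed(seed)
    feats <- list(lapply(1:6, function(m) {
      apply(X, 2, sample)
    }))
    vdp <- variance_decomposition(arr_from_features(feats, R))
    vdp$mean_var_ratio_method_time
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)

  expect_error(variance_decomposition(arr_from_features(
    list(list(X)), R)), "single method")
})

test_that("RSN-pair variance aggregation averages before the ratio", {
  set.seed(49)
  R <- 6
  Tn <- 10
  rsn <- rep(c("A", "B"), each = 3)
  vals <- array(0, c(1, 2, Tn, R, R))
  for (m in 1:2) for (t in seq_len(Tn)) {
    a <- matrix(rnorm(R * R), R, R)
    vals[1, m, t, , ] <- (a + t(a)) / 2
  }
  arr <- dfc_array(vals, "s1", c("SW", "TF"), seq_len(Tn),
                   rsn_labels = rsn, check_symmetry = FALSE)
  vd <- variance_decomposition(arr)
  expect_equal(dim(vd$rsn_ratio_minus1), c(2L, 2L))
  expect_symmetric(vd$rsn_ratio_minus1, tol = 1e-12)
  # ratio - 1 is zero-centered by construction of the statistic:
  # reconstruct one cell from the parts
  pairs <- which(lower.tri(matrix(0, R, R)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  sel <- rsn[pairs[, 1]] == "A" & rsn[pairs[, 2]] == "A"
  manual <- mean(vd$var_method[, sel]) / mean(vd$var_time[, sel]) - 1
  expect_equal(vd$rsn_ratio_minus1["A", "A"], manual)
})

test_that("time-shuffled null preserves occupancy and uses add-one p-values", {
  set.seed(50)
  R <- 5; C <- 10; Tn <- 8
  X <- matrix(rnorm(Tn * C), Tn, C)
  arr <- arr_from_features(list(list(X, X)), R)
  res <- time_shuffle_null(arr, n_perm = 99, seed = 7)
  expect_equal(res$observed[1, 2], 1)
  # identical arrays, distinct slices: no null draw reaches the observed 1
  expect_equal(res$p[1, 2], 1 / 100)

  # a pure time permutation preserves fractional occupancy exactly
  labels <- c(1, 1, 2, 3, 2, 1, 3, 3)
  fo <- fractional_occupancy(labels, 3)
  set.seed(1)
  for (i in 1:20) {
    expect_equal(fractional_occupancy(sample(labels), 3), fo)
  }

  # constant-in-time arrays: the null is degenerate at the observed value
  Xc <- matrix(rep(rnorm(C), each = Tn), Tn, C)
  arrc <- arr_from_features(list(list(Xc, Xc + 0.1)), R)
  resc <- time_shuffle_null(arrc, n_perm = 20, seed = 8)
  expect_true(all(abs(resc$null[, 1, 2] - resc$observed[1, 2]) < 1e-12))
})
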