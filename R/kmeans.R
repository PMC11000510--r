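# Seeded k-means with k-means++ initialization and the two-stage
# (subject-level then group-level) clustering shared by CAP and SWC.

# k-means++ seeding; assumes the RNG state is already set by the caller.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (i in seq_len(k)[-1]) {
    if (all(d2 <= 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[i, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[i, ])^2))
  }
  centers
}

# Deterministic-given-RNG-state k-means: k-means++ seeding, n restarts,
# best total within-cluster sum of squares kept.
kmeans_seeded <- function(X, k, nstart = 10, iter_max = 100) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) k <- n_distinct
  if (k == 1) {
    ctr <- matrix(colMeans(X), 1, ncol(X))
    return(list(centers = ctr, cluster = rep(1L, nrow(X)), k = 1L))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    ctr <- kmeanspp_centers(X, k)
    ctr <- unique(ctr)
    if (nrow(ctr) < k) next
    fit <- tryCatch(
      stats::kmeans(X, centers = ctr, iter.max = iter_max),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(X, centers = ctr, iter.max = iter_max))
      })
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop_fmt("k-means failed for k = %d", k)
  list(centers = best$centers, cluster = best$cluster, k = k)
}

nearest_center <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Two-stage (subject-level, then group-level) k-means
#'
#' Stage 1 clusters each subject's samples into `k_subject` centroids;
#' stage 2 clusters the pooled subject centroids into `k_group` group
#' centroids; finally every original sample is assigned to its nearest group
#' centroid (Euclidean). Subjects with fewer samples than `k_subject` use
#' their sample count instead (with a warning). Deterministic given `seed`.
#'
#' @param sample_list List (one element per subject) of sample matrices,
#'   rows = samples.
#' @param k_subject Subject-level cluster count (default 20).
#' @param k_group Group-level cluster count (default 12).
#' @param seed Integer seed.
#' @return List with `centers` (k_group x P), `labels` (list of per-subject
#'   integer vectors), and `subject_centers`.
#' @export
two_level_kmeans <- function(sample_list, k_subject = 20, k_group = 12,
                             seed = 1L) {
  stopifnot(is.list(sample_list), length(sample_list) >= 1)
  set.seed(as.integer(seed))
  subject_centers <- vector("list", length(sample_list))
  for (s in seq_along(sample_list)) {
    X <- as.matrix(sample_list[[s]])
    ks <- k_subject
    if (nrow(X) < k_subject) {
      warn_fmt("subject %d has %d samples < k_subject = %d; lowering",
               s, nrow(X), k_subject)
      ks <- nrow(X)
    }
    ctr <- kmeans_seeded(X, ks)$centers
    # duplicate samples can shrink the centroid set; pad by repetition so
    # the pooled size keeps the structural contract
    if (nrow(ctr) < ks) {
      ctr <- ctr[rep_len(seq_len(nrow(ctr)), ks), , drop = FALSE]
    }
    subject_centers[[s]] <- ctr
  }
  pooled <- do.call(rbind, subject_centers)
  if (k_group > nrow(pooled)) {
    stop_fmt("k_group (%d) exceeds the %d pooled subject centroids",
             k_group, nrow(pooled))
  }
  grp <- kmeans_seeded(pooled, k_group)
  labels <- lapply(sample_list, function(X) {
    nearest_center(as.matrix(X), grp$centers)
  })
  list(centers = grp$centers, labels = labels,
       subject_centers = subject_centers, k = grp$k)
}
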