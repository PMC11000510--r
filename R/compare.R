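# The analytical-flexibility comparison framework: pairwise method
# similarity at four levels (overall, spatial, temporal, intersubject),
# Ward hierarchical grouping of methods, variance decomposition of dFC over
# method / time / subject, and a time-shuffled permutation null.

SIM_METRICS <- c("spearman", "pearson", "euclidean", "mutual_information")

metric_identity <- function(metric) {
  switch(metric, spearman = 1, pearson = 1, euclidean = 0,
         mutual_information = NA_real_)
}

check_metric <- function(metric) {
  metric <- match.arg(metric, SIM_METRICS)
  metric
}

# Scalar similarity between two equal-length vectors; NA (with caller-level
# warning bookkeeping) when a correlation is undefined.
metric_value <- function(x, y, metric) {
  switch(metric,
         spearman = {
           if (pop_sd(x) == 0 || pop_sd(y) == 0) return(NA_real_)
           stats::cor(x, y, method = "spearman")
         },
         pearson = {
           if (pop_sd(x) == 0 || pop_sd(y) == 0) return(NA_real_)
           stats::cor(x, y)
         },
         euclidean = sqrt(sum((x - y)^2)),
         mutual_information = mutual_information_metric(x, y, warn = FALSE))
}

# Column-wise metric between two T x C matrices (one value per column).
metric_colwise <- function(X, Y, metric) {
  if (metric == "euclidean") return(sqrt(colSums((X - Y)^2)))
  if (metric == "mutual_information") {
    return(vapply(seq_len(ncol(X)), function(c) {
      mutual_information_metric(X[, c], Y[, c], warn = FALSE)
    }, numeric(1)))
  }
  if (metric == "spearman") {
    X <- apply(X, 2, rank, ties.method = "average")
    Y <- apply(Y, 2, rank, ties.method = "average")
  }
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- colSums(Xc * Yc)
  den <- sqrt(colSums(Xc^2) * colSums(Yc^2))
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

new_similarity_result <- function(level, metric, matrix, per_subject = NULL,
                                  n_excluded = 0L, note = NULL) {
  structure(list(level = level, metric = metric, matrix = matrix,
                 per_subject = per_subject, n_excluded = n_excluded,
                 note = note),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> level = %s, metric = %s\n", x$level, x$metric))
  print(round(x$matrix, 3))
  invisible(x)
}

flat_views <- function(arr) {
  d <- dim(arr$values)
  lapply(seq_len(d[1]), function(s) {
    lapply(seq_len(d[2]), function(m) {
      vectorize_dfc(arr$values[s, m, , , ])
    })
  })
}

average_pair_matrices <- function(stack, method_ids) {
  M <- length(method_ids)
  avg <- apply(stack, c(2, 3), mean, na.rm = TRUE)
  dimnames(avg) <- list(method_ids, method_ids)
  avg
}

pairwise_over_subjects <- function(arr, metric, pair_fun, level) {
  metric <- check_metric(metric)
  d <- dim(arr$values)
  S <- d[1]; M <- d[2]
  views <- flat_views(arr)
  stack <- array(NA_real_, c(S, M, M))
  n_excluded <- 0L
  for (s in seq_len(S)) {
    for (i in seq_len(M)) {
      stack[s, i, i] <- if (metric == "mutual_information") {
        pair_fun(views[[s]][[i]], views[[s]][[i]], metric)
      } else metric_identity(metric)
      for (j in seq_len(M)) {
        if (j >= i) next
        v <- pair_fun(views[[s]][[i]], views[[s]][[j]], metric)
        if (is.na(v)) n_excluded <- n_excluded + 1L
        stack[s, i, j] <- v
        stack[s, j, i] <- v
      }
    }
  }
  if (n_excluded > 0) {
    warn_fmt("%s similarity: %d undefined pair value(s) recorded as NaN",
             level, n_excluded)
  }
  new_similarity_result(level, metric,
                        average_pair_matrices(stack, arr$method_ids),
                        per_subject = stack, n_excluded = n_excluded)
}

#' Overall similarity between methods
#'
#' For each subject, each method's dFC block (all time points x all
#' lower-triangle connections) is flattened to one vector, the pairwise
#' metric is computed between methods, and the method x method matrix is
#' averaged over subjects (per-subject stack retained).
#'
#' @param arr A [dfc_array()] on the common time grid.
#' @param metric One of `"spearman"`, `"pearson"`, `"euclidean"`,
#'   `"mutual_information"`.
#' @return A `similarity_result` with fields `matrix` (M x M average) and
#'   `per_subject` (S x M x M stack).
#' @export
overall_similarity <- function(arr, metric = "spearman") {
  stopifnot(inherits(arr, "dfc_array"))
  pairwise_over_subjects(arr, metric, function(X, Y, m) {
    metric_value(as.vector(X), as.vector(Y), m)
  }, "overall")
}

#' Spatial similarity between methods
#'
#' The metric is computed between the two methods' connection vectors at
#' each time point, averaged over time within subject, then over subjects.
#'
#' @inheritParams overall_similarity
#' @return A `similarity_result`.
#' @export
spatial_similarity <- function(arr, metric = "spearman") {
  stopifnot(inherits(arr, "dfc_array"))
  pairwise_over_subjects(arr, metric, function(X, Y, m) {
    per_t <- vapply(seq_len(nrow(X)), function(t) {
      metric_value(X[t, ], Y[t, ], m)
    }, numeric(1))
    if (all(is.na(per_t))) NA_real_ else mean(per_t, na.rm = TRUE)
  }, "spatial")
}

#' Temporal similarity between methods
#'
#' The metric is computed between the two methods' time courses for each
#' functional connection, averaged over connections within subject, then
#' over subjects. Connections with a zero-variance time course under a
#' correlation metric are undefined and excluded from the average (the
#' exclusion count is recorded in `n_excluded`), never imputed.
#'
#' @inheritParams overall_similarity
#' @return A `similarity_result`.
#' @export
temporal_similarity <- function(arr, metric = "spearman") {
  stopifnot(inherits(arr, "dfc_array"))
  excl <- 0L
  res <- pairwise_over_subjects(arr, metric, function(X, Y, m) {
    per_c <- metric_colwise(X, Y, m)
    excl <<- excl + sum(is.na(per_c))
    if (all(is.na(per_c))) NA_real_ else mean(per_c, na.rm = TRUE)
  }, "temporal")
  res$n_excluded <- excl
  res
}

#' Intersubject similarity between methods
#'
#' For each method, the S(S-1)/2 intersubject correlations of the flattened
#' dFC blocks are computed (395 subjects give 77815 values); methods are
#' then compared by the metric between their intersubject-correlation
#' vectors. Alternatively, per-subject feature vectors (e.g., fractional
#' occupancy) can be supplied via `features`.
#'
#' @inheritParams overall_similarity
#' @param features Optional list, one element per method, each an S x F
#'   matrix of per-subject features replacing the flattened dFC.
#' @return A `similarity_result`; the intersubject-correlation vectors are
#'   attached as `intersubj` (M x S(S-1)/2).
#' @export
intersubject_similarity <- function(arr, metric = "spearman",
                                    features = NULL) {
  stopifnot(inherits(arr, "dfc_array"))
  metric <- check_metric(metric)
  d <- dim(arr$values)
  S <- d[1]; M <- d[2]
  if (S < 3) stop_fmt("intersubject similarity needs at least 3 subjects")
  if (is.null(features)) {
    views <- flat_views(arr)
    features <- lapply(seq_len(M), function(m) {
      do.call(rbind, lapply(seq_len(S), function(s) as.vector(views[[s]][[m]])))
    })
  }
  n_pairs <- S * (S - 1) / 2
  isc <- matrix(NA_real_, M, n_pairs)
  for (m in seq_len(M)) {
    Fm <- features[[m]]
    p <- 0L
    for (a in seq_len(S - 1)) {
      for (b in (a + 1):S) {
        p <- p + 1L
        isc[m, p] <- metric_value(Fm[a, ], Fm[b, ], metric)
      }
    }
  }
  mat <- matrix(metric_identity(metric), M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (j > i) next
      v <- if (i == j && metric != "mutual_information") {
        metric_identity(metric)
      } else {
        metric_value(isc[i, ], isc[j, ], metric)
      }
      mat[i, j] <- v
      mat[j, i] <- v
    }
  }
  dimnames(mat) <- list(arr$method_ids, arr$method_ids)
  res <- new_similarity_result("intersubject", metric, mat)
  res$intersubj <- isc
  res
}

#' Mutual information between two continuous vectors (bits)
#'
#' Both vectors are rank-transformed and discretized into `bins`
#' equal-frequency bins; the mutual information of the resulting joint
#' histogram is returned in bits. Identical inputs give `log2(bins)` when
#' the length is a multiple of `bins`.
#'
#' @param x,y Equal-length finite numeric vectors.
#' @param bins Number of equal-frequency bins (default 10).
#' @param warn Warn when the sample is too short for a stable estimate
#'   (length < bins^2).
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information_metric <- function(x, y, bins = 10, warn = TRUE) {
  n <- length(x)
  if (length(y) != n) stop_fmt("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_fmt("inputs must be finite")
  if (warn && n < bins^2) {
    warn_fmt("n = %d < bins^2 = %d: unstable MI estimate", n, bins^2)
  }
  bx <- ceiling(bins * rank(x, ties.method = "first") / n)
  by <- ceiling(bins * rank(y, ties.method = "first") / n)
  joint <- table(factor(bx, levels = seq_len(bins)),
                 factor(by, levels = seq_len(bins))) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Group methods by Ward hierarchical clustering of a similarity matrix
#'
#' Converts the similarity matrix to a distance (`1 - value` for
#' correlation metrics, the raw value for Euclidean distance,
#' `max - value` for mutual information), applies Ward linkage, and cuts
#' the tree at `cutoff_frac` (default 0.7) times the maximum merge height.
#'
#' @param sim A `similarity_result` (or a plain symmetric similarity matrix
#'   plus `metric`).
#' @param metric Metric of a plain-matrix `sim`; ignored when `sim` is a
#'   `similarity_result`.
#' @param cutoff_frac Fraction of the maximum merge height used as the flat
#'   cutoff (default 0.7).
#' @return A `method_grouping`: `tree` (hclust), `cutoff`, `groups` (named
#'   integer vector), `n_groups`, `distance`.
#' @export
group_methods <- function(sim, metric = NULL, cutoff_frac = 0.7) {
  if (inherits(sim, "similarity_result")) {
    metric <- sim$metric
    mat <- sim$matrix
  } else {
    mat <- as.matrix(sim)
    metric <- check_metric(metric %||% "spearman")
  }
  if (any(is.na(mat))) {
    stop_fmt("similarity matrix contains NaN; recompute or impute explicitly before grouping")
  }
  dist_mat <- switch(metric,
                     spearman = 1 - mat,
                     pearson = 1 - mat,
                     euclidean = mat,
                     mutual_information = max(mat) - mat)
  diag(dist_mat) <- 0
  tree <- stats::hclust(stats::as.dist(dist_mat), method = "ward.D2")
  cutoff <- cutoff_frac * max(tree$height)
  if (diff(range(tree$height)) < 1e-12) {
    # flat polytomy (all pairwise distances tie): no split is supported,
    # so everything forms one group
    groups <- rep(1L, nrow(mat))
  } else {
    groups <- stats::cutree(tree, h = cutoff)
  }
  names(groups) <- rownames(mat) %||% paste0("m", seq_len(nrow(mat)))
  structure(list(tree = tree, cutoff = cutoff, groups = groups,
                 n_groups = length(unique(groups)), distance = dist_mat),
            class = "method_grouping")
}

#' @export
print.method_grouping <- function(x, ...) {
  cat(sprintf("<method_grouping> %d group(s), cutoff = %.3f\n",
              x$n_groups, x$cutoff))
  print(split(names(x$groups), x$groups))
  invisible(x)
}

#' Variance decomposition of dFC over method, time, and subject
#'
#' After jointly rank-normalizing each (subject, method) dFC block, computes
#' per (subject, connection): the variance over time averaged over methods
#' (`var_time`) and the variance over methods averaged over time
#' (`var_method`); and per connection: the variance over subjects averaged
#' over time and method (`var_subj`) and the variance over methods averaged
#' over time and subject. Summary ratios compare method variability to the
#' temporal and intersubject variability of dFC; the RSN-pair matrix
#' averages `var_method` and `var_time` over the connections linking each
#' pair of networks before forming `ratio - 1` (0 = equal variability).
#'
#' @param arr A [dfc_array()] with at least 2 methods and 2 time points.
#' @return A `variance_ratios` object: matrices `var_time`, `var_method`
#'   (S x C), vectors `var_subj`, `var_method_c` (C), summary ratios
#'   `mean_var_ratio_method_time`, `mean_sd_ratio_method_time`,
#'   `mean_var_ratio_method_subj`, `mean_sd_ratio_method_subj`, and
#'   `rsn_ratio_minus1` (RSN x RSN).
#' @export
variance_decomposition <- function(arr) {
  stopifnot(inherits(arr, "dfc_array"))
  d <- dim(arr$values)
  S <- d[1]; M <- d[2]; Tn <- d[3]; R <- d[4]
  if (M < 2) stop_fmt("variance over method undefined with a single method")
  if (Tn < 2) stop_fmt("variance over time undefined with a single time point")
  C <- R * (R - 1) / 2
  # A[s, m, t, c]: rank-normalized per (subject, method) block.
  A <- array(0, c(S, M, Tn, C))
  for (s in seq_len(S)) {
    for (m in seq_len(M)) {
      A[s, m, , ] <- rank_normalize(vectorize_dfc(arr$values[s, m, , , ]))
    }
  }
  var_time <- matrix(0, S, C)    # var over t, averaged over m
  var_method <- matrix(0, S, C)  # var over m, averaged over t
  for (s in seq_len(S)) {
    block <- A[s, , , , drop = FALSE]
    dim(block) <- c(M, Tn, C)
    vt <- apply(block, c(1, 3), stats::var)   # M x C
    var_time[s, ] <- colMeans(vt)
    vm <- apply(block, c(2, 3), stats::var)   # T x C
    var_method[s, ] <- colMeans(vm)
  }
  var_method_c <- colMeans(var_method)        # var over m, avg over t and s
  var_subj <- if (S >= 2) {
    vs <- apply(A, c(2, 3, 4), stats::var)    # over subjects -> M x T x C
    apply(vs, 3, mean)
  } else rep(NA_real_, C)

  ok <- var_time > 0
  mean_var_ratio_mt <- mean(var_method[ok] / var_time[ok])
  mean_sd_ratio_mt <- mean(sqrt(var_method[ok]) / sqrt(var_time[ok]))
  if (S >= 2) {
    oks <- var_subj > 0
    mean_var_ratio_ms <- mean(var_method_c[oks] / var_subj[oks])
    mean_sd_ratio_ms <- mean(sqrt(var_method_c[oks]) / sqrt(var_subj[oks]))
  } else {
    mean_var_ratio_ms <- NA_real_
    mean_sd_ratio_ms <- NA_real_
  }

  # RSN-pair aggregation: average variances over the connections linking
  # each network pair (and over subjects) before forming the ratio.
  pairs <- lt_pairs(R)
  rsn_i <- arr$rsn_labels[pairs[, 1]]
  rsn_j <- arr$rsn_labels[pairs[, 2]]
  rsns <- unique(arr$rsn_labels)
  nr <- length(rsns)
  rsn_ratio <- matrix(NA_real_, nr, nr, dimnames = list(rsns, rsns))
  for (a in seq_len(nr)) {
    for (b in seq_len(a)) {
      sel <- (rsn_i == rsns[a] & rsn_j == rsns[b]) |
        (rsn_i == rsns[b] & rsn_j == rsns[a])
      if (!any(sel)) next
      vm <- mean(var_method[, sel])
      vt <- mean(var_time[, sel])
      val <- if (vt > 0) vm / vt - 1 else NA_real_
      rsn_ratio[a, b] <- val
      rsn_ratio[b, a] <- val
    }
  }
  structure(
    list(var_time = var_time, var_method = var_method,
         var_subj = var_subj, var_method_c = var_method_c,
         mean_var_ratio_method_time = mean_var_ratio_mt,
         mean_sd_ratio_method_time = mean_sd_ratio_mt,
         mean_var_ratio_method_subj = mean_var_ratio_ms,
         mean_sd_ratio_method_subj = mean_sd_ratio_ms,
         rsn_ratio_minus1 = rsn_ratio),
    class = "variance_ratios"
  )
}

#' @export
print.variance_ratios <- function(x, ...) {
  cat(sprintf(
    "<variance_ratios> var method/time = %.3f (sd %.3f); var method/subject = %.3f (sd %.3f)\n",
    x$mean_var_ratio_method_time, x$mean_sd_ratio_method_time,
    x$mean_var_ratio_method_subj, x$mean_sd_ratio_method_subj))
  invisible(x)
}

#' Time-shuffled null distribution of overall similarity
#'
#' For each permutation, the time axis of every (subject, method) block is
#' independently permuted — a pure time permutation, so state fractional
#' occupancy is preserved exactly — and the overall similarity matrix is
#' recomputed. Empirical p-values use the one-sided (>= observed) tail with
#' the add-one convention: `p = (1 + #{null >= obs}) / (n_perm + 1)`.
#'
#' @param arr A [dfc_array()].
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @param metric Similarity metric (default `"spearman"`).
#' @return List with `observed` (M x M), `null` (n_perm x M x M), and `p`
#'   (M x M, NA on the diagonal).
#' @export
time_shuffle_null <- function(arr, n_perm = 100, seed = 1L,
                              metric = "spearman") {
  stopifnot(inherits(arr, "dfc_array"))
  metric <- check_metric(metric)
  d <- dim(arr$values)
  S <- d[1]; M <- d[2]; Tn <- d[3]
  observed <- overall_similarity(arr, metric)$matrix
  null <- array(NA_real_, c(n_perm, M, M))
  set.seed(as.integer(seed))
  for (p in seq_len(n_perm)) {
    shuffled <- arr
    for (s in seq_len(S)) {
      for (m in seq_len(M)) {
        perm <- sample.int(Tn)
        shuffled$values[s, m, , , ] <- arr$values[s, m, perm, , ]
      }
    }
    null[p, , ] <- suppressWarnings(overall_similarity(shuffled, metric)$matrix)
  }
  pmat <- matrix(NA_real_, M, M, dimnames = dimnames(observed))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      pmat[i, j] <- (1 + sum(null[, i, j] >= observed[i, j], na.rm = TRUE)) /
        (n_perm + 1)
    }
  }
  list(observed = observed, null = null, p = pmat, n_perm = n_perm,
       seed = as.integer(seed))
}
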