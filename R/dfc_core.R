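# Common dFC data model: per-(subject, method) dFC matrices, the shared
# 5-way dFC array, lower-triangle vectorization, temporal downsampling to
# the sliding-window grid, and joint rank normalization.

#' Construct a dFC matrix (one subject, one method)
#'
#' A time-indexed sequence of symmetric FC matrices: a T' x R x R array with
#' one time stamp (TR index, possibly fractional for window centers) per
#' slice.
#'
#' @param values T' x R x R numeric array; each slice must be symmetric and
#'   free of NaN.
#' @param time_stamps Length-T' numeric vector of TR indices.
#' @param subject_id,method_id Identifiers; `method_id` must be one of
#'   [DFC_METHODS].
#' @param roi_labels,rsn_labels Optional length-R label vectors.
#' @param tol Symmetry tolerance (default 1e-8).
#' @return An object of class `dfc_matrix`.
#' @export
dfc_matrix <- function(values, time_stamps, subject_id, method_id,
                       roi_labels = NULL, rsn_labels = NULL, tol = 1e-8) {
  if (!is.array(values) || length(dim(values)) != 3 ||
      dim(values)[2] != dim(values)[3]) {
    stop_fmt("values must be a T' x R x R array")
  }
  if (!all(is.finite(values))) stop_fmt("dFC values contain NaN/Inf")
  Tn <- dim(values)[1]
  R <- dim(values)[2]
  if (length(time_stamps) != Tn) {
    stop_fmt("time_stamps length (%d) does not match T' (%d)",
             length(time_stamps), Tn)
  }
  if (!method_id %in% DFC_METHODS) {
    stop_fmt("unknown method_id '%s'; valid: %s", method_id,
             paste(DFC_METHODS, collapse = ", "))
  }
  for (t in seq_len(Tn)) {
    check_symmetric(values[t, , ], tol = tol,
                    what = sprintf("FC slice %d", t))
  }
  structure(
    list(subject_id = as.character(subject_id), method_id = method_id,
         time_stamps = as.numeric(time_stamps), values = values,
         roi_labels = as.character(roi_labels %||% paste0("ROI", seq_len(R))),
         rsn_labels = as.character(rsn_labels %||% rep("None", R))),
    class = "dfc_matrix"
  )
}

#' @export
print.dfc_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dfc_matrix> %s / %s: %d x %d x %d\n",
              x$subject_id, x$method_id, d[1], d[2], d[3]))
  invisible(x)
}

# Row-major (i, j), i > j ordering of the strict lower triangle.
lt_pairs <- function(R) {
  idx <- which(lower.tri(matrix(0, R, R)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Vectorize the strict lower triangle of a symmetric FC matrix
#'
#' Returns the R(R-1)/2 off-diagonal values in row-major order of (i, j),
#' i > j; the diagonal is excluded. For R = 96 the vector has length 4560.
#'
#' @param fc Symmetric R x R matrix.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length R(R-1)/2.
#' @seealso [devectorize_lower_triangle()]
#' @export
vectorize_lower_triangle <- function(fc, tol = 1e-8) {
  check_symmetric(fc, tol = tol, what = "FC matrix")
  fc[lt_pairs(nrow(fc))]
}

#' Rebuild a symmetric matrix from its lower-triangle vector
#'
#' @param v Length R(R-1)/2 vector as produced by
#'   [vectorize_lower_triangle()].
#' @param diag Value placed on the diagonal (default 1, the correlation
#'   convention).
#' @return Symmetric R x R matrix.
#' @export
devectorize_lower_triangle <- function(v, diag = 1) {
  L <- length(v)
  R <- (1 + sqrt(1 + 8 * L)) / 2
  if (abs(R - round(R)) > 1e-9) {
    stop_fmt("vector length %d is not R(R-1)/2 for any integer R", L)
  }
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  p <- lt_pairs(R)
  m[p] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

#' Vectorize every time slice of a dFC matrix
#'
#' Stacks the lower-triangle connection vectors of all time slices into a
#' T' x R(R-1)/2 matrix (rows = time points, columns = connections in the
#' [vectorize_lower_triangle()] order).
#'
#' @param values A [dfc_matrix()] or a T x R x R array of symmetric slices.
#' @return T' x C numeric matrix.
#' @export
vectorize_dfc <- function(values) {
  if (inherits(values, "dfc_matrix")) values <- values$values
  R <- dim(values)[2]
  p <- lt_pairs(R)
  flat <- matrix(values, nrow = dim(values)[1])  # T x (R*R), column-major slices
  flat[, (p[, 2] - 1) * R + p[, 1], drop = FALSE]
}

#' Downsample a per-TR dFC matrix onto a coarser time grid
#'
#' Picks, for each target stamp, the source slice whose time stamp is
#' nearest (ties resolved toward the earlier TR). Used to bring per-TR
#' methods onto the 38-point sliding-window grid before assembly; nearest-TR
#' selection (rather than averaging) preserves state labels exactly.
#'
#' @param dfc A [dfc_matrix()].
#' @param target_stamps Numeric vector of target time stamps (TR indices),
#'   each within the range of `dfc$time_stamps`.
#' @return A [dfc_matrix()] on the target grid.
#' @export
temporal_downsample <- function(dfc, target_stamps) {
  stopifnot(inherits(dfc, "dfc_matrix"))
  src <- dfc$time_stamps
  if (any(target_stamps < min(src) - 1e-9) ||
      any(target_stamps > max(src) + 1e-9)) {
    stop_fmt("target stamp outside the source time range [%g, %g]",
             min(src), max(src))
  }
  pick <- vapply(target_stamps, function(tt) {
    which.min(abs(src - tt))  # which.min takes the first (earlier) tie
  }, integer(1))
  dfc_matrix(dfc$values[pick, , , drop = FALSE], target_stamps,
             dfc$subject_id, dfc$method_id, dfc$roi_labels, dfc$rsn_labels)
}

#' Jointly rank-normalize dFC values
#'
#' Replaces all values of one (subject, method) dFC block by their ranks
#' (average rank for ties) computed jointly over time and connections, then
#' rescales to \[0, 1\]. The output depends only on the ordering of the
#' input, so any strictly monotone transform of the input yields identical
#' output; an all-equal input maps to 0.5 everywhere.
#'
#' @param x Numeric vector, matrix, or array of finite values.
#' @return Object of the same shape with values in \[0, 1\].
#' @export
rank_normalize <- function(x) {
  if (!all(is.finite(x))) stop_fmt("rank_normalize requires finite values")
  n <- length(x)
  if (n == 1) {
    x[] <- 0.5
    return(x)
  }
  r <- rank(as.vector(x), ties.method = "average")
  x[] <- (r - 1) / (n - 1)
  x
}

#' Assemble per-(subject, method) dFC matrices into the 5-way dFC array
#'
#' All entries must cover the same subjects, the same methods and share one
#' common time grid (bring per-TR methods onto the window grid with
#' [temporal_downsample()] first). Missing (subject, method) combinations
#' are an error listing the gaps.
#'
#' @param dfc_list List of [dfc_matrix()] objects.
#' @param config Optional [run_config()] embedded in the result.
#' @return A [dfc_array()].
#' @export
assemble_dfc_array <- function(dfc_list, config = NULL) {
  if (!length(dfc_list)) stop_fmt("empty dFC list")
  subjects <- unique(vapply(dfc_list, `[[`, "", "subject_id"))
  methods <- unique(vapply(dfc_list, `[[`, "", "method_id"))
  stamps <- dfc_list[[1]]$time_stamps
  R <- dim(dfc_list[[1]]$values)[2]
  key <- function(s, m) paste(s, m, sep = "\r")
  seen <- new.env(parent = emptyenv())
  for (d in dfc_list) {
    if (!isTRUE(all.equal(d$time_stamps, stamps, tolerance = 1e-9))) {
      stop_fmt("mismatched time grids: %s/%s differs from the first entry",
               d$subject_id, d$method_id)
    }
    if (dim(d$values)[2] != R) stop_fmt("mismatched ROI counts")
    assign(key(d$subject_id, d$method_id), d, envir = seen)
  }
  missing <- character(0)
  vals <- array(NA_real_, c(length(subjects), length(methods), length(stamps), R, R))
  for (si in seq_along(subjects)) {
    for (mi in seq_along(methods)) {
      k <- key(subjects[si], methods[mi])
      if (!exists(k, envir = seen, inherits = FALSE)) {
        missing <- c(missing, sprintf("(%s, %s)", subjects[si], methods[mi]))
        next
      }
      vals[si, mi, , , ] <- get(k, envir = seen)$values
    }
  }
  if (length(missing)) {
    stop_fmt("assembly error; missing (subject, method) cells: %s",
             paste(missing, collapse = ", "))
  }
  d1 <- dfc_list[[1]]
  dfc_array(vals, subjects, methods, stamps, d1$roi_labels, d1$rsn_labels,
            config = config)
}

#' Construct the standardized 5-way dFC array
#'
#' The common container for comparing methods: values indexed as
#' (subject, method, time, ROI, ROI) with label vectors for each axis. In
#' full-scale use the shape is (395, 7, 38, 96, 96).
#'
#' @param values 5-way numeric array, dims S x M x T' x R x R.
#' @param subject_ids,method_ids,time_stamps,roi_labels,rsn_labels Label
#'   vectors matching the array dimensions.
#' @param config Optional [run_config()] that produced the array.
#' @param check_symmetry Validate slice symmetry (default TRUE).
#' @return An object of class `dfc_array`.
#' @export
dfc_array <- function(values, subject_ids, method_ids, time_stamps,
                      roi_labels = NULL, rsn_labels = NULL, config = NULL,
                      check_symmetry = TRUE) {
  d <- dim(values)
  if (length(d) != 5 || d[4] != d[5]) {
    stop_fmt("values must be a 5-way S x M x T' x R x R array")
  }
  if (!all(is.finite(values))) stop_fmt("dFC array contains NaN/Inf")
  if (length(subject_ids) != d[1] || length(method_ids) != d[2] ||
      length(time_stamps) != d[3]) {
    stop_fmt("label axes do not match array dimensions")
  }
  R <- d[4]
  if (check_symmetry) {
    for (s in seq_len(d[1])) {
      for (m in seq_len(d[2])) {
        for (t in seq_len(d[3])) {
          check_symmetric(matrix(values[s, m, t, , ], R, R), tol = 1e-8,
                          what = sprintf("slice (%d,%d,%d)", s, m, t))
        }
      }
    }
  }
  structure(
    list(values = values, subject_ids = as.character(subject_ids),
         method_ids = as.character(method_ids),
         time_stamps = as.numeric(time_stamps),
         roi_labels = as.character(roi_labels %||% paste0("ROI", seq_len(R))),
         rsn_labels = as.character(rsn_labels %||% rep("None", R)),
         config = config),
    class = "dfc_array"
  )
}

#' @export
print.dfc_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dfc_array> %d subjects x %d methods x %d time points x %d x %d ROIs\n",
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Plan a dFC array assembly (manifest of expected cells)
#'
#' Returns the manifest of (subject, method) dFC matrices an assembly over
#' the given registry will contain — one row per expected cell, e.g.,
#' 395 subjects x 7 methods = 2765 matrices.
#'
#' @param subject_ids Character vector of subjects.
#' @param method_ids Character vector of methods.
#' @return A data.frame with columns `subject_id`, `method_id`.
#' @export
plan_assembly <- function(subject_ids, method_ids = DFC_METHODS) {
  unknown <- setdiff(method_ids, DFC_METHODS)
  if (length(unknown)) {
    stop_fmt("unknown method name(s): %s", paste(unknown, collapse = ", "))
  }
  expand.grid(subject_id = as.character(subject_ids),
              method_id = as.character(method_ids),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}
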