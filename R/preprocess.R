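# Subject-level conditioning of parcellated BOLD series: ROI exclusion,
# proportional hemisphere-balanced ROI downsampling, zero-phase high-pass
# filtering, z-standardization.

subset_rois <- function(ts, keep) {
  parcellated_ts(ts$values[, keep, drop = FALSE], ts$tr_seconds,
                 subject_id = ts$subject_id,
                 roi_labels = ts$roi_labels[keep],
                 rsn_labels = ts$rsn_labels[keep],
                 hemisphere = ts$hemisphere[keep])
}

#' Drop ROIs that belong to no resting-state network
#'
#' Columns whose atlas RSN label is the sentinel `"None"` are removed
#' (e.g., a 333-ROI atlas with 47 unassigned parcels retains 286). Order of
#' the remaining ROIs is preserved.
#'
#' @param ts A [parcellated_ts()].
#' @param atlas Optional [atlas_table()]; defaults to the labels carried by
#'   `ts`. When given, it must match the ROI ids of `ts`.
#' @return A [parcellated_ts()] with unassigned ROIs removed.
#' @export
exclude_unassigned_rois <- function(ts, atlas = NULL) {
  stopifnot(inherits(ts, "parcellated_ts"))
  rsn <- ts$rsn_labels
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "atlas_table"))
    if (!identical(atlas$roi_id, ts$roi_labels)) {
      stop_fmt("atlas ROI ids do not match the time series")
    }
    rsn <- atlas$rsn_label
  }
  keep <- rsn != "None"
  if (!any(keep)) stop_fmt("all ROIs are unassigned; nothing would remain")
  subset_rois(ts, keep)
}

#' Downsample ROIs proportionally per network with hemisphere balance
#'
#' Selects at most `n_target` ROIs: each RSN receives a quota proportional
#' to its size (largest-remainder apportionment of hemisphere pairs), split
#' equally between the two hemispheres, and within each (RSN, hemisphere)
#' block ROIs are taken at evenly spaced index positions. The selection is
#' deterministic given the labels. RSNs missing a hemisphere are dropped
#' with a warning.
#'
#' @param ts A [parcellated_ts()]; unassigned (`"None"`) ROIs should be
#'   excluded first.
#' @param n_target Maximum number of ROIs to keep (e.g., 96).
#' @return A [parcellated_ts()] with at most `n_target` ROIs, original
#'   column order preserved.
#' @export
select_uniform_rois <- function(ts, n_target) {
  stopifnot(inherits(ts, "parcellated_ts"))
  R <- ncol(ts$values)
  if (!is_count(n_target)) stop_fmt("n_target must be a positive integer")
  if (n_target > R) stop_fmt("n_target (%d) exceeds available ROIs (%d)",
                             n_target, R)
  if (n_target == R) return(ts)
  rsns <- unique(ts$rsn_labels)
  rsns <- rsns[rsns != "None"]
  # Drop RSNs that cannot contribute one ROI per hemisphere.
  usable <- vapply(rsns, function(nm) {
    all(c("L", "R") %in% ts$hemisphere[ts$rsn_labels == nm])
  }, logical(1))
  if (any(!usable)) {
    warn_fmt("dropping RSN(s) lacking both hemispheres: %s",
             paste(rsns[!usable], collapse = ", "))
  }
  rsns <- rsns[usable]
  if (!length(rsns)) stop_fmt("no RSN has ROIs in both hemispheres")
  sizes <- vapply(rsns, function(nm) sum(ts$rsn_labels == nm), integer(1))
  n_pairs <- n_target %/% 2L
  # Largest-remainder apportionment of hemisphere pairs across RSNs.
  exact <- n_pairs * sizes / sum(sizes)
  quota <- floor(exact)
  left <- n_pairs - sum(quota)
  if (left > 0) {
    ord <- order(exact - quota, decreasing = TRUE)
    quota[ord[seq_len(left)]] <- quota[ord[seq_len(left)]] + 1L
  }
  keep <- logical(R)
  for (i in seq_along(rsns)) {
    q <- quota[i]
    if (q == 0) next
    for (h in c("L", "R")) {
      block <- which(ts$rsn_labels == rsns[i] & ts$hemisphere == h)
      nb <- length(block)
      take <- if (nb <= q) {
        if (nb < q) warn_fmt("RSN %s hemisphere %s has only %d ROIs for quota %d",
                             rsns[i], h, nb, q)
        seq_len(nb)
      } else {
        # Evenly spaced index positions across the block.
        unique(round(seq(1, nb, length.out = q)))
      }
      keep[block[take]] <- TRUE
    }
  }
  subset_rois(ts, keep)
}

#' Zero-phase high-pass filter
#'
#' Applies a 5th-order Butterworth high-pass filter forward and backward
#' (zero phase) to each ROI time course; the default 0.01 Hz cutoff removes
#' slow scanner drift while leaving the resting-state band intact.
#'
#' @param ts A [parcellated_ts()].
#' @param cutoff_hz High-pass cutoff frequency in Hz (default 0.01).
#' @param order Filter order (default 5).
#' @return The filtered [parcellated_ts()].
#' @export
highpass_filter <- function(ts, cutoff_hz = 0.01, order = 5) {
  stopifnot(inherits(ts, "parcellated_ts"))
  fs <- 1 / ts$tr_seconds
  nyq <- fs / 2
  if (!(cutoff_hz > 0) || cutoff_hz >= nyq) {
    stop_fmt("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)", cutoff_hz, nyq)
  }
  if (nrow(ts$values) <= 3 * (order + 1)) {
    stop_fmt("series too short (%d points) for order-%d zero-phase filtering",
             nrow(ts$values), order)
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  filtered <- apply(ts$values, 2, function(x) {
    signal::filtfilt(bf, x - mean(x))
  })
  parcellated_ts(filtered, ts$tr_seconds, subject_id = ts$subject_id,
                 roi_labels = ts$roi_labels, rsn_labels = ts$rsn_labels,
                 hemisphere = ts$hemisphere)
}

#' z-standardize each ROI time course
#'
#' Centers each column to mean 0 and scales to standard deviation 1 using
#' the population (1/T) variance convention.
#'
#' @param ts A [parcellated_ts()].
#' @return The standardized [parcellated_ts()].
#' @export
z_standardize <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  sds <- apply(ts$values, 2, pop_sd)
  if (any(sds == 0)) {
    bad <- ts$roi_labels[sds == 0]
    stop_fmt("zero-variance ROI(s): %s", paste(bad, collapse = ", "))
  }
  z <- sweep(sweep(ts$values, 2, colMeans(ts$values)), 2, sds, "/")
  parcellated_ts(z, ts$tr_seconds, subject_id = ts$subject_id,
                 roi_labels = ts$roi_labels, rsn_labels = ts$rsn_labels,
                 hemisphere = ts$hemisphere)
}
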