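# Parcellated BOLD time series: one subject's T x R matrix (rows = TRs,
# columns = ROIs in atlas order) with sampling interval and ROI labels.

#' Construct a parcellated time series
#'
#' @param values Numeric T x R matrix, rows = time points (TRs), columns =
#'   ROIs. All values must be finite; T >= 2.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param subject_id Subject identifier string.
#' @param roi_labels,rsn_labels,hemisphere Length-R label vectors (ROI id,
#'   resting-state network, hemisphere code).
#' @return An object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(values, tr_seconds, subject_id = "subject",
                           roi_labels = NULL, rsn_labels = NULL,
                           hemisphere = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2) stop_fmt("time series needs at least 2 time points")
  if (!all(is.finite(values))) stop_fmt("time series contains NaN/Inf/NA values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    stop_fmt("tr_seconds must be a positive scalar")
  }
  R <- ncol(values)
  roi_labels <- as.character(roi_labels %||% paste0("ROI", seq_len(R)))
  rsn_labels <- as.character(rsn_labels %||% rep("None", R))
  hemisphere <- as.character(hemisphere %||% rep(c("L", "R"), length.out = R))
  if (length(roi_labels) != R || length(rsn_labels) != R ||
      length(hemisphere) != R) {
    stop_fmt("label vectors must have length R = %d", R)
  }
  dimnames(values) <- NULL
  structure(
    list(subject_id = as.character(subject_id), tr_seconds = tr_seconds,
         values = values, roi_labels = roi_labels, rsn_labels = rsn_labels,
         hemisphere = hemisphere),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("<parcellated_ts> subject %s: %d time points x %d ROIs, TR = %g s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Read a parcellated time series from a delimited text file
#'
#' The file holds the numeric T x R body, rows = time points, with an
#' optional single header line. The ROI (column) order is defined by the
#' atlas, never by the file: a column-count mismatch is an error.
#'
#' @param path Path to a TSV (or CSV, by extension) matrix file.
#' @param atlas An [atlas_table()] defining ROI order and labels.
#' @param tr_seconds Repetition time in seconds (default 0.72).
#' @param subject_id Subject identifier; defaults to the file base name.
#' @return A [parcellated_ts()].
#' @export
read_timeseries <- function(path, atlas, tr_seconds = 0.72,
                            subject_id = NULL) {
  stopifnot(inherits(atlas, "atlas_table"))
  if (!file.exists(path)) stop_fmt("time-series file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop_fmt("empty time-series file: %s", path)
  # Optional header: drop the first line if any field is non-numeric.
  first <- suppressWarnings(as.numeric(unlist(raw[1, ], use.names = FALSE)))
  if (anyNA(first)) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) != nrow(atlas)) {
    stop_fmt("format error: file has %d columns but atlas defines %d ROIs",
             ncol(raw), nrow(atlas))
  }
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw), ncol = ncol(raw))
  )
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_fmt("parse error: non-numeric cell at row %d, column %d",
             bad[1], bad[2])
  }
  parcellated_ts(num, tr_seconds,
                 subject_id = subject_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 roi_labels = atlas$roi_id, rsn_labels = atlas$rsn_label,
                 hemisphere = atlas$hemisphere)
}

#' Write a parcellated time series to a TSV file
#'
#' Values are written with 15 significant digits; a
#' [write_timeseries()]/[read_timeseries()] roundtrip reproduces them to
#' within 1e-12.
#'
#' @param ts A [parcellated_ts()].
#' @param path Output path.
#' @param header Write a header line of ROI ids (default TRUE).
#' @export
write_timeseries <- function(ts, path, header = TRUE) {
  stopifnot(inherits(ts, "parcellated_ts"))
  body <- apply(ts$values, 1, function(r) {
    paste(sprintf("%.15g", r), collapse = "\t")
  })
  lines <- if (header) c(paste(ts$roi_labels, collapse = "\t"), body) else body
  writeLines(lines, path)
  invisible(path)
}
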